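#' Recursive-least-squares motion-artifact cancellation for PPG
#'
#' Head and body motion couples into forehead PPG through the optical path;
#' the tri-axial accelerometer sees the same motion and serves as the
#' artifact reference. Each reference channel drives an exponentially
#' weighted RLS adaptive FIR that predicts the artifact component of the
#' PPG; the prediction is subtracted. The default topology is a cascade of
#' three single-reference stages (x, then y, then z); `"joint"` stacks all
#' three references into one multi-channel stage.
#'
#' With an all-zero reference the prediction is identically zero and the
#' input passes through unchanged.
#'
#' @param ppg PPG samples.
#' @param accel numeric matrix or data frame with 3 columns (x, y, z
#'   acceleration), same number of rows as `length(ppg)`.
#' @param order FIR taps per reference channel (default 10).
#' @param lambda forgetting factor in (0, 1] (default 0.999).
#' @param delta inverse-correlation initialization scale (> 0, default
#'   0.01): the inverse correlation matrix starts at `I / delta`.
#' @param topology `"cascade"` (default) or `"joint"`.
#' @return Cleaned PPG samples, same length as the input.
#' @export
rls_cancel <- function(ppg, accel, order = 10L, lambda = 0.999, delta = 0.01,
                       topology = c("cascade", "joint")) {
  topology <- match.arg(topology)
  check_finite(ppg, "ppg")
  accel <- as.matrix(accel)
  if (!is.numeric(accel) || anyNA(accel) || any(!is.finite(accel))) {
    stop_data("`accel` must be finite and numeric")
  }
  if (ncol(accel) != 3L) stop_data("`accel` must have 3 columns")
  if (nrow(accel) != length(ppg)) stop_data("`ppg` and `accel` lengths differ")
  if (lambda <= 0 || lambda > 1) stop_config("`lambda` must lie in (0, 1]")
  if (delta <= 0) stop_config("`delta` must be > 0")
  if (order < 1L) stop_config("`order` must be >= 1")
  if (topology == "cascade") {
    d <- ppg
    for (ax in 1:3) d <- rls_stage(d, accel[, ax, drop = FALSE], order, lambda, delta)
    d
  } else {
    rls_stage(ppg, accel, order, lambda, delta)
  }
}

# one exponentially weighted RLS stage; ref may have multiple columns
# (taps are stacked per column). Returns the error signal d - w'u.
rls_stage <- function(d, ref, order, lambda, delta) {
  n <- length(d)
  nch <- ncol(ref)
  m <- order * nch
  w <- numeric(m)
  P <- diag(1 / delta, m)
  out <- numeric(n)
  buf <- matrix(0, order, nch)  # most recent reference samples, row 1 = newest
  for (i in seq_len(n)) {
    if (order > 1L) buf[2:order, ] <- buf[1:(order - 1L), ]
    buf[1L, ] <- ref[i, ]
    u <- as.vector(buf)
    if (all(u == 0)) { out[i] <- d[i]; next }
    Pu <- P %*% u
    denom <- lambda + sum(u * Pu)
    # round-off can destroy the symmetry / positive-definiteness of P over
    # long runs; guard the gain denominator and re-symmetrize each step
    if (denom < .Machine$double.eps) denom <- .Machine$double.eps
    k <- as.vector(Pu) / denom
    e <- d[i] - sum(w * u)
    w <- w + k * e
    P <- (P - tcrossprod(k, as.vector(Pu))) / lambda
    P <- (P + t(P)) / 2
    out[i] <- e
  }
  out
}

#' Windowed pulse-rate estimation by FFT spectral-peak tracking
#'
#' Slides an 8-s window in 2-s steps (6-s overlap). Each window is
#' detrended, Hann-windowed and zero-padded to a spectral resolution of at
#' most `resolution_hz`; the pulse-rate peak is searched in the cardiac
#' band 0.7-3.5 Hz (42-210 BPM). Tracking verification: after the first
#' window (global in-band maximum) the strongest spectral peak within
#' `collar_bpm` of the previous estimate is preferred, falling back to the
#' global in-band maximum if the collar holds no peak (re-acquisition); a
#' peak landing near twice the previous estimate is treated as the second
#' harmonic and halved.
#'
#' @param ppg PPG samples (any amplitude scale; estimates are
#'   amplitude-invariant).
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds (default 8).
#' @param step_s window step in seconds (default 2).
#' @param fmin,fmax cardiac search band in Hz.
#' @param collar_bpm tracking collar around the previous estimate (default
#'   12 BPM).
#' @param resolution_hz maximum FFT bin spacing (default 0.02 Hz).
#' @return A tibble of class `pr_series` with `window`, `start_s`,
#'   `pr_bpm`; attributes `win_s`, `step_s`, `fs`.
#' @export
estimate_pr <- function(ppg, fs, win_s = 8, step_s = 2, fmin = 0.7, fmax = 3.5,
                        collar_bpm = 12, resolution_hz = 0.02) {
  check_finite(ppg, "ppg")
  nwin <- round(win_s * fs)
  if (length(ppg) < nwin) stop_data("recording shorter than one %g-s window", win_s)
  step <- round(step_s * fs)
  starts <- seq(1L, length(ppg) - nwin + 1L, by = step)
  nfft <- 2^ceiling(log2(fs / resolution_hz))
  nfft <- max(nfft, nwin)
  freq <- (0:(nfft - 1L)) * fs / nfft
  band <- which(freq >= fmin & freq <= fmax)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L))
  tt <- seq_len(nwin)
  prev_f <- NA_real_
  pr <- numeric(length(starts))
  for (j in seq_along(starts)) {
    seg <- ppg[starts[j]:(starts[j] + nwin - 1L)]
    fit <- lm.fit(cbind(1, tt), seg)
    seg <- fit$residuals * hann
    spec <- Mod(fft(c(seg, rep(0, nfft - nwin))))^2
    sb <- spec[band]
    # local maxima within the band
    is_peak <- c(FALSE, sb[2:(length(sb) - 1L)] > sb[1:(length(sb) - 2L)] &
                   sb[2:(length(sb) - 1L)] >= sb[3:length(sb)], FALSE)
    peak_idx <- band[is_peak]
    if (!length(peak_idx)) peak_idx <- band[which.max(sb)]
    f_cand <- freq[peak_idx]
    if (is.na(prev_f)) {
      f_sel <- freq[band[which.max(sb)]]
    } else {
      collar_hz <- collar_bpm / 60
      near <- which(abs(f_cand - prev_f) <= collar_hz)
      f_sel <- if (length(near)) {
        f_cand[near[which.min(abs(f_cand[near] - prev_f))]]
      } else {
        # collar empty: re-acquire from the global in-band maximum
        freq[band[which.max(sb)]]
      }
    }
    # harmonic guard: if substantial power sits at half the chosen
    # frequency, the choice is the 2nd harmonic of the true pulse
    if (f_sel / 2 >= fmin) {
      nb_half <- which(abs(freq[band] - f_sel / 2) <= 0.06)
      if (length(nb_half)) {
        p_half <- max(sb[nb_half])
        p_sel <- spec[which.min(abs(freq - f_sel))]
        if (p_half >= 0.4 * p_sel) {
          f_sel <- freq[band[nb_half[which.max(sb[nb_half])]]]
        }
      }
    }
    prev_f <- f_sel
    pr[j] <- 60 * f_sel
  }
  out <- tibble(window = seq_along(starts), start_s = (starts - 1L) / fs,
                pr_bpm = pr)
  class(out) <- c("pr_series", class(out))
  attr(out, "win_s") <- win_s
  attr(out, "step_s") <- step_s
  attr(out, "fs") <- fs
  out
}

#' Ground-truth pulse rate per analysis window
#'
#' Averages an instantaneous pulse-rate track over the same windows that
#' [estimate_pr()] uses, aligning estimated and true series for agreement
#' statistics.
#'
#' @param pr_track_bpm instantaneous pulse rate in BPM, sampled at `fs`.
#' @param fs sampling rate of the track in Hz.
#' @param win_s,step_s window geometry, matching [estimate_pr()].
#' @return A `pr_series` tibble with the window-mean true rate.
#' @export
windowed_truth <- function(pr_track_bpm, fs, win_s = 8, step_s = 2) {
  check_finite(pr_track_bpm, "pr_track_bpm")
  nwin <- round(win_s * fs)
  if (length(pr_track_bpm) < nwin) stop_data("track shorter than one window")
  starts <- seq(1L, length(pr_track_bpm) - nwin + 1L, by = round(step_s * fs))
  pr <- vapply(starts, function(s) mean(pr_track_bpm[s:(s + nwin - 1L)]), numeric(1))
  out <- tibble(window = seq_along(starts), start_s = (starts - 1L) / fs, pr_bpm = pr)
  class(out) <- c("pr_series", class(out))
  attr(out, "win_s") <- win_s
  attr(out, "step_s") <- step_s
  attr(out, "fs") <- fs
  out
}

as_pr_vector <- function(x, what) {
  if (inherits(x, "pr_series") || (is.data.frame(x) && "pr_bpm" %in% names(x))) {
    return(x$pr_bpm)
  }
  if (is.numeric(x)) return(as.numeric(x))
  stop_data("`%s` must be numeric or a pr_series", what)
}

#' Average absolute error between pulse-rate series
#'
#' `AAE = (1/W) * sum |PR_est(i) - PR_true(i)|` over the W analysis
#' windows.
#'
#' @param pr_est,pr_true numeric vectors or `pr_series` tibbles of equal
#'   length.
#' @return AAE in BPM.
#' @export
aae <- function(pr_est, pr_true) {
  est <- as_pr_vector(pr_est, "pr_est")
  tru <- as_pr_vector(pr_true, "pr_true")
  if (length(est) != length(tru)) stop_data("series lengths differ")
  if (!length(est)) stop_data("empty series")
  mean(abs(est - tru))
}

#' Agreement statistics between estimated and true pulse rates
#'
#' Bland-Altman bias and 95% limits of agreement (`bias +/- 1.96 sd` of the
#' paired differences) together with the Pearson correlation and the AAE.
#'
#' @param pr_est,pr_true numeric vectors or `pr_series` tibbles of equal
#'   length (>= 3); neither may be constant.
#' @return A one-row tibble of class `pr_agreement` with `aae_bpm`,
#'   `bias_bpm`, `loa_low_bpm`, `loa_high_bpm`, `pearson_r`, `n`.
#' @export
agreement <- function(pr_est, pr_true) {
  est <- as_pr_vector(pr_est, "pr_est")
  tru <- as_pr_vector(pr_true, "pr_true")
  if (length(est) != length(tru)) stop_data("series lengths differ")
  if (length(est) < 3L) stop_data("need at least 3 paired windows")
  if (var(est) == 0 || var(tru) == 0) {
    stop_data("undefined correlation: zero-variance input")
  }
  d <- est - tru
  bias <- mean(d)
  s <- sd(d)
  out <- tibble(
    aae_bpm = mean(abs(d)),
    bias_bpm = bias,
    loa_low_bpm = bias - 1.96 * s,
    loa_high_bpm = bias + 1.96 * s,
    pearson_r = cor(est, tru),
    n = length(d)
  )
  class(out) <- c("pr_agreement", class(out))
  out
}

#' @export
tidy.pr_agreement <- function(x, ...) {
  tibble(
    term = c("aae_bpm", "bias_bpm", "loa_low_bpm", "loa_high_bpm", "pearson_r"),
    estimate = c(x$aae_bpm, x$bias_bpm, x$loa_low_bpm, x$loa_high_bpm, x$pearson_r)
  )
}

#' @export
glance.pr_agreement <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
autoplot.pr_series <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$start_s, y = .data$pr_bpm)) +
    ggplot2::geom_line(ggplot2::aes(colour = "estimated")) +
    ggplot2::labs(x = "window start (s)", y = "pulse rate (BPM)", colour = NULL)
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth,
      ggplot2::aes(x = .data$start_s, y = .data$pr_bpm, colour = "truth")
    )
  }
  p
}

#' Bland-Altman plot of paired pulse-rate series
#'
#' @param pr_est,pr_true paired series (vectors or `pr_series`).
#' @return A ggplot: per-window difference against per-window mean, with
#'   the bias and 95% limits of agreement as horizontal lines.
#' @export
plot_bland_altman <- function(pr_est, pr_true) {
  est <- as_pr_vector(pr_est, "pr_est")
  tru <- as_pr_vector(pr_true, "pr_true")
  stats <- agreement(est, tru)
  dat <- tibble(mean_bpm = (est + tru) / 2, diff_bpm = est - tru)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_bpm, y = .data$diff_bpm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = stats$bias_bpm, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(stats$loa_low_bpm, stats$loa_high_bpm),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of estimate and truth (BPM)",
                  y = "estimate - truth (BPM)")
}

#' Bland-Altman scatter data for external plotting
#'
#' @param pr_est,pr_true paired series.
#' @return A tibble with `mean_bpm`, `diff_bpm`, plus the agreement
#'   statistics as attributes.
#' @export
bland_altman_data <- function(pr_est, pr_true) {
  est <- as_pr_vector(pr_est, "pr_est")
  tru <- as_pr_vector(pr_true, "pr_true")
  out <- tibble(mean_bpm = (est + tru) / 2, diff_bpm = est - tru)
  attr(out, "agreement") <- agreement(est, tru)
  out
}
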