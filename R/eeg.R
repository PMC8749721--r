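#' Welch power spectral density estimate
#'
#' Averages modified periodograms of overlapping, Hann-windowed,
#' mean-removed segments. The one-sided density is scaled so that the
#' trapezoidal integral over frequency approximates the signal variance
#' (Parseval).
#'
#' @param x numeric sample vector; must cover at least one segment.
#' @param fs sampling rate in Hz.
#' @param segment_len_s segment length in seconds (default 2).
#' @param overlap_frac fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @return A tibble of class `biopad_psd` with columns `freq_hz` and `power`
#'   (input units squared per Hz) and attributes `fs`, `segment_len_s`,
#'   `overlap_frac`.
#' @export
welch_psd <- function(x, fs, segment_len_s = 2, overlap_frac = 0.5) {
  check_finite(x, "x")
  if (overlap_frac < 0 || overlap_frac >= 1) stop_config("`overlap_frac` must be in [0, 1)")
  nseg <- round(segment_len_s * fs)
  if (nseg < 8L) stop_config("segment too short")
  if (length(x) < nseg) stop_data("input shorter than one segment (%d samples)", nseg)
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L))  # Hann
  u <- sum(w^2)
  half <- floor(nseg / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- Mod(fft(seg))^2 / (fs * u)
    spec <- spec[1:half]
    # fold negative frequencies into the one-sided density
    interior <- 2:(half - 1L)
    if (nseg %% 2 == 0) spec[interior] <- 2 * spec[interior]
    else spec[2:half] <- 2 * spec[2:half]
    acc <- acc + spec
  }
  out <- tibble(
    freq_hz = (0:(half - 1L)) * fs / nseg,
    power = acc / length(starts)
  )
  class(out) <- c("biopad_psd", class(out))
  attr(out, "fs") <- fs
  attr(out, "segment_len_s") <- segment_len_s
  attr(out, "overlap_frac") <- overlap_frac
  out
}

#' @export
autoplot.biopad_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD ~ (units^2 / Hz)))
}

#' @export
glance.biopad_psd <- function(x, ...) {
  tibble(
    peak_freq_hz = x$freq_hz[which.max(x$power)],
    total_power = trapz(x$freq_hz, x$power),
    n_bins = nrow(x)
  )
}

#' Absolute and relative band power from a PSD
#'
#' Trapezoidal integral of the density over `(lo, hi]`; `relative` divides by
#' the integral over the full `(0, fs/2]` range (DC bin excluded).
#'
#' @param psd a `biopad_psd` tibble from [welch_psd()].
#' @param lo,hi band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return A one-row tibble with `band_lo_hz`, `band_hi_hz`, `absolute`,
#'   `relative`.
#' @export
band_power <- function(psd, lo, hi) {
  fs <- attr(psd, "fs")
  if (is.null(fs)) fs <- 2 * max(psd$freq_hz)
  if (!(lo >= 0 && lo < hi && hi <= fs / 2 + 1e-9)) {
    stop_data("band edges must satisfy 0 <= lo < hi <= fs/2")
  }
  in_band <- psd$freq_hz > lo & psd$freq_hz <= hi
  if (sum(in_band) < 2L) stop_data("band (%g, %g] covers fewer than 2 PSD bins", lo, hi)
  total_sel <- psd$freq_hz > 0
  absolute <- trapz(psd$freq_hz[in_band], psd$power[in_band])
  total <- trapz(psd$freq_hz[total_sel], psd$power[total_sel])
  tibble(band_lo_hz = lo, band_hi_hz = hi, absolute = absolute,
         relative = if (total > 0) absolute / total else NA_real_)
}

#' Alpha-band dominance between eyes-closed and eyes-open EEG
#'
#' Ratio of the relative alpha-band (8-13 Hz by default) power of the
#' eyes-closed segment to that of the eyes-open segment. Values above 1
#' indicate alpha blocking on eye opening; clearly resolvable alpha gives
#' ratios well above 2. Both segments should be clean epochs of at least
#' 15 s.
#'
#' @param eeg_closed,eeg_open numeric EEG sample vectors (same units).
#' @param fs sampling rate in Hz.
#' @param band alpha band edges in Hz.
#' @param min_epoch_s minimum epoch length in seconds.
#' @return A one-row tibble with `rel_alpha_closed`, `rel_alpha_open`,
#'   `ratio`.
#' @export
alpha_dominance <- function(eeg_closed, eeg_open, fs, band = c(8, 13),
                            min_epoch_s = 15) {
  for (seg in list(eeg_closed, eeg_open)) {
    if (length(seg) < min_epoch_s * fs) {
      stop_data("each epoch must cover at least %g s", min_epoch_s)
    }
  }
  if (var(eeg_closed) == 0 || var(eeg_open) == 0) {
    stop_data("degenerate (zero-power) epoch")
  }
  rel <- function(seg) {
    band_power(welch_psd(seg, fs), band[1L], band[2L])$relative
  }
  rc <- rel(eeg_closed); ro <- rel(eeg_open)
  if (!is.finite(ro) || ro == 0) stop_data("eyes-open epoch has no measurable power")
  tibble(rel_alpha_closed = rc, rel_alpha_open = ro, ratio = rc / ro)
}

#' Pearson correlation between two PSDs on the same grid
#'
#' Used to compare spectra of the same signal recorded by two devices.
#'
#' @param psd_a,psd_b `biopad_psd` tibbles on identical frequency grids.
#' @return Pearson r in `[-1, 1]`.
#' @export
psd_pearson <- function(psd_a, psd_b) {
  if (nrow(psd_a) != nrow(psd_b) ||
      max(abs(psd_a$freq_hz - psd_b$freq_hz)) > 1e-9) {
    stop_data("PSDs must share the same frequency grid")
  }
  if (var(psd_a$power) == 0 || var(psd_b$power) == 0) {
    stop_data("undefined correlation: constant PSD")
  }
  cor(psd_a$power, psd_b$power)
}

#' Detect eye-blink transients in frontal EEG
#'
#' Blinks appear on frontal channels as large (~100 uV) slow biphasic
#' pulses. The detector low-passes the signal below `lowpass_hz`
#' (zero-phase, to preserve event timing), flags excursions beyond
#' `k` scaled median absolute deviations from the median, and keeps one
#' event per suprathreshold run with at least `refractory_s` spacing.
#' This is a pragmatic fixture-validation detector, not a published
#' algorithm.
#'
#' @param x frontal EEG samples (uV).
#' @param fs sampling rate in Hz.
#' @param lowpass_hz detector low-pass corner (default 5 Hz).
#' @param k MAD multiplier (default 6).
#' @param refractory_s minimum spacing between events in seconds.
#' @return A tibble with `time_s` (peak time) and `peak_uv`; zero rows when
#'   nothing crosses threshold.
#' @export
detect_blinks <- function(x, fs, lowpass_hz = 5, k = 6, refractory_s = 0.5) {
  check_finite(x, "x")
  if (length(x) < fs) return(tibble(time_s = numeric(), peak_uv = numeric()))
  lp <- design_butterworth_lp(order = 2L, fc = lowpass_hz, fs = fs)
  y <- apply_iir_df2(x, lp, zero_phase = TRUE)
  dev <- abs(y - median(y))
  thr <- k * mad(y)
  above <- dev > thr & thr > 0
  if (!any(above)) return(tibble(time_s = numeric(), peak_uv = numeric()))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  peaks <- vapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(dev[idx])]
  }, integer(1))
  times <- (peaks - 1L) / fs
  sel <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) {
      sel[i] <- TRUE
      last <- times[i]
    }
  }
  tibble(time_s = times[sel], peak_uv = y[peaks[sel]])
}
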