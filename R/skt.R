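#' Weighted three-point moving average for skin temperature
#'
#' `y(n) = 0.8 x(n) + 0.1 x(n-1) + 0.1 x(n-2)`; the first two samples are
#' passed through unchanged (warm-up). Weights sum to one, so constants are
#' preserved.
#'
#' @param x temperature samples (degC), length >= 3.
#' @param weights the three weights, most recent first.
#' @return Smoothed samples, same length as `x`.
#' @export
smooth_skt <- function(x, weights = c(0.8, 0.1, 0.1)) {
  check_finite(x, "x")
  if (length(x) < 3L) stop_data("`x` must have at least 3 samples")
  if (length(weights) != 3L) stop_config("`weights` must have length 3")
  n <- length(x)
  y <- x
  idx <- 3:n
  y[idx] <- weights[1L] * x[idx] + weights[2L] * x[idx - 1L] + weights[3L] * x[idx - 2L]
  y
}

#' Stimulus-locked skin-temperature response
#'
#' Quantifies the temperature change across a stimulation paradigm:
#' the baseline mean, the stimulus delta (mean over the last `edge_s`
#' seconds of the stimulus window minus the mean over its first `edge_s`
#' seconds — robust to noise compared with point differences), and the
#' post-stimulus recovery slope by least squares. Unpleasant stimulation
#' typically produces a negative delta of a few tenths of a degree.
#'
#' @param x temperature samples (degC).
#' @param fs sampling rate in Hz.
#' @param baseline_win,stim_win,recovery_win `(t0, t1)` windows in seconds;
#'   must lie within the record, be ordered and non-overlapping.
#' @param edge_s edge-mean length for the stimulus delta (default 5 s).
#' @return A one-row tibble of class `skt_response` with `baseline_mean_c`,
#'   `stim_delta_c`, `recovery_slope_c_per_s`.
#' @export
stimulus_delta <- function(x, fs, baseline_win, stim_win, recovery_win,
                           edge_s = 5) {
  check_finite(x, "x")
  dur <- length(x) / fs
  wins <- list(baseline = baseline_win, stimulus = stim_win, recovery = recovery_win)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) != 2L || w[1L] < 0 || w[2L] > dur + 1e-9 || w[1L] >= w[2L]) {
      stop_data("%s window out of bounds or degenerate", nm)
    }
  }
  if (baseline_win[2L] > stim_win[1L] + 1e-9 || stim_win[2L] > recovery_win[1L] + 1e-9) {
    stop_data("windows must be ordered and non-overlapping")
  }
  if (diff(stim_win) < 2 * edge_s) {
    stop_data("stimulus window must cover at least 2 * edge_s = %g s", 2 * edge_s)
  }
  win_idx <- function(t0, t1) {
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(length(x), ceiling(t1 * fs))
    i0:i1
  }
  baseline_mean <- mean(x[win_idx(baseline_win[1L], baseline_win[2L])])
  first_edge <- mean(x[win_idx(stim_win[1L], stim_win[1L] + edge_s)])
  last_edge <- mean(x[win_idx(stim_win[2L] - edge_s, stim_win[2L])])
  rec_idx <- win_idx(recovery_win[1L], recovery_win[2L])
  t_rec <- (rec_idx - 1L) / fs
  slope <- if (length(rec_idx) > 1L) unname(coef(lm(x[rec_idx] ~ t_rec))[2L]) else 0
  out <- tibble(
    baseline_mean_c = baseline_mean,
    stim_delta_c = last_edge - first_edge,
    recovery_slope_c_per_s = slope
  )
  class(out) <- c("skt_response", class(out))
  out
}
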