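#' Band-split signal-to-noise ratio of an EDA segment
#'
#' Electrodermal activity carries essentially all of its information below
#' 5 Hz, so the SNR statistic takes the periodogram power in `(0, band_edge]`
#' Hz as signal and everything in `(band_edge, fs/2]` as noise:
#' `SNR_dB = 10 log10( sum PSD(0,5] / sum PSD(5, fs/2] )`. The DC bin is
#' excluded. A rectangular-window periodogram over the whole segment is
#' used; segments are conventionally 10 s.
#'
#' @param x EDA samples (uS); at least 10 s at `fs`.
#' @param fs sampling rate in Hz; must exceed `2 * band_edge`.
#' @param band_edge signal/noise split frequency in Hz (default 5).
#' @return A one-row tibble with `snr_db`, `fs`, `band_edge`.
#' @export
eda_snr <- function(x, fs, band_edge = 5) {
  check_finite(x, "x")
  if (fs <= 2 * band_edge) stop_config("`fs` must exceed 2 * band_edge")
  if (length(x) < 10 * fs) stop_data("EDA segment must cover at least 10 s")
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  freq <- (0:(n - 1L)) * fs / n
  half <- freq <= fs / 2
  sig <- sum(spec[half & freq > 0 & freq <= band_edge])
  noise <- sum(spec[half & freq > band_edge])
  snr <- if (noise == 0) {
    warn("zero noise power: SNR is infinite", class = "biopad_snr_warning")
    Inf
  } else {
    10 * log10(sig / noise)
  }
  tibble(snr_db = snr, fs = fs, band_edge = band_edge)
}

#' Segment-wise EDA SNR over a recording
#'
#' Splits the recording into `seg_s`-second segments with fractional
#' `overlap` (a 150-s recording at 10 s / 50% yields 29 segments) and
#' computes [eda_snr()] for each. `glance()` on the result gives the mean
#' and standard deviation in dB (`sd = 0` for a single segment).
#'
#' @param x EDA samples (uS).
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 10).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param band_edge signal/noise split in Hz.
#' @return A tibble of class `eda_snr_segments` with one row per segment:
#'   `segment`, `start_s`, `snr_db`.
#' @export
segment_snr <- function(x, fs, seg_s = 10, overlap = 0.5, band_edge = 5) {
  check_finite(x, "x")
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) stop_data("recording shorter than one segment")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  snr <- vapply(starts, function(s) {
    eda_snr(x[s:(s + nseg - 1L)], fs, band_edge)$snr_db
  }, numeric(1))
  out <- tibble(segment = seq_along(starts), start_s = (starts - 1L) / fs,
                snr_db = snr)
  class(out) <- c("eda_snr_segments", class(out))
  out
}

#' @export
glance.eda_snr_segments <- function(x, ...) {
  tibble(
    n_segments = nrow(x),
    mean_snr_db = mean(x$snr_db),
    sd_snr_db = if (nrow(x) > 1L) sd(x$snr_db) else 0
  )
}

#' Extract the skin-conductance-response signal from EDA
#'
#' The phasic extraction chain: anti-alias low-pass (zero-phase order-8
#' Butterworth at 8 Hz), decimation to 20 Hz, first differencing scaled to
#' a derivative in uS/s, then smoothing by convolution with a 20-point
#' Bartlett (triangular) window normalized to unit sum (support 1 s at
#' 20 Hz). Output length matches the decimated signal; the derivative at
#' the first sample is taken as zero.
#'
#' @param x EDA samples (uS); at least 2 s.
#' @param fs input sampling rate in Hz (>= 40 and an integer multiple
#'   of 20).
#' @return A tibble of class `biopad_scr` with `time_s` and `scr_us_per_s`
#'   at 20 Hz.
#' @export
extract_scr <- function(x, fs) {
  check_finite(x, "x")
  if (fs < 40) stop_config("`fs` must be at least 40 Hz")
  if (fs %% 20 != 0) stop_config("`fs` must be an integer multiple of 20 Hz")
  if (length(x) < 2 * fs) stop_data("EDA input must cover at least 2 s")
  aa <- design_butterworth_lp(order = 8L, fc = 8, fs = fs)
  # remove the tonic offset before filtering: the filter starts from zero
  # state, and a 5-uS step at t = 0 would ring through the whole chain
  y <- apply_iir_df2(x - x[1L], aa, zero_phase = TRUE) + x[1L]
  dec <- as.integer(fs / 20)
  x20 <- y[seq(1L, length(y), by = dec)]
  fs20 <- 20
  d <- c(0, diff(x20)) * fs20
  w <- bartlett_window(20L)
  w <- w / sum(w)
  scr <- conv_same(d, w)
  out <- tibble(time_s = (seq_along(scr) - 1L) / fs20, scr_us_per_s = scr)
  class(out) <- c("biopad_scr", class(out))
  attr(out, "fs") <- fs20
  out
}

# triangular (Bartlett) window with zero end points
bartlett_window <- function(n) {
  k <- 0:(n - 1L)
  1 - abs((k - (n - 1) / 2) / ((n - 1) / 2))
}

# centered same-length linear convolution
conv_same <- function(x, w) {
  n <- length(x); m <- length(w)
  full <- stats::convolve(x, rev(w), type = "open")
  start <- floor((m - 1) / 2) + 1L
  full[start:(start + n - 1L)]
}

#' Detect stimulus-locked skin-conductance responses
#'
#' Flags intervals where the phasic SCR signal exceeds `k` scaled median
#' absolute deviations above the baseline median for at least `min_dur_s`,
#' and matches each onset to the latest stimulus at most `max_latency_s`
#' earlier. Responses typically begin 1-5 s after their stimulus.
#'
#' @param scr a `biopad_scr` tibble from [extract_scr()].
#' @param stimuli stimulus onset times in seconds (may be empty).
#' @param k MAD multiplier above the baseline median (default 4).
#' @param min_dur_s minimum suprathreshold duration in seconds (default
#'   0.25).
#' @param max_latency_s maximum onset-to-stimulus lookback in seconds
#'   (default 10).
#' @return A tibble with one row per event: `onset_s`, `peak_s`,
#'   `amplitude` (peak above baseline, uS/s), `stimulus_time_s`,
#'   `latency_s` (`NA` when no stimulus precedes the onset within the
#'   lookback).
#' @export
detect_scr_events <- function(scr, stimuli = numeric(), k = 4,
                              min_dur_s = 0.25, max_latency_s = 10) {
  if (!inherits(scr, "biopad_scr")) stop_data("`scr` must come from extract_scr()")
  fs <- attr(scr, "fs") %||% 20
  v <- scr$scr_us_per_s
  base <- median(v)
  thr <- base + k * mad(v)
  empty <- tibble(onset_s = numeric(), peak_s = numeric(), amplitude = numeric(),
                  stimulus_time_s = numeric(), latency_s = numeric())
  above <- v > thr & (thr > base)
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= max(1L, round(min_dur_s * fs)))
  if (!length(keep)) return(empty)
  events <- purrr::map_dfr(keep, function(i) {
    idx <- starts[i]:ends[i]
    peak <- idx[which.max(v[idx])]
    tibble(onset_s = scr$time_s[starts[i]],
           peak_s = scr$time_s[peak],
           amplitude = v[peak] - base)
  })
  match_stim <- vapply(events$onset_s, function(t0) {
    prior <- stimuli[stimuli <= t0 & stimuli >= t0 - max_latency_s]
    if (length(prior)) max(prior) else NA_real_
  }, numeric(1))
  events$stimulus_time_s <- match_stim
  events$latency_s <- events$onset_s - match_stim
  events
}
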