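#' Recursive (IIR) filter specification
#'
#' Holds the rational transfer function `H(z) = B(z^-1) / A(z^-1)` with
#' feed-forward coefficients `b`, recursive coefficients `a` (normalized so
#' `a[1] = 1`) and the sampling rate. Stability (all poles strictly inside
#' the unit circle) is checked at construction.
#'
#' @param b feed-forward coefficients.
#' @param a recursive coefficients, `a[1] != 0`.
#' @param fs sampling rate in Hz (> 0).
#' @param design optional named list describing how the filter was designed
#'   (kept for YAML serialization).
#' @return An object of class `iir_spec`.
#' @export
iir_spec <- function(b, a, fs, design = list()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop_config("`fs` must be > 0")
  check_finite(b, "b"); check_finite(a, "a")
  if (a[1L] == 0) stop_config("`a[1]` must be non-zero")
  b <- b / a[1L]; a <- a / a[1L]
  if (length(a) > 1L) {
    poles <- polyroot(rev(a))
    if (any(Mod(poles) >= 1 - 1e-12)) {
      stop_config("unstable filter: pole magnitude(s) up to %.6f", max(Mod(poles)))
    }
  }
  structure(list(b = as.numeric(b), a = as.numeric(a), fs = fs, design = design),
            class = "iir_spec")
}

#' @export
print.iir_spec <- function(x, ...) {
  kind <- x$design$kind %||% "custom"
  cat(sprintf("<iir_spec> %s, order %d/%d, fs = %g Hz\n",
              kind, length(x$b) - 1L, length(x$a) - 1L, x$fs))
  invisible(x)
}

#' Design the mains-rejection IIR comb filter
#'
#' Realizes the difference equation
#' `y(n) = ((1 + rh0)/2) * (x(n) - x(n - N)) + rh0 * y(n - N)`,
#' which places zeros (notches) at every multiple of `fs / N` including DC,
#' each flanked by a pole at radius `rh0^(1/N)` that keeps the inter-notch
#' response at unity. With `N = 8` at 400 Hz the notches fall on 0, 50, 100,
#' 150 and 200 Hz, rejecting 50-Hz mains and its harmonics.
#'
#' @param n_order comb delay in samples (`N >= 1`).
#' @param rh0 comb coefficient in (0, 1); the device's design value is
#'   `0.96852105385218623`.
#' @param fs sampling rate in Hz.
#' @return An [iir_spec].
#' @export
design_comb <- function(n_order = 8L, rh0 = 0.96852105385218623, fs = 400) {
  if (n_order < 1L || n_order != round(n_order)) stop_config("`n_order` must be a positive integer")
  if (rh0 <= 0 || rh0 >= 1) stop_config("`rh0` must lie in (0, 1) for stability")
  g <- (1 + rh0) / 2
  b <- c(g, rep(0, n_order - 1L), -g)
  a <- c(1, rep(0, n_order - 1L), -rh0)
  iir_spec(b, a, fs, design = list(kind = "comb", n_order = as.integer(n_order), rh0 = rh0))
}

#' Design a direct-form-II Butterworth low-pass
#'
#' Standard bilinear-transform Butterworth design (delegated to
#' [signal::butter()]); magnitude is monotone with -3.01 dB at the corner.
#' The EEG display chain uses order 2 at 30 Hz.
#'
#' @param order filter order (>= 1).
#' @param fc cutoff frequency in Hz, `0 < fc < fs/2`.
#' @param fs sampling rate in Hz.
#' @return An [iir_spec].
#' @export
design_butterworth_lp <- function(order = 2L, fc = 30, fs = 400) {
  if (fc <= 0 || fc >= fs / 2) stop_config("`fc` must lie in (0, fs/2)")
  ba <- signal::butter(order, fc / (fs / 2), type = "low")
  iir_spec(ba$b, ba$a, fs,
           design = list(kind = "butterworth_lp", order = as.integer(order), fc = fc))
}

# channel-specific low-pass corners: EDA mirrors the 5-Hz analog stage,
# PPG keeps cardiac content to the 3rd harmonic, SKT is quasi-static
peripheral_cutoffs_hz <- c(EDA = 5, PPG = 8, SKT = 1)

#' Design the low-pass filter for a peripheral channel
#'
#' Order-2 Butterworth at channel-specific default corners (EDA 5 Hz,
#' PPG 8 Hz, SKT 1 Hz) at the 100-Hz peripheral rate.
#'
#' @param channel one of `"EDA"`, `"SKT"`, `"PPG"`.
#' @param fs sampling rate in Hz.
#' @param fc optional cutoff override in Hz.
#' @return An [iir_spec].
#' @export
design_peripheral_lp <- function(channel, fs = 100, fc = NULL) {
  if (length(channel) != 1L || !channel %in% names(peripheral_cutoffs_hz)) {
    stop_config("unknown peripheral channel `%s` (expected EDA, SKT or PPG)",
                paste(channel, collapse = ","))
  }
  design_butterworth_lp(order = 2L, fc = fc %||% peripheral_cutoffs_hz[[channel]], fs = fs)
}

#' Apply an IIR filter in direct form II
#'
#' Runs the two-stage direct-form-II recursion with zero initial state:
#' `w(n) = x(n) - sum_i a_i w(n - i)` followed by
#' `y(n) = sum_j b_j w(n - j)`. By default the filter runs causally (as in
#' streaming display use, so transients and group delay are those of a
#' real-time chain); `zero_phase = TRUE` applies it forward and backward
#' for offline analysis, squaring the magnitude response and cancelling
#' phase.
#'
#' @param x numeric sample vector (finite).
#' @param spec an [iir_spec].
#' @param zero_phase logical; forward-backward filtering if `TRUE`.
#' @return Filtered samples, same length as `x`.
#' @export
apply_iir_df2 <- function(x, spec, zero_phase = FALSE) {
  if (!inherits(spec, "iir_spec")) stop_config("`spec` must be an iir_spec")
  check_finite(x, "x")
  if (zero_phase) {
    y <- apply_iir_df2(x, spec)
    y <- apply_iir_df2(rev(y), spec)
    return(rev(y))
  }
  n <- length(x)
  if (n == 0L) return(numeric())
  a <- spec$a; b <- spec$b
  w <- if (length(a) > 1L) {
    as.numeric(stats::filter(x, -a[-1L], method = "recursive"))
  } else {
    x
  }
  nb <- length(b)
  if (nb == 1L) return(b * w)
  wpad <- c(rep(0, nb - 1L), w)
  y <- as.numeric(stats::filter(wpad, b, method = "convolution", sides = 1L))
  y[nb:(nb + n - 1L)]
}

#' Evaluate a filter's frequency response on a grid
#'
#' Exact rational-transfer-function evaluation
#' `H(f) = B(e^{-i 2 pi f / fs}) / A(e^{-i 2 pi f / fs})`.
#'
#' @param spec an [iir_spec].
#' @param freqs frequency grid in Hz within `[0, fs/2]`.
#' @return A tibble of class `biopad_freqresp` with `freq_hz`, `magnitude`,
#'   `magnitude_db`, `phase_rad`.
#' @export
frequency_response <- function(spec, freqs) {
  if (!inherits(spec, "iir_spec")) stop_config("`spec` must be an iir_spec")
  if (any(freqs < 0 | freqs > spec$fs / 2)) {
    stop_data("`freqs` must lie within [0, fs/2]")
  }
  h <- vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / spec$fs)
    hb <- sum(spec$b * z^(seq_along(spec$b) - 1L))
    ha <- sum(spec$a * z^(seq_along(spec$a) - 1L))
    hb / ha
  }, complex(1))
  out <- tibble(
    freq_hz = freqs,
    magnitude = Mod(h),
    magnitude_db = 20 * log10(Mod(h)),
    phase_rad = Arg(h)
  )
  class(out) <- c("biopad_freqresp", class(out))
  attr(out, "fs") <- spec$fs
  out
}

#' Attenuation of a filter near a notch frequency, display-grid convention
#'
#' At an exact comb notch the analytic response is zero (infinite
#' attenuation in dB); plotted responses read a finite depth off a finite
#' frequency grid. This helper evaluates the response on an `n_grid`-point
#' inclusive grid over `[0, fs/2]` and reports the attenuation at the grid
#' point nearest `f0`.
#'
#' @param spec an [iir_spec].
#' @param f0 target frequency in Hz.
#' @param n_grid grid resolution (default 8192).
#' @return Attenuation in dB (positive numbers = loss).
#' @export
notch_attenuation_db <- function(spec, f0, n_grid = 8192L) {
  grid <- seq(0, spec$fs / 2, length.out = n_grid)
  f <- grid[which.min(abs(grid - f0))]
  -frequency_response(spec, f)$magnitude_db
}

#' @export
autoplot.biopad_freqresp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude (dB)")
}

#' Serialize a filter specification to / from YAML
#'
#' @param spec an [iir_spec].
#' @param path file path.
#' @return `write_iir_yaml()` returns `path` invisibly; `read_iir_yaml()`
#'   returns the reconstructed [iir_spec].
#' @export
write_iir_yaml <- function(spec, path) {
  if (!inherits(spec, "iir_spec")) stop_config("`spec` must be an iir_spec")
  yaml::write_yaml(list(b = spec$b, a = spec$a, fs = spec$fs, design = spec$design),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_iir_yaml
#' @export
read_iir_yaml <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  obj <- yaml::read_yaml(path)
  iir_spec(obj$b, obj$a, obj$fs, design = obj$design %||% list())
}
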