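#' Analog-front-end constants
#'
#' Default component values and conversion constants of the acquisition
#' front end, as a named list suitable for YAML round-tripping. Fields:
#' `rg_ohm` (instrumentation-amplifier gain resistor), `vref_v` (ADC
#' reference, 2.5 V), `pga` (ADC programmable gain), `hp_cutoff_hz` (DC
#' correction loop corner, 0.5 Hz), `lp_cutoff_hz` (analog anti-alias
#' corner, 35 Hz), `lp_gain` (post-filter gain, 2), `sallen_key_r_ohm` /
#' `sallen_key_c_f` (EDA low-pass components), `skt_slope_c_per_mv`,
#' `skt_intercept_c`, `adc_span_v` (peripheral ADC input span, 3.3 V).
#'
#' @param ... named overrides of any default field.
#' @return A named list.
#' @export
afe_constants <- function(...) {
  defaults <- list(
    rg_ohm            = 200,
    ia_num_ohm        = 19800,
    vref_v            = 2.5,
    pga               = 1,
    hp_cutoff_hz      = 0.5,
    ia_gain           = 100,
    lp_cutoff_hz      = 35,
    lp_gain           = 2,
    sallen_key_r_ohm  = 300e3,
    sallen_key_c_f    = 0.1e-6,
    skt_slope_c_per_mv = 0.1943,
    skt_intercept_c   = 213.340,
    adc_span_v        = 3.3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop_config("unknown AFE constant(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(defaults, dots)
}

#' Instrumentation-amplifier gain from the gain-set resistor
#'
#' `G = 1 + 19.8 kOhm / Rg`. With the device's 200-ohm resistor the gain
#' is 100.
#'
#' @param rg_ohm gain-set resistance in ohms (> 0).
#' @return Dimensionless gain.
#' @export
ia_gain <- function(rg_ohm) {
  if (!is.numeric(rg_ohm) || any(rg_ohm <= 0)) stop_data("`rg_ohm` must be > 0")
  1 + 19800 / rg_ohm
}

#' Common-mode rejection ratio at a given gain
#'
#' `CMRR = 80 dB + 20 log10(G)`; 120 dB at the device's gain of 100.
#'
#' @param gain dimensionless amplifier gain (>= 1).
#' @return CMRR in dB.
#' @export
cmrr_db <- function(gain) {
  if (!is.numeric(gain) || any(gain < 1)) stop_data("`gain` must be >= 1")
  80 + 20 * log10(gain)
}

#' Complex frequency response of the EEG analog front end
#'
#' Cascade model of the conditioning chain: the integral-feedback DC
#' correction loop acts as a first-order high-pass at 0.5 Hz (fully
#' rejecting electrode polarization DC), followed by the 100x amplifier,
#' a second-order Butterworth low-pass at 35 Hz, and the filter stage's 2x
#' gain — a passband plateau of about 200x between 0.5 and 35 Hz.
#'
#' @param f frequency in Hz (>= 0), vectorized.
#' @param const AFE constants, see [afe_constants()].
#' @return Complex gain, same length as `f`.
#' @export
afe_frequency_response <- function(f, const = afe_constants()) {
  if (!is.numeric(f) || any(f < 0)) stop_data("`f` must be >= 0")
  s_hp <- 1i * f / const$hp_cutoff_hz
  hp <- s_hp / (1 + s_hp)
  s_lp <- 1i * f / const$lp_cutoff_hz
  lp <- 1 / (1 + sqrt(2) * s_lp + s_lp^2)   # Butterworth 2nd order
  hp * const$ia_gain * lp * const$lp_gain
}

#' Convert a 24-bit bipolar sigma-delta ADC code to volts
#'
#' `V = (2 * VREF / (2^23 - 1)) * L / PGA` with `VREF = 2.5` V: full positive
#' code at unity PGA reads 5 V differential.
#'
#' @param code signed 24-bit ADC code(s), in `[-2^23, 2^23 - 1]`.
#' @param pga programmable gain (>= 1).
#' @param const AFE constants.
#' @return Volts.
#' @export
adc_to_volts <- function(code, pga = 1, const = afe_constants()) {
  if (any(code < -8388608 | code > 8388607)) stop_data("ADC code out of 24-bit range")
  if (any(pga < 1)) stop_data("`pga` must be >= 1")
  (2 * const$vref_v / (2^23 - 1)) * code / pga
}

#' @rdname adc_to_volts
#' @param volts voltage(s) to quantize back to the nearest ADC code.
#' @export
volts_to_adc <- function(volts, pga = 1, const = afe_constants()) {
  code <- round(volts * pga * (2^23 - 1) / (2 * const$vref_v))
  pmin(pmax(code, -8388608), 8388607)
}

#' Cutoff frequency of an equal-component Sallen-Key low-pass
#'
#' `fp = 1 / (2 pi R C)`; with the EDA stage's 300 kOhm / 0.1 uF this is
#' approximately 5.3 Hz.
#'
#' @param r_ohm resistance in ohms (> 0).
#' @param c_f capacitance in farads (> 0).
#' @return Cutoff in Hz.
#' @export
sallen_key_cutoff <- function(r_ohm, c_f) {
  if (any(r_ohm <= 0) || any(c_f <= 0)) stop_data("R and C must be > 0")
  1 / (2 * pi * r_ohm * c_f)
}

#' Convert the EDA front-end output voltage to skin conductance
#'
#' The divider/feedback algebra of the EDA stage gives conductance
#' `rho = 16.5 / (8 U - 3.3)` microsiemens in the default `consistent`
#' mode, which lands typical skin in the physiological 1-25 uS range over
#' the stage's 0.4-2.4 V output span. The `as_printed` mode retains the
#' additional 10^3 factor of the source formula verbatim.
#'
#' @param ueda_v front-end output voltage(s); must satisfy `8 U - 3.3 > 0`.
#' @param mode `"consistent"` (default) or `"as_printed"`.
#' @return Conductance in microsiemens.
#' @export
eda_volts_to_microsiemens <- function(ueda_v, mode = c("consistent", "as_printed")) {
  mode <- match.arg(mode)
  den <- 8 * ueda_v - 3.3
  if (any(den <= 0)) stop_data("EDA voltage out of valid range (requires 8*U - 3.3 > 0)")
  rho <- 16.5 / den
  if (mode == "as_printed") rho <- rho * 1e3
  rho
}

#' @rdname eda_volts_to_microsiemens
#' @param rho_us conductance(s) in microsiemens (> 0).
#' @export
eda_microsiemens_to_volts <- function(rho_us, mode = c("consistent", "as_printed")) {
  mode <- match.arg(mode)
  if (any(rho_us <= 0)) stop_data("conductance must be > 0")
  if (mode == "as_printed") rho_us <- rho_us / 1e3
  (16.5 / rho_us + 3.3) / 8
}

#' Measurement current through the skin in the EDA stage
#'
#' Derived safety diagnostic: `I = (3.3 / 16) / R3` with the divider ratio
#' implied by the conductance algebra. The design keeps this below the
#' 10-uA skin-safety limit.
#'
#' @param r3_ohm feedback resistance in ohms (> 0).
#' @return Current in amperes.
#' @export
eda_safety_current <- function(r3_ohm) {
  if (any(r3_ohm <= 0)) stop_data("`r3_ohm` must be > 0")
  (3.3 / 16) / r3_ohm
}

#' Convert the temperature sensor output voltage to degrees Celsius
#'
#' Affine sensor law `T = m * V + b` with `|m| = 0.1943` degC/mV and
#' `b = 213.340` degC, calibrated over the 30-40 degC forehead range.
#' The sensor's output falls as temperature rises, so the default slope
#' sign is negative; `"as_printed_positive"` applies the positive slope
#' verbatim.
#'
#' @param vtao_mv sensor output in millivolts.
#' @param slope_sign `"negative"` (default) or `"as_printed_positive"`.
#' @param const AFE constants.
#' @return Temperature in degrees Celsius.
#' @export
skt_millivolts_to_celsius <- function(vtao_mv,
                                      slope_sign = c("negative", "as_printed_positive"),
                                      const = afe_constants()) {
  slope_sign <- match.arg(slope_sign)
  m <- const$skt_slope_c_per_mv
  if (slope_sign == "negative") m <- -m
  m * vtao_mv + const$skt_intercept_c
}

#' @rdname skt_millivolts_to_celsius
#' @param temp_c temperature(s) in degrees Celsius.
#' @export
skt_celsius_to_millivolts <- function(temp_c,
                                      slope_sign = c("negative", "as_printed_positive"),
                                      const = afe_constants()) {
  slope_sign <- match.arg(slope_sign)
  m <- const$skt_slope_c_per_mv
  if (slope_sign == "negative") m <- -m
  (temp_c - const$skt_intercept_c) / m
}

# ---- codec quantization scales ---------------------------------------------

#' Quantization scales between physical units and wire-field codes
#'
#' Maps each channel's physical units onto its wire-field code range so that
#' nominal physiological spans occupy most of the code space: EEG microvolts
#' through the 200x analog gain onto the signed 24-bit ADC; EDA and SKT
#' through their front-end voltage laws onto 16 bits over the 0-3.3 V ADC
#' span; PPG dimensionless units (nominal +/- 8, covering pulse plus
#' motion artifact) onto 8 bits around
#' mid-code; acceleration +/- 2 g onto the signed 8-bit field.
#'
#' @param eda_mode EDA conversion mode, see [eda_volts_to_microsiemens()].
#' @param skt_slope SKT slope sign, see [skt_millivolts_to_celsius()].
#' @param const AFE constants.
#' @return A named list consumed by [record_to_packets()] and
#'   [frames_to_record()].
#' @export
codec_scales <- function(eda_mode = c("consistent", "as_printed"),
                         skt_slope = c("negative", "as_printed_positive"),
                         const = afe_constants()) {
  list(
    eda_mode  = match.arg(eda_mode),
    skt_slope = match.arg(skt_slope),
    const     = const,
    eeg_gain  = const$ia_gain * const$lp_gain,  # analog gain between scalp and ADC
    ppg_span  = 16,                             # a.u. mapped onto 0..255
    accel_span_g = 2                            # +/- 2 g onto -127..127
  )
}

eeg_uv_to_code <- function(uv, scales = codec_scales()) {
  volts_to_adc(uv * 1e-6 * scales$eeg_gain, pga = scales$const$pga, const = scales$const)
}

eeg_code_to_uv <- function(code, scales = codec_scales()) {
  adc_to_volts(code, pga = scales$const$pga, const = scales$const) / scales$eeg_gain * 1e6
}

eda_us_to_code <- function(us, scales = codec_scales()) {
  v <- eda_microsiemens_to_volts(us, mode = scales$eda_mode)
  clip_code(round(v / scales$const$adc_span_v * 65535), 0, 65535)
}

eda_code_to_us <- function(code, scales = codec_scales()) {
  v <- code / 65535 * scales$const$adc_span_v
  # codes below the divider's physical floor (~0.4 V output) cannot arise
  # from a real front end; clamp so arbitrary streams still decode
  v <- pmax(v, 0.42)
  eda_volts_to_microsiemens(v, mode = scales$eda_mode)
}

skt_c_to_code <- function(temp_c, scales = codec_scales()) {
  mv <- skt_celsius_to_millivolts(temp_c, slope_sign = scales$skt_slope,
                                  const = scales$const)
  clip_code(round(mv / (scales$const$adc_span_v * 1000) * 65535), 0, 65535)
}

skt_code_to_c <- function(code, scales = codec_scales()) {
  mv <- code / 65535 * scales$const$adc_span_v * 1000
  skt_millivolts_to_celsius(mv, slope_sign = scales$skt_slope, const = scales$const)
}

ppg_au_to_code <- function(x, scales = codec_scales()) {
  clip_code(round((x / scales$ppg_span + 0.5) * 255), 0, 255)
}

ppg_code_to_au <- function(code, scales = codec_scales()) {
  (code / 255 - 0.5) * scales$ppg_span
}

accel_g_to_code <- function(g, scales = codec_scales()) {
  clip_code(round(g / scales$accel_span_g * 127), -127, 127)
}

accel_code_to_g <- function(code, scales = codec_scales()) {
  code / 127 * scales$accel_span_g
}

clip_code <- function(code, lo, hi) {
  n_clip <- sum(code < lo | code > hi)
  if (n_clip > 0L) {
    warn(sprintf("%d sample(s) clipped to the field code range", n_clip),
         class = "biopad_clip_warning")
  }
  pmin(pmax(code, lo), hi)
}
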