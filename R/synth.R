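# run code under a temporary RNG state so generators are pure in (cfg, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-session configuration
#'
#' Returns the default configuration of the seeded session generator as a
#' plain nested list (YAML round-trippable). The default paradigm mirrors
#' the skin-temperature stimulation protocol: 20 s baseline, 60 s
#' stimulation, 90 s recovery (170 s total), with three stimulus events
#' during the scene.
#'
#' Defaults represent ordinary desk-scale recording conditions: 10-50 uV
#' EEG with a 10-Hz alpha rhythm (20 uV eyes closed, 2 uV open), ~100 uV
#' blink transients, 10 uV of 50-Hz mains pickup; a 5-uS tonic skin
#' conductance with 0.5-uS responses rising in 0.75 s and decaying in 3 s;
#' a 34 degC forehead baseline dropping 0.2 degC under unpleasant
#' stimulation; a 72-BPM pulse with harmonic amplitudes (1.0, 0.4, 0.15)
#' and accelerometer-coupled motion artifact.
#'
#' @param duration_s session length in seconds.
#' @param seed default RNG seed carried in the config.
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged shallowly per top-level section).
#' @return A named list of class `session_config`.
#' @export
session_config <- function(duration_s = 170, seed = 1L, ...) {
  # the 20/60/90-s protocol needs at least 80 s; shorter sessions default
  # to a single unlabelled window and stimulus-free traces
  long_enough <- duration_s >= 80
  default_paradigm <- if (long_enough) {
    c(list(
      list(label = "baseline", start_s = 0, end_s = 20),
      list(label = "stimulus", start_s = 20, end_s = 80)
    ), if (duration_s > 80) list(list(label = "rest", start_s = 80, end_s = duration_s)))
  } else {
    list(list(label = "rest", start_s = 0, end_s = duration_s))
  }
  default_events <- if (long_enough) {
    lapply(c(30, 50, 70), function(s0) {
      list(stimulus_s = s0, latency_s = 2, amplitude_us = 0.5,
           rise_s = 0.75, decay_s = 3)
    })
  } else {
    list()
  }
  default_drop <- if (long_enough) c(20, 80) else c(0.25, 0.75) * duration_s
  default_bursts <- if (long_enough) {
    list(
      list(start_s = 30, dur_s = 10, rms_g = 0.3, freq_hz = 2.2, freq_end_hz = 1.4),
      list(start_s = 60, dur_s = 10, rms_g = 0.3, freq_hz = 1.0, freq_end_hz = 1.8)
    )
  } else {
    list()
  }
  cfg <- list(
    duration_s = duration_s,
    seed = as.integer(seed),
    paradigm = default_paradigm,
    eeg = list(
      alpha_freq_hz = 10,
      alpha_amp_closed_uv = 20,
      alpha_amp_open_uv = 2,
      schedule = list(list(start_s = 0, end_s = duration_s, state = "open")),
      blink_rate_per_min = 10,
      blink_amp_uv = 100,
      mains_amp_uv = 10,
      noise_uv = 10
    ),
    eda = list(
      tonic_us = 5,
      drift_us = 0.2,
      noise_us = 0.02,
      scr_events = default_events
    ),
    skt = list(
      baseline_c = 34,
      stim_drop_c = 0.2,
      drop_window = default_drop,
      recovery_rise_c = 0.1,
      noise_c = 0.01
    ),
    ppg = list(
      pr_profile = list(time_s = c(0, duration_s), bpm = c(72, 72)),
      harmonic_amps = c(1.0, 0.4, 0.15),
      wander_amp = 0.3,
      wander_freq_hz = 0.1,
      noise = 0.05,
      artifact_gain = 6,
      artifact_taps = 5L
    ),
    accel = list(
      motion_bursts = default_bursts,
      base_noise_g = 0.005
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop_config("unknown config section(s): %s", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    # two-level merge: named fields inside a section are replaced wholesale
    # (no deeper recursion — schedules and event lists are atomic values)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && !is.null(names(dots[[nm]]))) {
      bad_f <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad_f)) {
        stop_config("unknown field(s) in `%s`: %s", nm, paste(bad_f, collapse = ", "))
      }
      for (f in names(dots[[nm]])) cfg[[nm]][[f]] <- dots[[nm]][[f]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_session_config(cfg)
  structure(cfg, class = c("session_config", "list"))
}

#' Preset configuration of the six-minute multi-scene session
#'
#' Four 60-s emotion scenes separated by 30-s rests after a 30-s lead-in
#' (360 s total); the pulse rate sweeps between 60 and 100 BPM across the
#' scenes and motion bursts fall inside each scene.
#'
#' @param seed RNG seed carried in the config.
#' @return A `session_config`.
#' @export
config_ppg_session <- function(seed = 1L) {
  scenes <- lapply(0:3, function(k) {
    list(label = paste0("scene", k + 1L), start_s = 30 + k * 90, end_s = 90 + k * 90)
  })
  rests <- lapply(0:3, function(k) {
    list(label = "rest", start_s = k * 90, end_s = k * 90 + 30)
  })
  paradigm <- c(rests[1], scenes[1], rests[2], scenes[2], rests[3], scenes[3],
                rests[4], scenes[4])
  session_config(
    duration_s = 360, seed = seed,
    paradigm = paradigm,
    ppg = list(pr_profile = list(
      time_s = c(0, 30, 90, 120, 180, 210, 270, 300, 360),
      bpm    = c(65, 65, 95, 70, 100, 68, 90, 62, 60)
    )),
    accel = list(motion_bursts = lapply(0:3, function(k) {
      list(start_s = 40 + k * 90, dur_s = 20, rms_g = 0.3,
           freq_hz = c(0.9, 1.0, 2.4, 0.8)[k + 1L],
           freq_end_hz = c(1.9, 2.0, 1.1, 1.6)[k + 1L])
    })),
    eda = list(scr_events = lapply(0:3, function(k) {
      list(stimulus_s = 45 + k * 90, latency_s = 2, amplitude_us = 0.5,
           rise_s = 0.75, decay_s = 3)
    })),
    skt = list(drop_window = c(210, 270))
  )
}

validate_session_config <- function(cfg) {
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0) {
    stop_config("`duration_s` must be > 0")
  }
  dur <- cfg$duration_s
  for (w in cfg$paradigm) {
    if (w$start_s < 0 || w$end_s > dur + 1e-9 || w$start_s >= w$end_s) {
      stop_config("paradigm window `%s` outside the session", w$label %||% "?")
    }
  }
  for (s in cfg$eeg$schedule) {
    if (s$start_s < 0 || s$end_s > dur + 1e-9) stop_config("EEG schedule outside the session")
    if (!s$state %in% c("open", "closed")) stop_config("EEG schedule state must be open/closed")
  }
  for (ev in cfg$eda$scr_events) {
    if (ev$amplitude_us < 0) stop_config("SCR amplitudes must be >= 0")
    if (ev$stimulus_s + ev$latency_s > dur) stop_config("SCR event beyond the session")
  }
  if (any(unlist(cfg$ppg$harmonic_amps) < 0)) stop_config("harmonic amplitudes must be >= 0")
  for (b in cfg$accel$motion_bursts) {
    if (b$start_s < 0 || b$start_s + b$dur_s > dur + 1e-9) {
      stop_config("motion burst outside the session")
    }
  }
  invisible(cfg)
}

#' Read / write a session configuration as YAML
#'
#' @param path file path.
#' @param cfg a `session_config`.
#' @return `read_session_config()` returns a validated `session_config`;
#'   `write_session_config()` returns `path` invisibly.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: %s", path)
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config("malformed YAML config: %s", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$duration_s)) stop_config("config must define `duration_s`")
  base <- session_config(duration_s = obj$duration_s, seed = obj$seed %||% 1L)
  for (nm in intersect(names(obj), names(base))) base[[nm]] <- obj[[nm]]
  validate_session_config(base)
  structure(base, class = c("session_config", "list"))
}

#' @rdname read_session_config
#' @export
write_session_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

# pink (1/f) noise: white noise shaped by the standard 3-pole pinking filter,
# rescaled to unit RMS
pink_noise <- function(n) {
  w <- rnorm(n + 400L)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  p <- apply_iir_df2(w, iir_spec(b, a, fs = 1), zero_phase = FALSE)
  p <- p[-(1:400)]  # drop filter warm-up
  p / sd(p)
}

# piecewise-constant value over time from a window schedule
schedule_value <- function(t, schedule, value_of, default = 0) {
  v <- rep(default, length(t))
  for (s in schedule) {
    v[t >= s$start_s & t < s$end_s] <- value_of(s)
  }
  v
}

#' Generate two-channel synthetic EEG at 400 Hz
#'
#' Pink background noise plus a 10-Hz alpha oscillation (slow frequency
#' jitter) whose amplitude follows the eyes-open/closed schedule, biphasic
#' 300-ms blink transients at the configured rate, and a 50-Hz mains
#' sinusoid. Deterministic per `(cfg, seed)`.
#'
#' @param cfg a [session_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param fs sampling rate in Hz.
#' @return A list with `eeg` (n x 2 matrix, uV), `blink_times_s`, `fs`.
#' @export
gen_eeg <- function(cfg, seed = cfg$seed, fs = 400) {
  with_seed(seed + 101L, {
    n <- round(cfg$duration_s * fs)
    t <- (0:(n - 1L)) / fs
    e <- cfg$eeg
    amp <- schedule_value(t, e$schedule, function(s) {
      if (s$state == "closed") e$alpha_amp_closed_uv else e$alpha_amp_open_uv
    }, default = e$alpha_amp_open_uv)
    # alpha with a slowly wandering instantaneous frequency (+/- ~0.4 Hz)
    f_inst <- e$alpha_freq_hz +
      0.4 * sin(2 * pi * 0.07 * t + runif(1, 0, 2 * pi)) +
      0.15 * sin(2 * pi * 0.23 * t + runif(1, 0, 2 * pi))
    phase <- cumsum(2 * pi * f_inst / fs)
    alpha <- amp * sin(phase)
    mains <- e$mains_amp_uv * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    blink_times <- numeric(0)
    if (e$blink_rate_per_min > 0) {
      gaps <- stats::rexp(ceiling(cfg$duration_s / 60 * e$blink_rate_per_min * 3) + 5L,
                          rate = e$blink_rate_per_min / 60)
      gaps <- pmax(gaps, 1)  # physiological refractory
      times <- cumsum(gaps)
      blink_times <- times[times < cfg$duration_s - 0.45]
    }
    blink_sig <- numeric(n)
    if (length(blink_times)) {
      # asymmetric biphasic deflection ~300 ms wide: dominant positive lobe
      # peaking 100 ms after onset, smaller negative rebound
      kt <- seq(0, 0.35, by = 1 / fs)
      kernel <- exp(-((kt - 0.1) / 0.04)^2 / 2) - 0.35 * exp(-((kt - 0.22) / 0.05)^2 / 2)
      kernel <- kernel / max(abs(kernel)) * e$blink_amp_uv
      for (bt in blink_times) {
        i0 <- round(bt * fs) + 1L
        idx <- i0:(i0 + length(kernel) - 1L)
        ok <- idx <= n
        blink_sig[idx[ok]] <- blink_sig[idx[ok]] + kernel[ok]
      }
      blink_times <- blink_times + 0.1  # truth marks the peak
    }
    ch1 <- alpha + blink_sig + mains + e$noise_uv * pink_noise(n)
    ch2 <- 0.9 * alpha + blink_sig + mains + e$noise_uv * pink_noise(n)
    list(eeg = cbind(ch1, ch2), blink_times_s = blink_times, fs = fs)
  })
}

# unit-peak bi-exponential response kernel
scr_kernel <- function(t, rise_s, decay_s) {
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

#' Generate a synthetic EDA stream at 100 Hz
#'
#' Tonic conductance with slow drift, bi-exponential skin-conductance
#' responses at the configured stimulus-locked times (superposed when they
#' overlap), and measurement noise.
#'
#' @inheritParams gen_eeg
#' @param fs sampling rate in Hz.
#' @return A list with `eda` (uS), `scr_onsets_s`, `stimulus_times_s`,
#'   `fs`.
#' @export
gen_eda <- function(cfg, seed = cfg$seed, fs = 100) {
  with_seed(seed + 202L, {
    n <- round(cfg$duration_s * fs)
    t <- (0:(n - 1L)) / fs
    e <- cfg$eda
    drift <- e$drift_us * sin(2 * pi * t / max(60, cfg$duration_s) + runif(1, 0, 2 * pi))
    x <- e$tonic_us + drift
    onsets <- numeric(0); stimuli <- numeric(0)
    for (ev in e$scr_events) {
      onset <- ev$stimulus_s + ev$latency_s
      onsets <- c(onsets, onset)
      stimuli <- c(stimuli, ev$stimulus_s)
      idx <- t >= onset
      x[idx] <- x[idx] + ev$amplitude_us *
        scr_kernel(t[idx] - onset, ev$rise_s, ev$decay_s)
    }
    x <- x + e$noise_us * rnorm(n)
    list(eda = x, scr_onsets_s = onsets, stimulus_times_s = stimuli, fs = fs)
  })
}

#' Generate a synthetic skin-temperature stream at 100 Hz
#'
#' Stable baseline, a linear decline of `stim_drop_c` across the configured
#' drop window (the unpleasant-stimulus response), exponential recovery
#' toward baseline afterwards, plus sensor noise.
#'
#' @inheritParams gen_eeg
#' @param fs sampling rate in Hz.
#' @return A list with `skt` (degC), `skt_delta_c` (configured drop, signed),
#'   `fs`.
#' @export
gen_skt <- function(cfg, seed = cfg$seed, fs = 100) {
  with_seed(seed + 303L, {
    n <- round(cfg$duration_s * fs)
    t <- (0:(n - 1L)) / fs
    s <- cfg$skt
    w <- s$drop_window
    x <- rep(s$baseline_c, n)
    during <- t >= w[1] & t < w[2]
    x[during] <- s$baseline_c - s$stim_drop_c * (t[during] - w[1]) / (w[2] - w[1])
    after <- t >= w[2]
    x[after] <- s$baseline_c - s$stim_drop_c * exp(-(t[after] - w[2]) / 60)
    x <- x + s$noise_c * rnorm(n)
    list(skt = x, skt_delta_c = -s$stim_drop_c, fs = fs)
  })
}

#' Generate synthetic PPG and accelerometer streams at 100 Hz
#'
#' The pulsatile waveform is a sum of harmonics at the instantaneous rate
#' integrated from the piecewise-linear pulse-rate profile, plus baseline
#' wander and noise; the accelerometer channels are band-limited noise
#' inside the configured motion bursts; the motion artifact is an
#' FIR-filtered mix of the acceleration channels added to both PPG
#' channels, scaled by `artifact_gain`.
#'
#' @inheritParams gen_eeg
#' @param fs sampling rate in Hz.
#' @return A list with `ppg` (n x 2 matrix: red, IR), `accel` (n x 3
#'   matrix, g), `pr_track_bpm` (instantaneous truth at `fs`), `fs`.
#' @export
gen_ppg_accel <- function(cfg, seed = cfg$seed, fs = 100) {
  with_seed(seed + 404L, {
    n <- round(cfg$duration_s * fs)
    t <- (0:(n - 1L)) / fs
    p <- cfg$ppg
    prof <- p$pr_profile
    pr <- approx(prof$time_s, prof$bpm, xout = t, rule = 2)$y
    phase <- cumsum(2 * pi * (pr / 60) / fs)
    h <- unlist(p$harmonic_amps)
    pulse <- Reduce(`+`, lapply(seq_along(h), function(k) h[k] * sin(k * phase)))
    wander <- p$wander_amp * sin(2 * pi * p$wander_freq_hz * t + runif(1, 0, 2 * pi))
    # motion bursts: rhythmic (head/body oscillation at freq_hz) with a
    # band-limited stochastic component, per-axis phases; plus sensor noise
    lp10 <- design_butterworth_lp(order = 2L, fc = 10, fs = fs)
    accel <- sapply(1:3, function(ax) {
      a <- cfg$accel$base_noise_g * rnorm(n)
      for (b in cfg$accel$motion_bursts) {
        idx <- which(t >= b$start_s & t < b$start_s + b$dur_s)
        if (!length(idx)) next
        f0 <- b$freq_hz %||% 2
        f1 <- b$freq_end_hz %||% f0
        fm <- seq(f0, f1, length.out = length(idx))  # slow cadence drift
        rhythmic <- sqrt(2) * sin(2 * pi * cumsum(fm) / fs + runif(1, 0, 2 * pi))
        bl <- apply_iir_df2(rnorm(length(idx)), lp10)
        bl <- bl / max(sd(bl), 1e-12)
        # taper the burst edges to avoid clicks
        ramp <- pmin(1, pmin(seq_along(idx), rev(seq_along(idx))) / fs)
        a[idx] <- a[idx] + b$rms_g * (0.9 * rhythmic + 0.45 * bl) * ramp
      }
      a
    })
    # unknown optical coupling path: a short FIR per axis, fixed per seed
    art <- numeric(n)
    for (ax in 1:3) {
      taps <- runif(p$artifact_taps, -1, 1)
      taps <- taps / sqrt(sum(taps^2))
      art <- art + as.numeric(stats::filter(c(rep(0, p$artifact_taps - 1L), accel[, ax]),
                                            taps, method = "convolution",
                                            sides = 1L))[p$artifact_taps:(p$artifact_taps + n - 1L)]
    }
    art <- art * p$artifact_gain
    red <- pulse + wander + art + p$noise * rnorm(n)
    ir <- 0.8 * pulse + wander + art + p$noise * rnorm(n)
    list(ppg = cbind(red, ir), accel = accel, pr_track_bpm = pr, fs = fs)
  })
}

#' Generate a complete synthetic session
#'
#' Runs all modality generators on a shared clock and assembles the
#' multirate record plus the ground-truth tracks used by the
#' parameter-recovery tests.
#'
#' @inheritParams gen_eeg
#' @return A list with `record` (a [multirate_record]) and `truth`, a list
#'   with `blink_times_s`, `scr_onsets_s`, `stimulus_times_s`,
#'   `skt_delta_c`, `pr_track` (tibble `time_s`, `bpm` at 100 Hz).
#' @export
gen_session <- function(cfg, seed = cfg$seed) {
  validate_session_config(cfg)
  eeg <- gen_eeg(cfg, seed)
  eda <- gen_eda(cfg, seed)
  skt <- gen_skt(cfg, seed)
  ppg <- gen_ppg_accel(cfg, seed)
  n_eeg <- nrow(eeg$eeg)
  n_per <- length(eda$eda)
  record <- multirate_record(
    eeg = tibble(
      time_s = (0:(n_eeg - 1L)) / eeg$fs,
      eeg1_uv = eeg$eeg[, 1L],
      eeg2_uv = eeg$eeg[, 2L]
    ),
    periph = tibble(
      time_s = (0:(n_per - 1L)) / eda$fs,
      eda_us = eda$eda,
      skt_c = skt$skt,
      ppg_red = ppg$ppg[, 1L],
      ppg_ir = ppg$ppg[, 2L],
      acc_x_g = ppg$accel[, 1L],
      acc_y_g = ppg$accel[, 2L],
      acc_z_g = ppg$accel[, 3L]
    ),
    fs_eeg = eeg$fs, fs_periph = eda$fs
  )
  truth <- list(
    blink_times_s = eeg$blink_times_s,
    scr_onsets_s = eda$scr_onsets_s,
    stimulus_times_s = eda$stimulus_times_s,
    skt_delta_c = skt$skt_delta_c,
    pr_track = tibble(time_s = (0:(n_per - 1L)) / ppg$fs, bpm = ppg$pr_track_bpm)
  )
  list(record = record, truth = truth)
}

#' Encode a multirate record into the framed byte stream
#'
#' Quantizes physical units back to wire-field ADC codes through the
#' inverse front-end conversions and frames them 50 ms at a time with
#' [encode_frame()]. Out-of-range values are clipped with a warning.
#'
#' @param record a [multirate_record]; channel lengths must divide into
#'   whole 50-ms frames unless `partial = "truncate"`.
#' @param scales quantization scales, see [codec_scales()].
#' @param partial `"error"` (default) or `"truncate"` for trailing samples
#'   that do not fill a frame.
#' @return A `raw` byte stream (168 bytes per frame, 20 frames per second).
#' @export
record_to_packets <- function(record, scales = codec_scales(),
                              partial = c("error", "truncate")) {
  partial <- match.arg(partial)
  fl <- frame_layout
  n_frames_eeg <- nrow(record$eeg) / fl$eeg_ticks
  n_frames_per <- nrow(record$periph) / fl$periph_ticks
  if (n_frames_eeg != floor(n_frames_eeg) || n_frames_per != floor(n_frames_per) ||
      n_frames_eeg != n_frames_per) {
    if (partial == "error") {
      stop_data("record length does not divide into whole 50-ms frames (EEG %.2f, peripheral %.2f)",
                n_frames_eeg, n_frames_per)
    }
  }
  n_frames <- floor(min(n_frames_eeg, n_frames_per))
  if (n_frames == 0L) return(raw(0))
  eeg1 <- eeg_uv_to_code(record$eeg$eeg1_uv, scales)
  eeg2 <- eeg_uv_to_code(record$eeg$eeg2_uv, scales)
  per <- list(
    eda = eda_us_to_code(record$periph$eda_us, scales),
    skt = skt_c_to_code(record$periph$skt_c, scales),
    ppg_red = ppg_au_to_code(record$periph$ppg_red, scales),
    ppg_ir = ppg_au_to_code(record$periph$ppg_ir, scales),
    acc_x = accel_g_to_code(record$periph$acc_x_g, scales),
    acc_y = accel_g_to_code(record$periph$acc_y_g, scales),
    acc_z = accel_g_to_code(record$periph$acc_z_g, scales)
  )
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ei <- ((f - 1L) * fl$eeg_ticks + 1L):(f * fl$eeg_ticks)
    pi_ <- ((f - 1L) * fl$periph_ticks + 1L):(f * fl$periph_ticks)
    frames[[f]] <- encode_frame(
      cbind(eeg1[ei], eeg2[ei]),
      lapply(per, `[`, pi_)
    )
  }
  do.call(c, frames)
}
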