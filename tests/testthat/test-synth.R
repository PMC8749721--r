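test_that("generators are pure functions of configuration and seed", {
  cfg <- session_config(duration_s = 20)
  expect_identical(gen_eeg(cfg, seed = 81)$eeg, gen_eeg(cfg, seed = 81)$eeg)
  expect_identical(gen_eda(cfg, seed = 81)$eda, gen_eda(cfg, seed = 81)$eda)
  expect_identical(gen_ppg_accel(cfg, seed = 81)$ppg, gen_ppg_accel(cfg, seed = 81)$ppg)
  expect_false(identical(gen_eeg(cfg, seed = 81)$eeg, gen_eeg(cfg, seed = 82)$eeg))
})

test_that("generated EEG reflects the eyes state schedule and blink settings", {
  cfg <- session_config(duration_s = 30, eeg = list(
    schedule = list(list(start_s = 0, end_s = 15, state = "closed"),
                    list(start_s = 15, end_s = 30, state = "open")),
    blink_rate_per_min = 0
  ))
  g <- gen_eeg(cfg, seed = 83)
  fs <- 400
  rel <- function(x) band_power(welch_psd(x, fs), 8, 13)$relative
  expect_gt(rel(g$eeg[1:(15 * fs), 1]), rel(g$eeg[(15 * fs + 1):(30 * fs), 1]))
  expect_identical(length(g$blink_times_s), 0L)
  expect_identical(nrow(detect_blinks(g$eeg[, 1], fs)), 0L)
})

test_that("generated EDA honours its event list", {
  cfg <- session_config(duration_s = 170)
  g <- gen_eda(cfg, seed = 84)
  expect_identical(length(g$scr_onsets_s), length(cfg$eda$scr_events))

  # zero-amplitude events leave the trace identical to a no-event trace
  ev0 <- lapply(cfg$eda$scr_events, function(e) { e$amplitude_us <- 0; e })
  cfg_zero <- session_config(duration_s = 170, eda = list(scr_events = ev0))
  cfg_none <- session_config(duration_s = 170, eda = list(scr_events = list()))
  expect_equal(gen_eda(cfg_zero, seed = 84)$eda, gen_eda(cfg_none, seed = 84)$eda)

  # without events the phasic output stays at the noise floor
  g0 <- gen_eda(cfg_none, seed = 84)
  scr <- extract_scr(g0$eda, g0$fs)
  expect_lt(max(abs(scr$scr_us_per_s)), 0.1)
})

test_that("generated PPG carries the configured rate and is clean without artifact", {
  cfg <- session_config(duration_s = 60,
                        ppg = list(artifact_gain = 0),
                        accel = list(motion_bursts = list()))
  g <- gen_ppg_accel(cfg, seed = 85)
  n <- length(g$ppg[, 1])
  spec <- Mod(fft(g$ppg[, 1] - mean(g$ppg[, 1])))^2
  freq <- (0:(n - 1)) * 100 / n
  inband <- freq >= 0.5 & freq <= 5
  expect_equal(freq[inband][which.max(spec[inband])], 1.2, tolerance = 0.02)
  truth <- windowed_truth(g$pr_track_bpm, 100)
  expect_lte(aae(estimate_pr(g$ppg[, 1], 100), truth), 1)
})

test_that("full sessions assemble all modalities on a shared clock", {
  sess <- gen_session(session_config(duration_s = 1))
  expect_identical(nrow(sess$record$eeg), 400L)
  expect_identical(nrow(sess$record$periph), 100L)

  sess150 <- gen_session(session_config(duration_s = 150))
  snr <- segment_snr(sess150$record$periph$eda_us, 100)
  expect_identical(nrow(snr), 29L)

  sess170 <- gen_session(session_config(duration_s = 170))
  expect_equal(record_duration(sess170$record), 20 + 60 + 90)
  expect_identical(length(sess170$truth$scr_onsets_s), 3L)

  expect_error(session_config(duration_s = 100, accel = list(
    motion_bursts = list(list(start_s = 90, dur_s = 20, rms_g = 0.3))
  )), class = "biopad_config_error")
})

test_that("records frame into 20 packets per second and back within quantization", {
  sess <- gen_session(session_config(duration_s = 30, seed = 86))
  stream <- record_to_packets(sess$record)
  expect_identical(length(stream), 30L * 20L * 168L)

  one_s <- gen_session(session_config(duration_s = 1, seed = 86))
  expect_identical(length(record_to_packets(one_s$record)), 3360L)

  empty <- frames_to_record(list())
  expect_identical(length(record_to_packets(empty)), 0L)

  dec <- decode_stream(stream)
  expect_identical(dec$diagnostics$frames_ok, 600L)
  back <- frames_to_record(dec$frames)

  sc <- codec_scales()
  # per-channel reconstruction bounded by one code step
  lsb_eeg_uv <- 2 * 2.5 / (2^23 - 1) / sc$eeg_gain * 1e6
  expect_lte(max(abs(back$eeg$eeg1_uv - sess$record$eeg$eeg1_uv)), lsb_eeg_uv)
  expect_lte(max(abs(back$eeg$eeg2_uv - sess$record$eeg$eeg2_uv)), lsb_eeg_uv)

  u <- eda_microsiemens_to_volts(sess$record$periph$eda_us)
  lsb_eda_us <- max(abs(eda_volts_to_microsiemens(u + 3.3 / 65535 / 2) -
                          eda_volts_to_microsiemens(u - 3.3 / 65535 / 2)))
  expect_lte(max(abs(back$periph$eda_us - sess$record$periph$eda_us)), lsb_eda_us)

  lsb_skt_c <- 3300 / 65535 * 0.1943
  expect_lte(max(abs(back$periph$skt_c - sess$record$periph$skt_c)), lsb_skt_c)

  lsb_ppg <- sc$ppg_span / 255
  expect_lte(max(abs(back$periph$ppg_red - sess$record$periph$ppg_red)), lsb_ppg)
  expect_lte(max(abs(back$periph$ppg_ir - sess$record$periph$ppg_ir)), lsb_ppg)

  lsb_acc <- sc$accel_span_g / 127
  for (ch in c("acc_x_g", "acc_y_g", "acc_z_g")) {
    expect_lte(max(abs(back$periph[[ch]] - sess$record$periph[[ch]])), lsb_acc)
  }

  # truncation policy for partial frames
  short <- sess$record
  short$eeg <- short$eeg[1:410, ]
  short$periph <- short$periph[1:103, ]
  expect_error(record_to_packets(short), class = "biopad_data_error")
  expect_identical(length(record_to_packets(short, partial = "truncate")), 20L * 168L)
})

test_that("session configurations round-trip through YAML", {
  cfg <- config_ppg_session(seed = 87)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_session_config(cfg, path)
  back <- read_session_config(path)
  expect_equal(back$duration_s, cfg$duration_s)
  expect_equal(back$ppg$pr_profile$bpm, cfg$ppg$pr_profile$bpm)
  expect_equal(length(back$accel$motion_bursts), 4L)
  # the regenerated session is identical
  expect_identical(gen_session(back)$record$periph$ppg_red,
                   gen_session(cfg)$record$periph$ppg_red)
  expect_error(read_session_config(withr::local_tempfile(fileext = ".yaml")),
               class = "biopad_config_error")
})
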