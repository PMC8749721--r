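comb_ref <- design_comb(8L, 0.96852105385218623, 400)

test_that("comb notches sit at multiples of fs/N and inter-notch gain is unity", {
  # zeros at k * 400/8 = k * 50 Hz including DC
  for (f in c(0, 50, 100, 150, 200)) {
    expect_lt(frequency_response(comb_ref, f)$magnitude, 1e-12)
  }
  # inter-notch midpoints: |z^-N| = -1 makes |H| exactly 1
  for (f in c(25, 75, 125, 175)) {
    expect_equal(frequency_response(comb_ref, f)$magnitude_db, 0, tolerance = 1e-9)
  }
  # response symmetric across each notch
  for (d in c(0.5, 2, 5)) {
    expect_equal(frequency_response(comb_ref, 50 - d)$magnitude,
                 frequency_response(comb_ref, 50 + d)$magnitude,
                 tolerance = 1e-9)
  }
  # closed-form agreement on a sweep
  f <- seq(0.5, 199.5, by = 0.5)
  expect_equal(frequency_response(comb_ref, f)$magnitude,
               comb_mag_oracle(f, 8L, 0.96852105385218623, 400),
               tolerance = 1e-12)
})

test_that("comb attenuation at 50 Hz meets the design depth", {
  expect_gte(notch_attenuation_db(comb_ref, 50), 20.4)
  expect_gte(notch_attenuation_db(comb_ref, 100), 20.4)
  expect_gte(notch_attenuation_db(comb_ref, 150), 20.4)
  expect_error(design_comb(rh0 = 1.01), class = "biopad_config_error")
})

test_that("Butterworth low-pass matches its closed-form bilinear magnitude", {
  bw <- design_butterworth_lp(2L, 30, 400)
  expect_equal(frequency_response(bw, 0)$magnitude_db, 0, tolerance = 1e-9)
  expect_equal(frequency_response(bw, 30)$magnitude_db, -3.0103, tolerance = 1e-3)
  # frozen from the closed-form prewarped oracle
  expect_equal(frequency_response(bw, 60)$magnitude_db, -13.2814, tolerance = 1e-3)
  f <- seq(0, 200, by = 2.5)
  expect_equal(frequency_response(bw, f)$magnitude,
               butter2_mag_oracle(f, 30, 400), tolerance = 1e-9)
  # monotone magnitude
  expect_true(all(diff(frequency_response(bw, f)$magnitude) < 1e-12))
  expect_error(design_butterworth_lp(2L, 250, 400), class = "biopad_config_error")
})

test_that("direct-form-II application matches the sample-by-sample recursion", {
  set.seed(21)
  bw <- design_butterworth_lp(2L, 30, 400)
  for (spec in list(comb_ref, bw)) {
    x <- rnorm(1e4)
    expect_equal(apply_iir_df2(x, spec), df2_oracle(x, spec$b, spec$a),
                 tolerance = 1e-10)
    # cross-check against the signal package's filter routine
    expect_equal(apply_iir_df2(x, spec),
                 as.numeric(signal::filter(spec$b, spec$a, x)),
                 tolerance = 1e-8)
  }
  expect_identical(apply_iir_df2(numeric(0), bw), numeric(0))
  expect_identical(apply_iir_df2(rep(0, 100), bw), rep(0, 100))
  expect_error(apply_iir_df2(c(1, NA, 3), bw), class = "biopad_data_error")
})

test_that("filtering is linear and time-invariant", {
  set.seed(22)
  x <- rnorm(2000); y <- rnorm(2000)
  bw <- design_butterworth_lp(2L, 30, 400)
  expect_equal(apply_iir_df2(2 * x + 3 * y, bw),
               2 * apply_iir_df2(x, bw) + 3 * apply_iir_df2(y, bw),
               tolerance = 1e-10)
  # a delayed input yields the delayed output (zero initial state)
  lag <- 17L
  xd <- c(rep(0, lag), x)
  expect_equal(apply_iir_df2(xd, bw)[(lag + 1):(lag + 2000)],
               apply_iir_df2(x, bw), tolerance = 1e-10)
})

test_that("a 50-Hz sine is suppressed to the frequency-response bound", {
  fs <- 400; t <- (0:(fs * 5 - 1)) / fs
  y <- apply_iir_df2(sin(2 * pi * 50 * t), comb_ref)
  steady <- tail(y, fs)
  expect_lte(max(abs(steady)), 10^(-20.4 / 20))
})

test_that("zero-phase filtering squares the magnitude and keeps timing", {
  fs <- 400; t <- (0:(fs * 10 - 1)) / fs
  bw <- design_butterworth_lp(2L, 30, 400)
  x <- sin(2 * pi * 10 * t)
  y <- apply_iir_df2(x, bw, zero_phase = TRUE)
  mid <- 2000:3000
  # 10 Hz lies in the passband: amplitude scales by |H|^2 with zero phase
  # shift, so the output tracks the input sample for sample
  h2 <- butter2_mag_oracle(10, 30, 400)^2
  expect_lt(max(abs(y[mid] - h2 * x[mid])), 0.01)
})

test_that("peripheral channel designs use the documented corners and are stable", {
  expect_equal(design_peripheral_lp("EDA")$design$fc, 5)
  expect_equal(design_peripheral_lp("PPG")$design$fc, 8)
  expect_equal(design_peripheral_lp("SKT")$design$fc, 1)
  expect_error(design_peripheral_lp("EMG"), class = "biopad_config_error")
  for (ch in c("EDA", "SKT", "PPG")) {
    a <- design_peripheral_lp(ch)$a
    expect_true(all(Mod(polyroot(rev(a))) < 1))
  }
})

test_that("comb plus low-pass removes mains but preserves the EEG band", {
  cfg <- session_config(duration_s = 30, eeg = list(blink_rate_per_min = 0))
  x <- gen_eeg(cfg, seed = 31)$eeg[, 1]
  fs <- 400
  lp <- design_butterworth_lp(2L, 30, fs)
  y <- apply_iir_df2(apply_iir_df2(x, comb_ref), lp)
  drop_50 <- band_power_db(x, fs, 49, 51) - band_power_db(y, fs, 49, 51)
  drop_eeg <- band_power_db(x, fs, 1, 13) - band_power_db(y, fs, 1, 13)
  expect_gte(drop_50, 20)
  expect_lt(abs(drop_eeg), 1)
})

test_that("filter specifications round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_iir_yaml(comb_ref, path)
  back <- read_iir_yaml(path)
  expect_equal(back$b, comb_ref$b, tolerance = 1e-12)
  expect_equal(back$a, comb_ref$a, tolerance = 1e-12)
  expect_equal(back$fs, comb_ref$fs)
  expect_equal(back$design$kind, "comb")
})
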