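test_that("crc8 matches the bit-level long-division oracle", {
  expect_identical(crc8(raw(0)), 0L)
  expect_identical(crc8(utf8ToInt("123456789")), 0xA1L)
  set.seed(11)
  for (len in c(1L, 7L, 64L, 165L)) {
    payload <- sample(0:255, len, replace = TRUE)
    expect_identical(crc8(payload), crc8_oracle(payload))
  }
})

test_that("crc8 detects every single-bit flip of a 64-byte payload", {
  set.seed(12)
  payload <- sample(0:255, 64L, replace = TRUE)
  ref <- crc8(payload)
  for (byte in seq_len(64L)) {
    for (bit in 0:7) {
      flipped <- payload
      flipped[byte] <- bitwXor(flipped[byte], bitwShiftL(1L, bit))
      expect_false(crc8(flipped) == ref)
    }
  }
})

test_that("encoded frames have the documented byte layout", {
  zero <- encode_frame(matrix(0L, 20, 2),
                       list(eda = rep(0L, 5), skt = rep(0L, 5),
                            ppg_red = rep(0L, 5), ppg_ir = rep(0L, 5),
                            acc_x = rep(0L, 5), acc_y = rep(0L, 5), acc_z = rep(0L, 5)))
  expect_length(zero, 168L)
  expect_identical(as.integer(zero[1:2]), c(0x7FL, 0xE6L))
  expect_true(all(as.integer(zero[3:167]) == 0L))
  expect_identical(as.integer(zero[168]), crc8(rep(0L, 165L)))

  # hand-packed reference bytes for known samples
  eeg <- matrix(0L, 20, 2)
  eeg[1, 1] <- 0x123456L         # first EEG tick, channel 1
  eeg[1, 2] <- -1L               # two's complement FF FF FF
  per <- list(eda = c(0xABCDL, 0L, 0L, 0L, 0L), skt = c(0x0102L, 0L, 0L, 0L, 0L),
              ppg_red = c(0x7FL, 0L, 0L, 0L, 0L), ppg_ir = c(0x80L, 0L, 0L, 0L, 0L),
              acc_x = c(-1L, 0L, 0L, 0L, 0L), acc_y = c(-128L, 0L, 0L, 0L, 0L),
              acc_z = c(127L, 0L, 0L, 0L, 0L))
  f <- as.integer(encode_frame(eeg, per))
  expect_identical(f[3:5], c(0x12L, 0x34L, 0x56L))     # offset 2: eeg t1 ch1
  expect_identical(f[6:8], c(0xFFL, 0xFFL, 0xFFL))     # offset 5: eeg t1 ch2
  expect_identical(f[123:124], c(0xABL, 0xCDL))        # offset 122: eda t1
  expect_identical(f[125:126], c(0x01L, 0x02L))        # skt t1
  expect_identical(f[127:128], c(0x7FL, 0x80L))        # ppg red/ir t1
  expect_identical(f[129:131], c(0xFFL, 0x80L, 0x7FL)) # accel x/y/z t1
})

test_that("encode rejects out-of-range samples with channel and tick", {
  base <- random_frame_inputs()
  bad_eeg <- base$eeg; bad_eeg[3, 1] <- 2^23
  expect_error(encode_frame(bad_eeg, base$per), class = "biopad_data_error")
  bad_per <- base$per; bad_per$acc_y[4] <- 130L
  err <- tryCatch(encode_frame(base$eeg, bad_per), error = identity)
  expect_s3_class(err, "biopad_data_error")
  expect_match(conditionMessage(err), "acc_y")
  expect_match(conditionMessage(err), "tick 4")
})

test_that("decode_frame inverts encode_frame on random frames", {
  set.seed(13)
  for (i in 1:200) {
    inp <- random_frame_inputs()
    dec <- decode_frame(encode_frame(inp$eeg, inp$per))
    expect_identical(dec$eeg_codes, inp$eeg)
    for (ch in names(inp$per)) {
      expect_identical(dec$peripheral[[ch]], inp$per[[ch]])
    }
  }
})

test_that("decode_frame raises framing and integrity errors", {
  inp <- random_frame_inputs()
  f <- encode_frame(inp$eeg, inp$per)
  bad_hdr <- f; bad_hdr[1] <- as.raw(0x00)
  expect_error(decode_frame(bad_hdr), class = "biopad_framing_error")
  flipped <- f
  flipped[60] <- xor(flipped[60], as.raw(0x04))
  expect_error(decode_frame(flipped), class = "biopad_integrity_error")
  expect_error(decode_frame(f[1:100]), class = "biopad_integrity_error")
})

test_that("decode_stream resynchronizes and accounts for every byte", {
  set.seed(14)
  frames <- replicate(3, {
    inp <- random_frame_inputs()
    encode_frame(inp$eeg, inp$per)
  }, simplify = FALSE)
  clean <- do.call(c, frames)

  res <- decode_stream(clean)
  expect_identical(res$diagnostics$frames_ok, 3L)
  expect_identical(res$diagnostics$bytes_skipped_resync, 0L)

  prefixed <- c(as.raw(c(0x01, 0x02, 0x03)), frames[[1]], frames[[2]])
  res <- decode_stream(prefixed)
  expect_identical(res$diagnostics$frames_ok, 2L)
  expect_identical(res$diagnostics$bytes_skipped_resync, 3L)

  corrupt <- frames[[2]]
  corrupt[168] <- xor(corrupt[168], as.raw(0xFF))
  res <- decode_stream(c(frames[[1]], corrupt, frames[[3]]))
  expect_identical(res$diagnostics$frames_ok, 2L)
  expect_identical(res$diagnostics$frames_crc_fail, 1L)

  # any garbage prefix shorter than one frame still yields every frame,
  # and consumed bytes always balance
  for (glen in c(1L, 50L, 167L)) {
    garbage <- as.raw(sample(0:255, glen, replace = TRUE))
    res <- decode_stream(c(garbage, clean))
    expect_identical(res$diagnostics$frames_ok, 3L)
    d <- res$diagnostics
    expect_identical(168L * (d$frames_ok + d$frames_crc_fail) + d$bytes_skipped_resync,
                     length(garbage) + length(clean))
  }
})

test_that("frames_to_record concatenates frames at the nominal rates", {
  set.seed(15)
  frames <- replicate(20, {
    inp <- random_frame_inputs()
    decode_frame(encode_frame(inp$eeg, inp$per))
  }, simplify = FALSE)
  rec <- frames_to_record(frames)
  expect_identical(nrow(rec$eeg), 400L)
  expect_identical(nrow(rec$periph), 100L)
  expect_equal(record_duration(rec), 1.0)

  empty <- frames_to_record(list())
  expect_identical(nrow(empty$eeg), 0L)
  expect_identical(nrow(empty$periph), 0L)

  expect_warning(
    frames_to_record(frames[1:3], frame_index = c(0L, 1L, 3L)),
    class = "biopad_gap_warning"
  )
})
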