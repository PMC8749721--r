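#' Frame layout of the device wire protocol
#'
#' One frame spans exactly 50 ms of signal and is 168 bytes:
#'
#' | offset | bytes | content |
#' |-------:|------:|---------|
#' | 0      | 1     | header, `0x7F` |
#' | 1      | 1     | protocol magic, `0xE6` |
#' | 2      | 120   | EEG block: 20 ticks x 2 channels x 3 bytes, 24-bit two's-complement ADC codes, big-endian |
#' | 122    | 45    | peripheral block: 5 ticks x 9 bytes (EDA u16 BE, SKT u16 BE, PPG red u8, PPG IR u8, accel x/y/z i8) |
#' | 167    | 1     | CRC-8 over bytes 2..166 |
#'
#' 20 EEG ticks at 400 Hz and 5 peripheral ticks at 100 Hz both cover 50 ms,
#' so a nominal-rate stream emits exactly 20 frames per second. `0xE6` is
#' carried as a literal protocol constant, not a computed payload length.
#' The peripheral tick is 9 bytes so that the frame closes at exactly
#' 168 bytes; the two PPG channels are carried at 8-bit depth (pulse-rate
#' estimation downstream is amplitude-invariant and spectral, so waveform
#' shape at 8 bits suffices), while EDA and SKT keep 16 bits for the
#' sub-0.01-unit resolution their pipelines need.
#'
#' @format A named list with fields `frame_len`, `header`, `magic`,
#'   `eeg_ticks`, `eeg_channels`, `periph_ticks`, `payload_offset`,
#'   `crc_offset`.
#' @export
frame_layout <- list(
  frame_len      = 168L,
  header         = 0x7FL,
  magic          = 0xE6L,
  eeg_ticks      = 20L,
  eeg_channels   = 2L,
  eeg_bytes      = 120L,
  periph_ticks   = 5L,
  periph_bytes   = 45L,
  payload_offset = 2L,   # zero-based offset of first payload byte
  crc_offset     = 167L, # zero-based offset of CRC byte
  frames_per_s   = 20L
)

# 256-entry lookup table for CRC-8 poly 0x31 reflected (0x8C), init 0x00.
# Built once at load by bitwise long division over each possible byte.
crc8_table <- local({
  tab <- integer(256L)
  for (byte in 0:255) {
    crc <- byte
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), 0x8CL)
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[byte + 1L] <- crc
  }
  tab
})

#' CRC-8 checksum of a byte sequence
#'
#' Reflected CRC-8 with polynomial `0x31` and initial value `0x00` (the
#' Dallas/Maxim sensor-bus variant), the integrity check byte of the wire
#' frame. The check value over the ASCII bytes of `"123456789"` is `0xA1`.
#'
#' @param payload a `raw` vector, or an integer vector with values in 0..255.
#' @return A single integer in 0..255.
#' @examples
#' crc8(as.raw(c(0x01, 0x02, 0x03)))
#' crc8(utf8ToInt("123456789")) # 0xA1 = 161
#' @export
crc8 <- function(payload) {
  bytes <- as_byte_ints(payload, "payload")
  crc <- 0L
  for (b in bytes) {
    crc <- crc8_table[bitwXor(crc, b) + 1L]
  }
  crc
}

as_byte_ints <- function(x, what) {
  if (is.raw(x)) return(as.integer(x))
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (anyNA(x) || any(x < 0L | x > 255L)) {
      stop_data("`%s` must contain byte values in 0..255", what)
    }
    return(x)
  }
  stop_data("`%s` must be raw or integer", what)
}

# ---- field packing helpers (big-endian) ------------------------------------

pack_i24 <- function(v) {
  # signed 24-bit two's complement, big-endian; v scalar integer-valued
  u <- if (v < 0) v + 16777216 else v
  c(u %/% 65536, (u %/% 256) %% 256, u %% 256)
}

unpack_i24 <- function(b) {
  u <- b[1L] * 65536 + b[2L] * 256 + b[3L]
  if (u >= 8388608) u - 16777216 else u
}

pack_u16 <- function(v) c(v %/% 256L, v %% 256L)
unpack_u16 <- function(b) b[1L] * 256L + b[2L]

check_range <- function(x, lo, hi, channel) {
  bad <- which(x < lo | x > hi | x != round(x))
  if (length(bad)) {
    stop_data("%s value out of field range at tick %d (value %s, allowed [%s, %s])",
              channel, bad[1L], format(x[bad[1L]]), format(lo), format(hi))
  }
}

#' Encode one 50-ms frame of multimodal samples
#'
#' Packs 20 ticks of two-channel EEG ADC codes and 5 ticks of peripheral
#' samples into one 168-byte wire frame, appending the CRC-8 of the payload.
#'
#' @param eeg_codes integer matrix, 20 rows (ticks) x 2 columns (channels),
#'   signed 24-bit ADC codes.
#' @param peripheral a data frame (or list) with 5-element integer columns
#'   `eda`, `skt` (unsigned 16-bit), `ppg_red`, `ppg_ir` (unsigned 8-bit),
#'   `acc_x`, `acc_y`, `acc_z` (signed 8-bit).
#' @return A `raw` vector of length 168.
#' @seealso [decode_frame()], [frame_layout]
#' @export
encode_frame <- function(eeg_codes, peripheral) {
  fl <- frame_layout
  eeg_codes <- as.matrix(eeg_codes)
  if (!identical(dim(eeg_codes), c(fl$eeg_ticks, fl$eeg_channels)) &&
      !all(dim(eeg_codes) == c(fl$eeg_ticks, fl$eeg_channels))) {
    stop_data("`eeg_codes` must be a %d x %d matrix", fl$eeg_ticks, fl$eeg_channels)
  }
  check_range(as.numeric(eeg_codes), -8388608, 8388607, "EEG")
  p <- lapply(peripheral[c("eda", "skt", "ppg_red", "ppg_ir",
                           "acc_x", "acc_y", "acc_z")], as.numeric)
  if (any(lengths(p) != fl$periph_ticks)) {
    stop_data("peripheral columns must each have %d ticks", fl$periph_ticks)
  }
  check_range(p$eda, 0, 65535, "EDA")
  check_range(p$skt, 0, 65535, "SKT")
  check_range(p$ppg_red, 0, 255, "PPG red")
  check_range(p$ppg_ir, 0, 255, "PPG IR")
  for (ax in c("acc_x", "acc_y", "acc_z")) check_range(p[[ax]], -128, 127, ax)

  payload <- numeric(fl$eeg_bytes + fl$periph_bytes)
  k <- 1L
  for (tick in seq_len(fl$eeg_ticks)) {
    for (ch in seq_len(fl$eeg_channels)) {
      payload[k:(k + 2L)] <- pack_i24(eeg_codes[tick, ch])
      k <- k + 3L
    }
  }
  for (tick in seq_len(fl$periph_ticks)) {
    payload[k:(k + 8L)] <- c(
      pack_u16(p$eda[tick]), pack_u16(p$skt[tick]),
      p$ppg_red[tick], p$ppg_ir[tick],
      (p$acc_x[tick] + 256) %% 256, (p$acc_y[tick] + 256) %% 256,
      (p$acc_z[tick] + 256) %% 256
    )
    k <- k + 9L
  }
  as.raw(c(fl$header, fl$magic, payload, crc8(as.integer(payload))))
}

#' Decode one 168-byte wire frame
#'
#' Validates the header, magic and CRC bytes and unpacks the payload;
#' the exact inverse of [encode_frame()].
#'
#' @param raw a `raw` (or 0..255 integer) vector of length 168.
#' @return A list with `eeg_codes` (20 x 2 integer matrix) and `peripheral`
#'   (tibble with 5 rows: `eda`, `skt`, `ppg_red`, `ppg_ir`, `acc_x`,
#'   `acc_y`, `acc_z`).
#' @export
decode_frame <- function(raw) {
  fl <- frame_layout
  b <- as_byte_ints(raw, "raw")
  if (length(b) != fl$frame_len) {
    stop_integrity("frame must be %d bytes, got %d", fl$frame_len, length(b))
  }
  if (b[1L] != fl$header || b[2L] != fl$magic) {
    abort(sprintf("bad framing bytes: %02X %02X", b[1L], b[2L]),
          class = c("biopad_framing_error", "biopad_data_error"))
  }
  payload <- b[3:(fl$frame_len - 1L)]
  if (crc8(payload) != b[fl$frame_len]) {
    stop_integrity("CRC mismatch: computed %02X, stored %02X",
                   crc8(payload), b[fl$frame_len])
  }
  eeg <- matrix(0L, fl$eeg_ticks, fl$eeg_channels)
  k <- 1L
  for (tick in seq_len(fl$eeg_ticks)) {
    for (ch in seq_len(fl$eeg_channels)) {
      eeg[tick, ch] <- as.integer(unpack_i24(payload[k:(k + 2L)]))
      k <- k + 3L
    }
  }
  per <- matrix(0L, fl$periph_ticks, 7L)
  for (tick in seq_len(fl$periph_ticks)) {
    chunk <- payload[k:(k + 8L)]
    per[tick, ] <- as.integer(c(
      unpack_u16(chunk[1:2]), unpack_u16(chunk[3:4]),
      chunk[5L], chunk[6L],
      ifelse(chunk[7:9] >= 128L, chunk[7:9] - 256L, chunk[7:9])
    ))
    k <- k + 9L
  }
  colnames(per) <- c("eda", "skt", "ppg_red", "ppg_ir", "acc_x", "acc_y", "acc_z")
  list(eeg_codes = eeg, peripheral = as_tibble(as.data.frame(per)))
}

#' Decode an arbitrary byte stream with resynchronization
#'
#' Scans for the `0x7F 0xE6` sync pattern, validates each candidate frame's
#' CRC, and emits the good frames in order. Malformed regions are skipped and
#' counted rather than raising errors, so a stream with a garbage prefix, a
#' corrupted frame or a truncated tail still yields every intact frame.
#'
#' @param bytes a `raw` vector (e.g. from [readBin()] on a `.bin` stream).
#' @return A list with `frames` (list of [decode_frame()] results, in stream
#'   order) and `diagnostics`, a one-row tibble with `frames_ok`,
#'   `frames_crc_fail` and `bytes_skipped_resync`. Every input byte is
#'   accounted for: `168 * (frames_ok + frames_crc_fail) +
#'   bytes_skipped_resync = length(bytes)`.
#' @export
decode_stream <- function(bytes) {
  fl <- frame_layout
  b <- as_byte_ints(bytes, "bytes")
  n <- length(b)
  frames <- list()
  ok <- 0L; crc_fail <- 0L; skipped <- 0L
  i <- 1L
  while (i <= n) {
    if (i + fl$frame_len - 1L <= n &&
        b[i] == fl$header && b[i + 1L] == fl$magic) {
      cand <- b[i:(i + fl$frame_len - 1L)]
      payload <- cand[3:(fl$frame_len - 1L)]
      if (crc8(payload) == cand[fl$frame_len]) {
        ok <- ok + 1L
        frames[[ok]] <- decode_frame(cand)
      } else {
        crc_fail <- crc_fail + 1L
      }
      i <- i + fl$frame_len
    } else {
      skipped <- skipped + 1L
      i <- i + 1L
    }
  }
  list(
    frames = frames,
    diagnostics = tibble(
      frames_ok = ok,
      frames_crc_fail = crc_fail,
      bytes_skipped_resync = skipped
    )
  )
}

#' Assemble decoded frames into a multirate record in physical units
#'
#' Concatenates per-frame channel blocks into continuous streams (EEG at
#' 400 Hz, peripherals at 100 Hz) and converts raw ADC codes to physical
#' units through the analog-front-end models: EEG codes to microvolts (24-bit
#' bipolar ADC scaling divided by the 200x analog gain), EDA codes to
#' microsiemens, SKT codes to degrees Celsius, PPG to dimensionless units and
#' acceleration to g.
#'
#' @param frames a list of decoded frames as produced by [decode_frame()] or
#'   `decode_stream()$frames`, in stream order.
#' @param frame_index optional integer vector of frame indices; gaps are
#'   flagged in the record's diagnostics (the samples are still concatenated
#'   back to back).
#' @param scales quantization scales, see [codec_scales()].
#' @return A [multirate_record] object.
#' @export
frames_to_record <- function(frames, frame_index = NULL, scales = codec_scales()) {
  fl <- frame_layout
  nf <- length(frames)
  gaps <- tibble(after_index = integer(), before_index = integer())
  if (!is.null(frame_index) && nf > 0L) {
    if (length(frame_index) != nf) stop_data("`frame_index` length mismatch")
    d <- diff(frame_index)
    if (any(d != 1L)) {
      at <- which(d != 1L)
      gaps <- tibble(after_index = frame_index[at], before_index = frame_index[at + 1L])
      warn(sprintf("frame-index gap(s) detected at %d position(s)", length(at)),
           class = "biopad_gap_warning")
    }
  }
  if (nf == 0L) {
    return(multirate_record(
      eeg = tibble(time_s = numeric(), eeg1_uv = numeric(), eeg2_uv = numeric()),
      periph = tibble(time_s = numeric(), eda_us = numeric(), skt_c = numeric(),
                      ppg_red = numeric(), ppg_ir = numeric(),
                      acc_x_g = numeric(), acc_y_g = numeric(), acc_z_g = numeric()),
      diagnostics = list(gaps = gaps)
    ))
  }
  eeg_codes <- do.call(rbind, lapply(frames, `[[`, "eeg_codes"))
  per <- do.call(rbind, lapply(frames, `[[`, "peripheral"))
  fs_eeg <- fl$eeg_ticks * fl$frames_per_s
  fs_per <- fl$periph_ticks * fl$frames_per_s
  eeg <- tibble(
    time_s  = (seq_len(nrow(eeg_codes)) - 1L) / fs_eeg,
    eeg1_uv = eeg_code_to_uv(eeg_codes[, 1L], scales),
    eeg2_uv = eeg_code_to_uv(eeg_codes[, 2L], scales)
  )
  periph <- tibble(
    time_s  = (seq_len(nrow(per)) - 1L) / fs_per,
    eda_us  = eda_code_to_us(per$eda, scales),
    skt_c   = skt_code_to_c(per$skt, scales),
    ppg_red = ppg_code_to_au(per$ppg_red, scales),
    ppg_ir  = ppg_code_to_au(per$ppg_ir, scales),
    acc_x_g = accel_code_to_g(per$acc_x, scales),
    acc_y_g = accel_code_to_g(per$acc_y, scales),
    acc_z_g = accel_code_to_g(per$acc_z, scales)
  )
  multirate_record(eeg = eeg, periph = periph, diagnostics = list(gaps = gaps))
}
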