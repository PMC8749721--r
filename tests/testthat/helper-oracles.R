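# Independent oracles kept deliberately separate from the package internals.

# CRC-8 (poly 0x31 reflected, init 0x00) by explicit bit-level long division:
# the register is a logical bit vector, message bits enter LSB-first, and the
# feedback taps are the reflected generator x^8 + x^5 + x^4 + 1 (0x8C).
crc8_oracle <- function(bytes) {
  reg <- rep(FALSE, 8L)           # reg[1] = LSB
  poly <- as.logical(c(0, 0, 1, 1, 0, 0, 0, 1))  # 0x8C bits, LSB-first
  for (b in bytes) {
    mbits <- as.logical(bitwAnd(bitwShiftR(b, 0:7), 1L))
    for (bit in mbits) {
      fb <- xor(reg[1L], bit)
      reg <- c(reg[-1L], FALSE)
      if (fb) reg <- xor(reg, poly)
    }
  }
  as.integer(sum(2^(0:7) * reg))
}

# direct evaluation of the two difference equations of a direct-form-II
# section, one sample at a time
df2_oracle <- function(x, b, a) {
  n <- length(x)
  na <- length(a); nb <- length(b)
  w <- numeric(n)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- x[i]
    if (na > 1L) for (k in 2:na) if (i - k + 1L >= 1L) acc <- acc - a[k] * w[i - k + 1L]
    w[i] <- acc
    out <- 0
    for (k in 1:nb) if (i - k + 1L >= 1L) out <- out + b[k] * w[i - k + 1L]
    y[i] <- out
  }
  y
}

# analytic magnitude of a bilinear-transform Butterworth low-pass of order 2:
# |H|^2 = 1 / (1 + (W/Wc)^4) in prewarped frequency W = tan(pi f / fs)
butter2_mag_oracle <- function(f, fc, fs) {
  W <- tan(pi * f / fs)
  Wc <- tan(pi * fc / fs)
  sqrt(1 / (1 + (W / Wc)^4))
}

# closed-form comb magnitude from the difference equation's transfer function
comb_mag_oracle <- function(f, n_order, rh0, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(((1 + rh0) / 2) * (1 - z^n_order) / (1 - rh0 * z^n_order))
}

# one valid random frame's worth of samples
random_frame_inputs <- function() {
  list(
    eeg = matrix(sample(-8388608:8388607, 40L, replace = TRUE), 20L, 2L),
    per = list(
      eda = sample(0:65535, 5L, replace = TRUE),
      skt = sample(0:65535, 5L, replace = TRUE),
      ppg_red = sample(0:255, 5L, replace = TRUE),
      ppg_ir = sample(0:255, 5L, replace = TRUE),
      acc_x = sample(-128:127, 5L, replace = TRUE),
      acc_y = sample(-128:127, 5L, replace = TRUE),
      acc_z = sample(-128:127, 5L, replace = TRUE)
    )
  )
}

band_power_db <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))^2 / n
  freq <- (0:(n - 1L)) * fs / n
  10 * log10(sum(spec[freq > lo & freq <= hi]))
}
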