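# Independent oracles and fixture builders shared across tests.

# Direct DFT-definition oracle: E[n] = |sum_k y[k] exp(-i 2 pi n k / N)|,
# one-sided. Built from the definition matrix, independent of stats::fft.
oracle_energy_spectrum <- function(frames) {
  N <- ncol(frames)
  k <- 0:(N - 1)
  n_bins <- N %/% 2 + 1
  W <- exp(-2i * pi * outer(0:(n_bins - 1), k) / N)
  t(abs(W %*% t(frames)))
}

# Naive double-loop DCT oracle: Ceps[n] = 2/N * sum_k x[k] cos(pi n (k+0.5)/N)
# for 0-based coefficient indices coef_idx.
oracle_dct <- function(x, coef_idx) {
  N <- length(x)
  out <- numeric(length(coef_idx))
  for (j in seq_along(coef_idx)) {
    n <- coef_idx[j]
    acc <- 0
    for (k in 0:(N - 1)) acc <- acc + x[k + 1] * cos(pi * n * (k + 0.5) / N)
    out[j] <- 2 / N * acc
  }
  out
}

# Pure sine clip at a given frequency.
sine_clip <- function(freq_hz, duration_s = 1, amp = 1, sample_rate = 48000,
                      phase = 0) {
  t <- (seq_len(round(duration_s * sample_rate)) - 1) / sample_rate
  audio_clip(amp * sin(2 * pi * freq_hz * t + phase), sample_rate,
             paste0("sine", freq_hz))
}

# Separable classification fixture: gaussian noise features with a mean
# shift in a coefficient band for the positive class.
separable_set <- function(n, seed, shape = c(110, 52), shift = 1.2,
                          band = 20:28, shuffle_labels = FALSE) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- array(stats::rnorm(n * shape[1] * shape[2]), c(n, shape[1], shape[2]))
  for (i in seq_len(n)) if (y[i] == 1) x[i, , band] <- x[i, , band] + shift
  if (shuffle_labels) y <- sample(y)
  list(x = x, y = y)
}

# Hand-written 16-bit mono PCM WAV with the given integer sample values
# (independent of write_wav).
write_pcm16_fixture <- function(values, path, sample_rate = 48000,
                                n_channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(values)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(n_channels), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L * n_channels, con, size = 4L,
           endian = "little")
  writeBin(2L * n_channels, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(as.integer(values), con, size = 2L, endian = "little")
  path
}
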