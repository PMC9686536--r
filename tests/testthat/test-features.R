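test_that("energy spectrum follows the one-sided DFT modulus definition", {
  expect_equal(energy_spectrum(numeric(1024)), numeric(513))
  imp <- c(1, numeric(1023))
  expect_equal(energy_spectrum(imp), rep(1, 513))
  # windowed 3000 Hz sine peaks at bin 3000 / (48000/1024) = 64 (0-based)
  fr <- frame_signal(sine_clip(3000, duration_s = 1024 / 48000))
  e <- energy_spectrum(fr$windowed_frames[1, ])
  expect_equal(which.max(e) - 1L, 64L)
  expect_error(energy_spectrum(numeric(100)), "1024")
})

test_that("energy spectrum matches the direct DFT oracle on random frames", {
  set.seed(13)
  frames <- matrix(stats::rnorm(10 * 1024), 10)
  got <- energy_spectrum(frames)
  want <- oracle_energy_spectrum(frames)
  expect_lt(max(abs(got - want) / (abs(want) + 1e-8)), 1e-7)
})

test_that("dB conversion is 10 log10 with a positive floor", {
  expect_equal(to_db(1), 0)
  expect_equal(to_db(100), 20)
  expect_equal(to_db(0, floor = 1e-10), -100)
  expect_error(to_db(1, floor = 0), "positive")
})

test_that("spectrogram has the contracted 110 x 513 shape with floor padding", {
  call <- generate_call(duration_s = 0.1, sex = "hen")  # 30 frames
  sp <- spectrogram(call)
  expect_equal(dim(sp), c(110, 513))
  expect_equal(attr(sp, "kind"), "spectrogram")
  expect_equal(attr(sp, "n_frames"), 30)
  expect_true(all(sp[31:110, ] == -100))
  expect_true(all(is.finite(sp)))
  expect_error(spectrogram(audio_clip(numeric(100) + 0.1, 48000)),
               "empty input")
})

test_that("frame-wise spectrogram peaks track a 5 kHz synthetic call", {
  set.seed(2)
  call <- generate_call(call_params(sex_offset_hz = 0), duration_s = 0.2)
  sp <- spectrogram(call)
  peaks <- apply(unclass(sp)[seq_len(attr(sp, "n_frames")), ], 1,
                 which.max) - 1L
  expect_true(all(abs(peaks - 5000 / (48000 / 1024)) <= 2))
})

test_that("amplitude scaling shifts every in-call dB value uniformly", {
  # dB here is 10*log10 of the DFT *modulus*, so scaling the waveform by c
  # shifts the spectrogram by exactly 10*log10(c)
  set.seed(4)
  x <- stats::runif(6000, -0.4, 0.4)
  base <- spectrogram(audio_clip(x, 48000))
  nf <- attr(base, "n_frames")
  for (c_amp in c(0.5, 2)) {
    scaled <- spectrogram(audio_clip(c_amp * x, 48000))
    expect_equal(unclass(scaled)[1:nf, ],
                 unclass(base)[1:nf, ] + 10 * log10(c_amp),
                 tolerance = 1e-9)
  }
})

test_that("cepstrogram keeps coefficients [5, 165) of the dB-spectrum DCT", {
  call <- generate_call(duration_s = 0.15)
  cep <- cepstrogram(call)
  expect_equal(dim(cep), c(110, 160))
  # independent double-loop oracle on the first frame's dB spectrum
  fr <- frame_signal(call)
  db1 <- to_db(energy_spectrum(fr$windowed_frames[1, ]))
  expect_equal(as.numeric(cep[1, ]), oracle_dct(db1, 5:164),
               tolerance = 1e-9)
  # a constant spectrum has no ripple: retained coefficients are all ~0
  expect_lt(max(abs(oracle_dct(rep(7.3, 513), 5:164))), 1e-10)
})

test_that("the mel map is the printed base-10 law and strictly increases", {
  expect_equal(mel_of_hz(0), 0)
  expect_equal(mel_of_hz(700), 2595 * log10(2))
  f <- seq(0, 24000, by = 100)
  expect_true(all(diff(mel_of_hz(f)) > 0))
  expect_error(mel_of_hz(-1), "non-negative")
})

test_that("the 26-channel mel bank has unit-peak ordered triangles", {
  bank <- build_mel_bank()
  expect_equal(dim(bank$filters), c(26, 513))
  expect_true(all(bank$filters >= 0))
  expect_equal(apply(bank$filters, 1, max), rep(1, 26))
  peaks <- apply(bank$filters, 1, which.max)
  expect_true(all(diff(peaks) > 0))
  # centers equally spaced in mel, recomputed through the mel map
  spacing <- diff(mel_of_hz(bank$centers_hz))
  expect_lt(max(abs(spacing - spacing[1])), 1e-6)
  expect_error(build_mel_bank(low_hz = 3000, high_hz = 1000), "Nyquist")
})

test_that("the combined feature is Logfbank ++ its DCT with 52 columns", {
  call <- generate_call(duration_s = 0.2)
  mf <- logfbank_mfcc(call)
  expect_equal(dim(mf), c(110, 52))
  nf <- attr(mf, "n_frames")
  # exponentiating the Logfbank block recovers the mel energies
  bank <- build_mel_bank()
  fr <- frame_signal(call)
  mfe <- energy_spectrum(fr$windowed_frames) %*% t(bank$filters)
  expect_equal(10^(unclass(mf)[1:nf, 1:26] / 10), mfe, tolerance = 1e-6,
               ignore_attr = TRUE)
  # MFCC block equals a brute-force DCT of the Logfbank block
  for (i in c(1, nf)) {
    expect_equal(as.numeric(mf[i, 27:52]),
                 oracle_dct(as.numeric(mf[i, 1:26]), 0:25),
                 tolerance = 1e-9)
  }
})

test_that("padding reaches the fixed frame count and truncates with warning", {
  m <- matrix(stats::rnorm(30 * 4), 30)
  p <- pad_to_fixed(m, 110, pad_value = -1)
  expect_equal(dim(p), c(110, 4))
  expect_equal(p[1:30, ], m)
  expect_true(all(p[31:110, ] == -1))
  expect_identical(pad_to_fixed(p, 110, -1), p)
  expect_warning(tr <- pad_to_fixed(matrix(0, 120, 4), 110, -1), "truncat")
  expect_equal(nrow(tr), 110)
  # pad rows are identical by construction: no gradient signal in padding
  expect_equal(apply(p[31:110, ], 2, stats::var), rep(0, 4))
})

test_that("every feature kind keeps its (kind, width) contract", {
  call <- generate_call(duration_s = 0.12)
  widths <- c(spectrogram = 513, cepstrogram = 160, mfcc_logfbank = 52)
  for (kind in names(widths)) {
    f <- call_features(call, kind)
    expect_equal(dim(f), c(110, unname(widths[kind])))
    expect_equal(attr(f, "kind"), kind)
    expect_true(all(is.finite(f)))
  }
})

test_that("feature archives round-trip through plain text", {
  calls <- list(generate_call(duration_s = 0.11),
                generate_call(duration_s = 0.13))
  feats <- lapply(calls, call_features, kind = "mfcc_logfbank")
  dir <- withr::local_tempdir()
  write_feature_archive(feats, dir)
  back <- read_feature_archive(dir)
  expect_equal(length(back), 2)
  expect_equal(unclass(back[[1]]), unclass(feats[[1]]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back[[2]], "kind"), "mfcc_logfbank")
})
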