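test_that("synthetic calls carry the planted fundamental and duration", {
  set.seed(6)
  call <- generate_call(sex = "cock")  # cock: 5000 + 400 Hz
  sp <- spectrogram(call)
  nf <- attr(sp, "n_frames")
  peaks <- (apply(unclass(sp)[1:nf, ], 1, which.max) - 1) * 48000 / 1024
  expect_true(all(peaks >= 5000 - 600 + 400 & peaks <= 5000 + 600 + 400))
  # 0.1 s call: 4800 samples, 30 frames
  c01 <- generate_call(duration_s = 0.1)
  expect_length(c01$samples, 4800)
  expect_equal(n_frames(frame_signal(c01)), 30)
  expect_lte(max(abs(call$samples)), 0.8 + 1e-12)
  expect_error(generate_call(call_params(fundamental_hz = 30000)), "Nyquist")
})

test_that("calls of one chick track each other in fundamental frequency", {
  set.seed(9)
  offset <- 120
  f_est <- function(call) {
    e <- abs(stats::fft(call$samples))[1:(length(call$samples) %/% 2)]
    (which.max(e) - 1) * 48000 / length(call$samples)
  }
  a <- generate_call(sex = "hen", chick_offset_hz = offset, duration_s = 0.2)
  b <- generate_call(sex = "hen", chick_offset_hz = offset, duration_s = 0.2)
  expect_lt(abs(f_est(a) - f_est(b)), 20)
  expect_lt(abs(f_est(a) - 5120), 20)
})

test_that("clean recordings are fully recovered by detection", {
  rec <- generate_recording(n_chicks = 2, calls_per_chick = 4, gap_s = 0.45,
                            noise_level = 0, seed = 31)
  seg <- detect_in_recording(apply_filter(rec$clip, design_highpass()))
  expect_equal(nrow(seg), nrow(rec$truth))
  expect_true(all(abs(seg$start_frame - rec$truth$start_frame) <= 2))
  expect_true(all(abs(seg$end_frame - rec$truth$end_frame) <= 2))
})

test_that("recordings are byte-identical WAVs under a fixed seed", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.wav")
  p2 <- file.path(d, "b.wav")
  write_wav(generate_recording(1, 3, seed = 5, noise_level = 0.02)$clip, p1)
  write_wav(generate_recording(1, 3, seed = 5, noise_level = 0.02)$clip, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- file.path(d, "c.wav")
  write_wav(generate_recording(1, 3, seed = 6, noise_level = 0.02)$clip, p3)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p3, "raw", file.size(p3))))
})

test_that("low-frequency noise is almost fully removed by the high-pass", {
  rec <- generate_recording(n_chicks = 1, calls_per_chick = 0,
                            noise_level = 0.1, seed = 8)
  expect_equal(sqrt(mean(rec$clip$samples^2)), 0.1, tolerance = 0.01)
  filt <- apply_filter(rec$clip, design_highpass())
  tail_rms <- sqrt(mean(filt$samples[-(1:2000)]^2))  # skip filter transient
  expect_lte(tail_rms, 0.01)
})

test_that("ground truth is internally consistent with the emitted audio", {
  rec <- generate_recording(n_chicks = 3, calls_per_chick = 2, gap_s = 0.5,
                            noise_level = 0, seed = 13)
  tr <- rec$truth
  expect_true(all(tr$start_sample[-1] >= utils::head(tr$end_sample, -1)))
  # samples inside the planted extents carry energy; gaps are silent
  for (i in seq_len(nrow(tr))) {
    seg <- rec$clip$samples[(tr$start_sample[i] + 1):tr$end_sample[i]]
    expect_gt(max(abs(seg)), 0.5)
  }
  gap <- rec$clip$samples[1:tr$start_sample[1]]
  expect_equal(max(abs(gap)), 0)
})

test_that("a generated study provides 41+ detectable calls per chick", {
  study <- generate_study(n_chicks_per_sex = 2,
                          breed_profiles = c(synth = 400),
                          calls_per_chick = 45, seed = 2)
  withr::defer(unlink(study$dir, recursive = TRUE))
  expect_equal(nrow(study$metadata), 4)
  expect_setequal(unique(study$metadata$sex), c("cock", "hen"))
  for (i in seq_len(nrow(study$metadata))) {
    clip <- read_wav(study$metadata$wav[i])
    seg <- detect_in_recording(apply_filter(clip, design_highpass()))
    expect_gte(nrow(seg), 41)
  }
})

test_that("study generation is reproducible under a fixed seed", {
  s1 <- generate_study(2, c(synth = 400), calls_per_chick = 5, seed = 4)
  s2 <- generate_study(2, c(synth = 400), calls_per_chick = 5, seed = 4)
  withr::defer(unlink(c(s1$dir, s2$dir), recursive = TRUE))
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(readBin(s1$metadata$wav[1], "raw", 1e5),
                   readBin(s2$metadata$wav[1], "raw", 1e5))
})
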