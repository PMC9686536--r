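# Synthetic chick-call generator. Real study recordings are not shareable,
# so fixtures with known ground truth stand in: harmonic chirps with a
# ~5 kHz fundamental and a weaker ~16 kHz formant band, a smooth onset/offset
# envelope, per-chick frequency jitter (calls of one bird track each other),
# a controllable per-sex fundamental offset, and additive low-frequency
# (< 1000 Hz) background noise. The sex offset is a test device -- a
# controllable analogue of sex differences, not a biological claim.

#' Synthetic call parameters
#'
#' @param fundamental_hz Base pitch in Hz (default 5000).
#' @param formant_hz Formant-band center in Hz (default 16000).
#' @param duration_range Call duration range in seconds, drawn uniformly
#'   (default `c(0.1, 0.26)`; durations up to 0.35 s are valid but calls
#'   longer than ~0.27 s exceed the detector's 110-frame duration ceiling
#'   once window overlap is counted, so the default keeps every planted call
#'   detectable).
#' @param harmonic_amps Relative amplitudes of the fundamental and its
#'   harmonics (default `c(1, 0.4, 0.2)`).
#' @param formant_amp Relative amplitude of the formant component
#'   (default 0.25, keeping the fundamental dominant).
#' @param amplitude Peak amplitude on the \[-1, 1\] scale (default 0.8).
#' @param attack_s,release_s Raised-cosine onset/offset lengths in seconds.
#' @param sex_offset_hz Added to the fundamental for cocks (default 400);
#'   0 makes the sexes acoustically identical.
#' @param chick_jitter_hz Per-chick base-frequency offset drawn uniformly in
#'   `[-chick_jitter_hz, chick_jitter_hz]` (default 150), making calls of one
#'   chick mutually similar but chicks distinct.
#' @return A `call_params`.
#' @export
call_params <- function(fundamental_hz = 5000, formant_hz = 16000,
                        duration_range = c(0.1, 0.26),
                        harmonic_amps = c(1, 0.4, 0.2), formant_amp = 0.25,
                        amplitude = 0.8, attack_s = 0.005, release_s = 0.01,
                        sex_offset_hz = 400, chick_jitter_hz = 150) {
  if (any(duration_range < 0.05) || diff(duration_range) < 0)
    stop("invalid duration range")
  structure(list(fundamental_hz = fundamental_hz, formant_hz = formant_hz,
                 duration_range = duration_range,
                 harmonic_amps = harmonic_amps, formant_amp = formant_amp,
                 amplitude = amplitude, attack_s = attack_s,
                 release_s = release_s, sex_offset_hz = sex_offset_hz,
                 chick_jitter_hz = chick_jitter_hz),
            class = "call_params")
}

call_envelope <- function(n, attack_n, release_n) {
  env <- rep(1, n)
  a <- min(attack_n, n %/% 2L)
  r <- min(release_n, n %/% 2L)
  if (a > 0) env[seq_len(a)] <- 0.5 * (1 - cos(pi * seq_len(a) / a))
  if (r > 0) env[n + 1L - seq_len(r)] <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  env
}

#' Generate one synthetic call
#'
#' Uses the current RNG state (seed at the recording/study level for
#' reproducibility). Harmonics at or above Nyquist are dropped silently; a
#' fundamental or formant at or above Nyquist is an error.
#'
#' @param params A [call_params()].
#' @param sex `"cock"` or `"hen"` (cocks get the `sex_offset_hz`).
#' @param chick_offset_hz This chick's fixed base-frequency offset.
#' @param duration_s Call length in seconds; drawn from
#'   `params$duration_range` when `NULL`.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @return An [audio_clip], peak amplitude `params$amplitude`.
#' @export
generate_call <- function(params = call_params(), sex = "hen",
                          chick_offset_hz = 0, duration_s = NULL,
                          sample_rate = 48000) {
  stopifnot(inherits(params, "call_params"), sex %in% c("cock", "hen"))
  f0 <- params$fundamental_hz + chick_offset_hz +
    if (sex == "cock") params$sex_offset_hz else 0
  nyq <- sample_rate / 2
  if (f0 <= 0 || f0 >= nyq)
    stop("fundamental ", f0, " Hz outside (0, Nyquist)")
  if (params$formant_hz >= nyq)
    stop("formant ", params$formant_hz, " Hz at or above Nyquist")
  if (is.null(duration_s))
    duration_s <- stats::runif(1, params$duration_range[1L],
                               params$duration_range[2L])
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (h in seq_along(params$harmonic_amps)) {
    fh <- h * f0
    if (fh >= nyq) next
    x <- x + params$harmonic_amps[h] * sin(2 * pi * fh * t +
                                             stats::runif(1, 0, 2 * pi))
  }
  x <- x + params$formant_amp * sin(2 * pi * params$formant_hz * t +
                                      stats::runif(1, 0, 2 * pi))
  x <- x * call_envelope(n, round(params$attack_s * sample_rate),
                         round(params$release_s * sample_rate))
  audio_clip(params$amplitude * x / max(abs(x)), sample_rate, "synthetic_call")
}

#' Generate a synthetic recording with ground truth
#'
#' Calls from `n_chicks` synthetic chicks (alternating sexes unless given)
#' are placed with silent gaps; low-pass background noise below
#' `noise_cutoff_hz` is added at the requested RMS. Ground truth carries
#' each call's sample extent (0-based, half-open) and its frame extent under
#' the window-overlap convention: the first/last analysis frame whose window
#' overlaps the call.
#'
#' @param n_chicks Number of chicks contributing calls (default 1).
#' @param calls_per_chick Calls per chick (0 gives a noise-only recording).
#' @param gap_s Mean silent gap between calls in seconds (default 0.4,
#'   jittered by +-20%).
#' @param noise_level RMS of the additive low-frequency noise (default 0).
#' @param noise_cutoff_hz Noise band edge (default 1000; real-world handling
#'   and footstep noise sits below this).
#' @param params A [call_params()].
#' @param sexes Optional per-chick sexes; alternates cock/hen by default.
#' @param sample_rate Sampling rate (default 48000).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param source_id Recording identifier.
#' @param spec The [window_spec()] used for ground-truth frame extents.
#' @return List with `clip` (an [audio_clip]) and `truth` (data frame:
#'   `call_id`, `chick_id`, `sex`, `start_sample`, `end_sample`,
#'   `start_frame`, `end_frame`).
#' @export
generate_recording <- function(n_chicks = 1, calls_per_chick = 10,
                               gap_s = 0.4, noise_level = 0,
                               noise_cutoff_hz = 1000,
                               params = call_params(), sexes = NULL,
                               sample_rate = 48000, seed = NULL,
                               source_id = "synthetic",
                               spec = window_spec()) {
  if (n_chicks < 1 || calls_per_chick < 0 || gap_s <= 0 || noise_level < 0)
    stop("generator parameters must be positive")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(sexes))
    sexes <- rep(c("cock", "hen"), length.out = n_chicks)
  offsets <- stats::runif(n_chicks, -params$chick_jitter_hz,
                          params$chick_jitter_hz)
  pieces <- list()
  rows <- list()
  pos <- 0L
  k <- 0L
  for (ci in seq_len(n_chicks)) {
    for (j in seq_len(calls_per_chick)) {
      gap <- round(gap_s * stats::runif(1, 0.8, 1.2) * sample_rate)
      call <- generate_call(params, sexes[ci], offsets[ci],
                            sample_rate = sample_rate)
      k <- k + 1L
      pieces[[2L * k - 1L]] <- numeric(gap)
      pieces[[2L * k]] <- call$samples
      s0 <- pos + gap
      s1 <- s0 + length(call$samples)
      rows[[k]] <- data.frame(call_id = k,
                              chick_id = sprintf("chick%03d", ci),
                              sex = sexes[ci],
                              start_sample = s0, end_sample = s1,
                              stringsAsFactors = FALSE)
      pos <- s1
    }
  }
  tail_gap <- round(gap_s * sample_rate)
  pieces[[length(pieces) + 1L]] <- numeric(tail_gap)
  x <- unlist(pieces)
  if (length(x) == 0L) x <- numeric(sample_rate) # noise-only second
  if (noise_level > 0) {
    lp <- signal::butter(8, noise_cutoff_hz / (sample_rate / 2), type = "low")
    nz <- as.numeric(signal::filter(lp, stats::rnorm(length(x))))
    nz <- nz * noise_level / sqrt(mean(nz^2))
    x <- pmax(-1, pmin(1, x + nz))
  }
  truth <- if (k > 0L) do.call(rbind, rows) else
    data.frame(call_id = integer(0), chick_id = character(0),
               sex = character(0), start_sample = integer(0),
               end_sample = integer(0))
  if (nrow(truth) > 0L) {
    m <- spec$length_samples
    hop <- spec$hop_samples
    truth$start_frame <- pmax(0L, as.integer((truth$start_sample - m) %/%
                                               hop + 1L))
    truth$end_frame <- as.integer(ceiling(truth$end_sample / hop))
  }
  list(clip = audio_clip(x, sample_rate, source_id), truth = truth)
}

#' Generate a full synthetic study
#'
#' One recording per chick (written as a 16-bit 48 kHz WAV, mirroring the
#' field protocol of one ~2 min file per bird) plus a metadata table. The
#' synthetic "breeds" are profiles differing only in their sex offset, which
#' controls how separable the sexes are; decreasing offsets emulate the
#' observed breed ordering of separability without modelling real breeds.
#'
#' @param n_chicks_per_sex Chicks per sex per breed.
#' @param breed_profiles Named numeric vector of per-breed sex offsets in Hz
#'   (default `c(synthA = 400, synthB = 250, synthC = 100)`).
#' @param calls_per_chick Calls per recording (default 45, comfortably above
#'   the 41-call voting inventory).
#' @param dir Output directory for the WAV files (created; default a fresh
#'   temporary directory).
#' @param params Base [call_params()] (the per-breed offset overrides
#'   `sex_offset_hz`).
#' @param gap_s,noise_level Passed to [generate_recording()].
#' @param seed Integer seed (per-chick recordings are seeded derivatively).
#' @return List with `metadata` (chick_id, breed, sex, wav path, planted
#'   call count), `ground_truth` (per-call table with chick ids), and `dir`.
#' @export
generate_study <- function(n_chicks_per_sex = 20,
                           breed_profiles = c(synthA = 400, synthB = 250,
                                              synthC = 100),
                           calls_per_chick = 45, dir = NULL,
                           params = call_params(), gap_s = 0.25,
                           noise_level = 0.02, seed = 1L) {
  if (n_chicks_per_sex < 2) stop("need at least 2 chicks per sex")
  if (is.null(dir)) dir <- tempfile("synthetic_study_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  gt <- list()
  i <- 0L
  for (b in seq_along(breed_profiles)) {
    breed <- names(breed_profiles)[b]
    p <- params
    p$sex_offset_hz <- unname(breed_profiles[b])
    for (sex in c("cock", "hen")) {
      for (ci in seq_len(n_chicks_per_sex)) {
        i <- i + 1L
        chick_id <- sprintf("%s_%s%03d", breed, sex, ci)
        rec <- generate_recording(1, calls_per_chick, gap_s = gap_s,
                                  noise_level = noise_level, params = p,
                                  sexes = sex, seed = seed * 10000L + i,
                                  source_id = chick_id)
        wav <- file.path(dir, paste0(chick_id, ".wav"))
        write_wav(rec$clip, wav)
        if (nrow(rec$truth) > 0L) rec$truth$chick_id <- chick_id
        rec$truth$breed <- breed
        gt[[i]] <- rec$truth
        meta[[i]] <- data.frame(chick_id = chick_id, breed = breed,
                                sex = sex, wav = wav,
                                n_calls_planted = nrow(rec$truth),
                                stringsAsFactors = FALSE)
      }
    }
  }
  list(metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
       ground_truth = do.call(rbind, c(gt, make.row.names = FALSE)),
       dir = dir)
}
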