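# Denoising and framing. Recordings are high-pass filtered (barn noise --
# footsteps, handling, hum -- sits below 1000 Hz while chick calls live above
# 1500 Hz), then cut into heavily overlapped windowed frames for short-time
# analysis.

#' Design the high-pass denoising filter
#'
#' Digital Butterworth high-pass design (bilinear transform, via the
#' \pkg{signal} package). The -3 dB (half-power) point of the design equals
#' `cutoff_hz` for every order, so the order only controls the roll-off
#' steepness below the cut.
#'
#' @param cutoff_hz -3 dB frequency in Hz (default 1500).
#' @param order Filter order (default 4).
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @return A `filter_spec`: recursion coefficients `a_coeffs`, `b_coeffs`
#'   of the IIR difference equation plus the design parameters.
#' @export
design_highpass <- function(cutoff_hz = 1500, order = 4, sample_rate = 48000) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2)
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency")
  if (order < 1) stop("order must be a positive integer")
  ba <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "high")
  structure(
    list(cutoff_hz = cutoff_hz, order = as.integer(order),
         sample_rate = sample_rate,
         b_coeffs = as.numeric(ba$b), a_coeffs = as.numeric(ba$a)),
    class = "filter_spec"
  )
}

#' Evaluate a filter's complex frequency response
#'
#' @param spec A `filter_spec` from [design_highpass()].
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @return Complex response H(f).
#' @export
filter_response <- function(spec, freq_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- 2 * pi * freq_hz / spec$sample_rate
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(spec$b_coeffs * zz^(seq_along(spec$b_coeffs) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(spec$a_coeffs * zz^(seq_along(spec$a_coeffs) - 1)),
                complex(1))
  num / den
}

#' Filter magnitude response in dB
#'
#' @inheritParams filter_response
#' @return `20 * log10(|H(f)|)`.
#' @export
filter_gain_db <- function(spec, freq_hz) {
  20 * log10(Mod(filter_response(spec, freq_hz)))
}

#' Locate the half-power (-3 dB) frequency of a designed filter
#'
#' Root-finds the frequency at which the evaluated magnitude response crosses
#' 1/sqrt(2) (i.e. -3.0103 dB, the conventional "-3 dB point").
#'
#' @param spec A `filter_spec`.
#' @return Frequency in Hz.
#' @export
half_power_frequency <- function(spec) {
  target <- -10 * log10(2)
  f <- stats::uniroot(function(fr) filter_gain_db(spec, fr) - target,
                      lower = 1, upper = spec$sample_rate / 2 - 1,
                      tol = 1e-6)
  f$root
}

#' Apply an IIR filter to a clip
#'
#' Single-pass causal recursion of the standard IIR difference equation
#' (a forward-backward pass would square the magnitude response and shift
#' the stated -3 dB point, so it is deliberately not used).
#'
#' @param clip An [audio_clip].
#' @param spec A `filter_spec` designed for `clip$sample_rate`.
#' @return A filtered [audio_clip] of the same length.
#' @export
apply_filter <- function(clip, spec) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(clip$sample_rate, spec$sample_rate)))
    stop("filter designed for ", spec$sample_rate, " Hz but clip is ",
         clip$sample_rate, " Hz")
  y <- as.numeric(signal::filter(spec$b_coeffs, spec$a_coeffs, clip$samples))
  audio_clip(y, clip$sample_rate, clip$source_id)
}

#' Framing / windowing specification
#'
#' Defaults follow the analysis setup: 1024-sample windows (21.3 ms at
#' 48 kHz) advanced by one eighth of the window, i.e. a 128-sample hop.
#'
#' @param length_samples Window length in samples (default 1024).
#' @param hop_samples Hop in samples (default `length_samples / 8`).
#' @param kind One of `"hanning"`, `"hamming"`, `"rectangular"`.
#' @return A `window_spec`.
#' @export
window_spec <- function(length_samples = 1024,
                        hop_samples = length_samples %/% 8,
                        kind = c("hanning", "hamming", "rectangular")) {
  kind <- match.arg(kind)
  if (length_samples < 2) stop("window length must be at least 2 samples")
  if (hop_samples < 1) stop("hop must be at least 1 sample")
  structure(list(length_samples = as.integer(length_samples),
                 hop_samples = as.integer(hop_samples),
                 kind = kind),
            class = "window_spec")
}

#' Evaluate the analysis window
#'
#' Periodic form with divisor M: Hamming `0.54 - 0.46 cos(2 pi n / M)` and
#' Hanning `0.5 - 0.5 cos(2 pi n / M)` for n = 0..M-1, so the edge values are
#' 0.08 (Hamming) and 0 (Hanning).
#'
#' @param spec A [window_spec()].
#' @return Numeric vector of length `spec$length_samples`.
#' @export
make_window <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  m <- spec$length_samples
  n <- seq_len(m) - 1
  switch(spec$kind,
    hamming = 0.54 - 0.46 * cos(2 * pi * n / m),
    hanning = 0.5 - 0.5 * cos(2 * pi * n / m),
    rectangular = rep(1, m),
    stop("unknown window kind: ", spec$kind)
  )
}

#' Slice a clip into overlapped frames
#'
#' Frames are laid out left to right with the given hop; a trailing remainder
#' shorter than one window is dropped, so the frame count is exactly
#' `floor((L - M) / hop) + 1`. Both the raw and the window-tapered views are
#' kept: zero-crossing analysis reads the raw frames, spectral features the
#' windowed ones.
#'
#' @param clip An [audio_clip] at least one window long.
#' @param spec A [window_spec()].
#' @return A `frame_matrix`: list with `raw_frames` and `windowed_frames`
#'   (`n_frames` x `length_samples` matrices), `spec`, `sample_rate`,
#'   `source_id`.
#' @export
frame_signal <- function(clip, spec = window_spec()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "window_spec"))
  m <- spec$length_samples
  hop <- spec$hop_samples
  L <- length(clip$samples)
  if (L < m)
    stop("empty input: clip (", L, " samples) is shorter than one window (",
         m, " samples)")
  nf <- (L - m) %/% hop + 1L
  idx <- outer(seq_len(m), (seq_len(nf) - 1L) * hop, "+")
  raw <- t(matrix(clip$samples[idx], nrow = m, ncol = nf))
  w <- make_window(spec)
  windowed <- raw * rep(w, each = nf)
  structure(list(raw_frames = raw, windowed_frames = windowed,
                 spec = spec, sample_rate = clip$sample_rate,
                 source_id = clip$source_id),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix '%s': %d frames x %d samples (hop %d, %s)>\n",
              x$source_id, nrow(x$raw_frames), x$spec$length_samples,
              x$spec$hop_samples, x$spec$kind))
  invisible(x)
}

#' Number of frames in a frame matrix
#' @param frames A `frame_matrix`.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) {
  stopifnot(inherits(frames, "frame_matrix"))
  nrow(frames$raw_frames)
}
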