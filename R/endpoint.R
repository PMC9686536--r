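# Endpoint detection: chick calls are found as maximal runs of frames whose
# offset-gated short-time zero-crossing rate exceeds a threshold, then gated
# by duration (calls last 0.1-0.35 s; runs shorter than T1 = 30 frames or
# longer than T2 = 110 frames are discarded).

#' Detector configuration
#'
#' @param zcr_threshold Crossings per frame above which a frame counts as
#'   voiced (default 10 -- silence sits near 0, a 5 kHz call in the hundreds).
#' @param min_frames Duration gate T1 in frames (default 30).
#' @param max_frames Duration gate T2 in frames (default 110).
#' @param offset Amplitude dead zone on the \[-1, 1\] scale; sign changes whose
#'   excursion stays within `offset` are treated as sensor/current noise and
#'   ignored (default 0.01).
#' @return A `detector_config`.
#' @export
detector_config <- function(zcr_threshold = 10, min_frames = 30,
                            max_frames = 110, offset = 0.01) {
  if (min_frames < 1 || max_frames < min_frames)
    stop("need 0 < min_frames <= max_frames")
  if (zcr_threshold < 0 || offset < 0)
    stop("zcr_threshold and offset must be non-negative")
  structure(list(zcr_threshold = zcr_threshold,
                 min_frames = as.integer(min_frames),
                 max_frames = as.integer(max_frames),
                 offset = offset),
            class = "detector_config")
}

#' Short-time zero-crossing rate
#'
#' Counts, per frame, the sign changes of the waveform after discarding the
#' amplitude dead zone: samples with |x| <= offset are dropped and a crossing
#' is scored whenever consecutive surviving samples (both inside the frame)
#' have opposite signs. Computed on *raw* (unwindowed) frames -- the window
#' taper would not change sign structure but is an artifact of spectral
#' analysis, not of the waveform.
#'
#' @param x A `frame_matrix` (per-frame counting) or an [audio_clip]
#'   (fast sample-domain path over a whole recording).
#' @param offset Amplitude dead zone (default 0.01).
#' @param ... Further arguments; the `audio_clip` method takes `spec`, a
#'   [window_spec()] defining the framing.
#' @return Integer vector of crossing counts, one per frame.
#' @export
short_time_zcr <- function(x, offset = 0.01, ...) UseMethod("short_time_zcr")

#' @rdname short_time_zcr
#' @export
short_time_zcr.frame_matrix <- function(x, offset = 0.01, ...) {
  fr <- x$raw_frames
  if (nrow(fr) == 0L) return(integer(0))
  s <- sign(fr)
  s[abs(fr) <= offset] <- 0
  # column scan: carry the last nonzero sign within each frame (row)
  carry <- s[, 1L]
  counts <- integer(nrow(fr))
  for (j in seq(2L, ncol(fr))) {
    cur <- s[, j]
    active <- cur != 0
    chg <- active & carry != 0 & (cur != carry)
    counts <- counts + chg
    carry[active] <- cur[active]
  }
  counts
}

#' @rdname short_time_zcr
#' @export
short_time_zcr.audio_clip <- function(x, offset = 0.01, spec = window_spec(),
                                      ...) {
  m <- spec$length_samples
  hop <- spec$hop_samples
  L <- length(x$samples)
  if (L < m)
    stop("empty input: clip is shorter than one window")
  nf <- (L - m) %/% hop + 1L
  s <- sign(x$samples)
  s[abs(x$samples) <= offset] <- 0
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(nf))
  sn <- s[nz]
  tr <- which(sn[-1L] != sn[-length(sn)])
  if (length(tr) == 0L) return(integer(nf))
  a <- nz[tr]        # last sample of the old sign
  b <- nz[tr + 1L]   # first sample of the new sign
  # a crossing (a, b) is counted by frame f (0-based) iff
  # f*hop + 1 <= a  and  b <= f*hop + m
  f_lo <- pmax(0L, as.integer(ceiling((b - m) / hop)))
  f_hi <- pmin(nf - 1L, as.integer((a - 1L) %/% hop))
  keep <- f_lo <= f_hi
  d <- tabulate(f_lo[keep] + 1L, nbins = nf + 1L) -
    tabulate(f_hi[keep] + 2L, nbins = nf + 1L)
  cumsum(d)[seq_len(nf)]
}

#' Detect calls from a ZCR sequence
#'
#' Maximal runs of consecutive frames with ZCR strictly above the threshold
#' become candidate segments; candidates whose duration falls outside
#' \[T1, T2\] frames are discarded. Frame indices are 0-based and half-open;
#' sample extents derive from the framing: `start_sample = start_frame * hop`,
#' `end_sample = (end_frame - 1) * hop + window_length`.
#'
#' @param zcr Integer vector of per-frame crossing counts.
#' @param config A [detector_config()].
#' @param spec The [window_spec()] the ZCR sequence was computed with (used
#'   for the frame-to-sample conversion).
#' @param source_id Recording identifier attached to every segment.
#' @return A `call_segments` data frame: `source_id`, `start_frame`,
#'   `end_frame`, `duration_frames`, `start_sample`, `end_sample`, sorted and
#'   disjoint.
#' @export
detect_calls <- function(zcr, config = detector_config(),
                         spec = window_spec(), source_id = "recording") {
  stopifnot(inherits(config, "detector_config"))
  voiced <- zcr > config$zcr_threshold
  seg <- empty_segments(source_id)
  if (any(voiced)) {
    r <- rle(voiced)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    sf <- starts[runs] - 1L            # 0-based
    ef <- ends[runs]                   # half-open
    dur <- ef - sf
    ok <- dur >= config$min_frames & dur <= config$max_frames
    if (any(ok)) {
      sf <- sf[ok]; ef <- ef[ok]; dur <- dur[ok]
      seg <- data.frame(
        source_id = source_id,
        start_frame = sf, end_frame = ef, duration_frames = dur,
        start_sample = sf * spec$hop_samples,
        end_sample = (ef - 1L) * spec$hop_samples + spec$length_samples,
        stringsAsFactors = FALSE
      )
      class(seg) <- c("call_segments", "data.frame")
    }
  }
  seg
}

empty_segments <- function(source_id = character(0)) {
  seg <- data.frame(source_id = character(0),
                    start_frame = integer(0), end_frame = integer(0),
                    duration_frames = integer(0),
                    start_sample = integer(0), end_sample = integer(0),
                    stringsAsFactors = FALSE)
  class(seg) <- c("call_segments", "data.frame")
  seg
}

#' Detect calls in a recording
#'
#' Convenience front end: computes the offset-gated ZCR profile of a (already
#' filtered) recording by the fast sample-domain path and applies
#' [detect_calls()].
#'
#' @param clip A filtered [audio_clip].
#' @param config A [detector_config()].
#' @param spec A [window_spec()].
#' @return A `call_segments` data frame.
#' @export
detect_in_recording <- function(clip, config = detector_config(),
                                spec = window_spec()) {
  zcr <- short_time_zcr(clip, offset = config$offset, spec = spec)
  detect_calls(zcr, config, spec, source_id = clip$source_id)
}

#' Extract one detected call's audio
#'
#' @param clip The [audio_clip] the segment was detected in.
#' @param segment A single row of a `call_segments` data frame.
#' @return An [audio_clip] covering `[start_sample, end_sample)` (0-based,
#'   half-open), with the segment appended to the source identifier.
#' @export
extract_call_audio <- function(clip, segment) {
  stopifnot(inherits(clip, "audio_clip"))
  s0 <- segment$start_sample[1L]
  s1 <- segment$end_sample[1L]
  if (is.na(s0) || is.na(s1) || s0 < 0 || s1 > length(clip$samples) || s0 >= s1)
    stop("segment [", s0, ", ", s1, ") out of clip bounds [0, ",
         length(clip$samples), ")")
  audio_clip(clip$samples[(s0 + 1L):s1], clip$sample_rate,
             paste0(clip$source_id, "#", s0, "-", s1))
}

#' Write a segment table as delimited text
#'
#' @param segments A `call_segments` data frame.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path Path to the tab-separated table.
#' @return A `call_segments` data frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(seg) <- c("call_segments", "data.frame")
  seg
}
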