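# RIFF/WAVE PCM reader and writer. Only uncompressed PCM (8/16/24/32-bit
# integer) and 32-bit IEEE float are supported; that covers every file the
# recording protocol (48 kHz / 16-bit mono) and the synthetic generator emit.

#' Construct an audio clip
#'
#' An `audio_clip` holds a sampled mono waveform on the \[-1, 1\] amplitude
#' scale (integer PCM is normalized by 2^(bits-1)) together with its sample
#' rate and an opaque source identifier.
#'
#' @param samples Numeric vector of samples. Values are expected on the
#'   \[-1, 1\] scale; small excursions beyond 1 (e.g. filter overshoot) are
#'   tolerated.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @param source_id Identifier carried through segmentation and featurization.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate = 48000, source_id = "clip") {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(samples) == 0L) stop("empty audio: clip has no samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Read a PCM WAV file
#'
#' Parses the RIFF container directly. Multi-channel files are reduced to
#' the first channel with a warning. Samples are normalized to \[-1, 1\]
#' (division by 2^(bits-1) for integer PCM).
#'
#' @param path Path to a RIFF/WAVE file.
#' @param source_id Identifier for the clip; defaults to the file name
#'   without extension.
#' @return An [audio_clip].
#' @export
read_wav <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read WAV: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little") # overall size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      blob <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(blob[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(blob[3:4], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(blob[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(blob[15:16], "integer", 1L, 2L, signed = FALSE,
                               endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1L, origin = "current") # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV (no fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("empty audio: WAV has no data: ", path)

  x <- decode_pcm(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV '", basename(path), "': using channel 1 of ",
            fmt$n_channels)
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  if (length(x) == 0L) stop("empty audio: WAV has no samples: ", path)
  if (is.null(source_id))
    source_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_clip(x, fmt$sample_rate, source_id)
}

decode_pcm <- function(raw, audio_format, bits) {
  if (audio_format == 3L && bits == 32L)
    return(readBin(raw, "double", length(raw) %/% 4L, 4L, endian = "little"))
  if (audio_format != 1L)
    stop("unsupported WAV encoding (format tag ", audio_format, ")")
  switch(as.character(bits),
    "8"  = (as.integer(raw) - 128) / 128,
    "16" = readBin(raw, "integer", length(raw) %/% 2L, 2L, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4L, 4L, endian = "little") /
      2147483648,
    stop("unsupported PCM bit depth: ", bits)
  )
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' Samples are scaled by 2^15, rounded and clamped to the 16-bit range, so a
#' write-then-read round trip agrees with the original within 1/2^15.
#'
#' @param clip An [audio_clip].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  v <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32768))))
  n_bytes <- 2L * length(v)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(clip$sample_rate) * 2L, con, size = 4L,
           endian = "little")                                  # byte rate
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}
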