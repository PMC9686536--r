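# Per-call time-frequency features. Each detected call becomes one of three
# fixed-shape matrices (frames x coefficients, padded to 110 frames):
#   spectrogram   110 x 513  one-sided dB magnitude spectrum per frame
#   cepstrogram   110 x 160  DCT of the dB spectrum, coefficients [5, 165)
#   mfcc_logfbank 110 x 52   26 log mel-filterbank energies ++ their 26 DCT
# All logs are base 10 with the 10x dB factor; energies are clamped at a
# floor (default 1e-10) before the log so features stay finite.

DB_FLOOR <- 1e-10

#' One-sided energy spectrum of a windowed frame
#'
#' Modulus (not squared modulus) of the 1024-point DFT, bins 0..512.
#'
#' @param frame Numeric vector of length `n_fft` (a windowed frame) or a
#'   matrix with frames in rows.
#' @param n_fft Expected frame length (default 1024).
#' @return Numeric vector of `n_fft/2 + 1` non-negative values, or a matrix
#'   with one such row per frame.
#' @export
energy_spectrum <- function(frame, n_fft = 1024) {
  n_bins <- n_fft %/% 2L + 1L
  if (is.matrix(frame)) {
    if (ncol(frame) != n_fft)
      stop("frames must have ", n_fft, " samples, got ", ncol(frame))
    sp <- Mod(stats::mvfft(t(frame)))[seq_len(n_bins), , drop = FALSE]
    return(t(sp))
  }
  if (length(frame) != n_fft)
    stop("frame must have ", n_fft, " samples, got ", length(frame))
  Mod(stats::fft(frame))[seq_len(n_bins)]
}

#' Convert energies to the dB scale
#'
#' `10 * log10(max(E, floor))` elementwise.
#'
#' @param energy Non-negative energies.
#' @param floor Positive clamp applied before the log (default 1e-10).
#' @return Values in dB.
#' @export
to_db <- function(energy, floor = DB_FLOOR) {
  if (floor <= 0) stop("floor must be positive")
  10 * log10(pmax(energy, floor))
}

#' Pad (or truncate) a per-frame feature stack to a fixed frame count
#'
#' Rows beyond the call are filled with `pad_value` -- a scalar, or a vector
#' giving one floor value per feature column. Inputs longer than the target
#' are truncated with a warning.
#'
#' @param m Numeric matrix, frames in rows.
#' @param target_frames Output row count (default 110).
#' @param pad_value Scalar or length-`ncol(m)` vector.
#' @return A `target_frames` x `ncol(m)` matrix.
#' @export
pad_to_fixed <- function(m, target_frames = 110, pad_value = to_db(0)) {
  nf <- nrow(m)
  if (nf > target_frames) {
    warning("call has ", nf, " frames; truncating to ", target_frames)
    return(m[seq_len(target_frames), , drop = FALSE])
  }
  if (nf == target_frames) return(m)
  pad <- matrix(pad_value, nrow = target_frames - nf, ncol = ncol(m),
                byrow = length(pad_value) > 1L)
  rbind(m, pad)
}

feature_matrix <- function(values, kind, n_frames_call, source_id = "call") {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, class = c("feature_matrix", "matrix"),
            kind = kind, n_frames = n_frames_call, source_id = source_id)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s: %d x %d ('%s', %d call frames)>\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "source_id"),
              attr(x, "n_frames")))
  invisible(x)
}

frame_call <- function(call, window) {
  fr <- frame_signal(call, window)
  if (n_frames(fr) < 1L) stop("empty input: call too short to frame")
  fr
}

#' dB-scale spectrogram of one call
#'
#' Frames the call, takes the one-sided DFT modulus of each windowed frame,
#' converts to dB, stacks the frames in time order and pads to the fixed
#' 110-frame shape (pad value: the dB floor).
#'
#' @param call An [audio_clip] holding one detected call.
#' @param window A [window_spec()].
#' @param target_frames Fixed output frame count (default 110).
#' @param db_floor Energy clamp before the log (default 1e-10).
#' @return A 110 x 513 `feature_matrix` of kind `"spectrogram"`.
#' @export
spectrogram <- function(call, window = window_spec(), target_frames = 110,
                        db_floor = DB_FLOOR) {
  fr <- frame_call(call, window)
  e <- energy_spectrum(fr$windowed_frames, window$length_samples)
  db <- to_db(e, db_floor)
  feature_matrix(pad_to_fixed(db, target_frames, to_db(0, db_floor)),
                 "spectrogram", nrow(db), call$source_id)
}

# DCT-II basis: B[k+1, j] = cos(pi * n_j * (k + 0.5) / N) * 2/N, one column
# per retained coefficient index n_j (0-based).
dct_basis <- function(N, coef_idx) {
  k <- seq_len(N) - 0.5
  sapply(coef_idx, function(n) cos(pi * n * k / N)) * (2 / N)
}

#' Cepstrogram of one call
#'
#' Per frame, the cepstrum is the DCT (taken over all `N = 513` dB-spectrum
#' bins) of the dB spectrum; coefficient indices \[5, 165) (0-based) are
#' retained, giving 160 values per frame, stacked and padded to 110 frames
#' (pad value: the dB floor).
#'
#' @inheritParams spectrogram
#' @param keep 0-based half-open coefficient range (default `c(5, 165)`).
#' @return A 110 x 160 `feature_matrix` of kind `"cepstrogram"`.
#' @export
cepstrogram <- function(call, window = window_spec(), target_frames = 110,
                        db_floor = DB_FLOOR, keep = c(5, 165)) {
  fr <- frame_call(call, window)
  e <- energy_spectrum(fr$windowed_frames, window$length_samples)
  db <- to_db(e, db_floor)
  N <- ncol(db)
  basis <- dct_basis(N, seq(keep[1], keep[2] - 1))
  ceps <- db %*% basis
  feature_matrix(pad_to_fixed(ceps, target_frames, to_db(0, db_floor)),
                 "cepstrogram", nrow(ceps), call$source_id)
}

#' Mel scale
#'
#' `M(f) = 2595 * log10(1 + f / 700)`; strictly increasing with `M(0) = 0`.
#'
#' @param f Frequency in Hz (non-negative).
#' @return Mel frequency.
#' @export
mel_of_hz <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Build a triangular mel filter bank
#'
#' `n_filters` triangular filters with unit peaks, their edge/center
#' frequencies equally spaced on the mel scale between `low_hz` and
#' `high_hz`, evaluated on the one-sided FFT bin grid (edges snapped to bins
#' so each filter peaks at exactly 1 on its center bin).
#'
#' @param n_filters Number of channels (default 26).
#' @param low_hz,high_hz Band edges in Hz (defaults 0 and Nyquist).
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @param n_fft FFT length (default 1024; the bank spans `n_fft/2 + 1` bins).
#' @return A `mel_filter_bank`: `filters` (`n_filters` x `n_fft/2+1` matrix),
#'   `centers_hz` (design centers), plus the band parameters.
#' @export
build_mel_bank <- function(n_filters = 26, low_hz = 0, high_hz = NULL,
                           sample_rate = 48000, n_fft = 1024) {
  if (is.null(high_hz)) high_hz <- sample_rate / 2
  if (n_filters < 1) stop("need at least one filter")
  if (low_hz < 0 || high_hz <= low_hz || high_hz > sample_rate / 2)
    stop("need 0 <= low_hz < high_hz <= Nyquist")
  n_bins <- n_fft %/% 2L + 1L
  mel_pts <- seq(mel_of_hz(low_hz), mel_of_hz(high_hz),
                 length.out = n_filters + 2L)
  hz_pts <- hz_of_mel(mel_pts)
  bin_pts <- floor((n_fft + 1) * hz_pts / sample_rate)
  filters <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    lo <- bin_pts[j]; ce <- bin_pts[j + 1L]; hi <- bin_pts[j + 2L]
    if (ce > lo)
      for (k in lo:(ce - 1L)) filters[j, k + 1L] <- (k - lo) / (ce - lo)
    filters[j, ce + 1L] <- 1
    if (hi > ce + 1L)
      for (k in (ce + 1L):(hi - 1L)) filters[j, k + 1L] <- (hi - k) / (hi - ce)
  }
  structure(list(filters = filters, centers_hz = hz_pts[2:(n_filters + 1L)],
                 n_filters = as.integer(n_filters), low_hz = low_hz,
                 high_hz = high_hz, sample_rate = sample_rate, n_fft = n_fft),
            class = "mel_filter_bank")
}

#' Combined Logfbank + MFCC feature of one call
#'
#' Per frame: linear energy spectrum -> mel energies (filter-bank product) ->
#' 10*log10 scaling (the Logfbank block, 26 values) -> DCT over the 26
#' channels (the MFCC block, all 26 coefficients kept) -> concatenation to a
#' 52-vector; frames stacked and padded to 110 (pad row: the feature of a
#' silent frame, i.e. the feature-wise floor).
#'
#' @inheritParams spectrogram
#' @param bank A `mel_filter_bank` (default: 26 channels over 0..Nyquist).
#' @return A 110 x 52 `feature_matrix` of kind `"mfcc_logfbank"`.
#' @export
logfbank_mfcc <- function(call, bank = NULL, window = window_spec(),
                          target_frames = 110, db_floor = DB_FLOOR) {
  if (is.null(bank))
    bank <- build_mel_bank(sample_rate = call$sample_rate,
                           n_fft = window$length_samples)
  fr <- frame_call(call, window)
  e <- energy_spectrum(fr$windowed_frames, window$length_samples)
  mfe <- e %*% t(bank$filters)
  logfbank <- to_db(mfe, db_floor)
  nc <- bank$n_filters
  basis <- dct_basis(nc, seq(0, nc - 1))
  mfcc <- logfbank %*% basis
  feats <- cbind(logfbank, mfcc)
  # silent-frame feature: logfbank at the floor, MFCC = DCT of that constant
  silent <- c(rep(to_db(0, db_floor), nc),
              as.numeric(rep(to_db(0, db_floor), nc) %*% basis))
  feature_matrix(pad_to_fixed(feats, target_frames, silent),
                 "mfcc_logfbank", nrow(feats), call$source_id)
}

#' Compute a named feature for one call
#'
#' @param call An [audio_clip] holding one detected call.
#' @param kind One of `"spectrogram"`, `"cepstrogram"`, `"mfcc_logfbank"`.
#' @param window A [window_spec()].
#' @param bank Optional `mel_filter_bank` (only for `"mfcc_logfbank"`).
#' @param ... Passed to the specific feature function.
#' @return A `feature_matrix`.
#' @export
call_features <- function(call,
                          kind = c("mfcc_logfbank", "spectrogram",
                                   "cepstrogram"),
                          window = window_spec(), bank = NULL, ...) {
  kind <- match.arg(kind)
  switch(kind,
    spectrogram = spectrogram(call, window, ...),
    cepstrogram = cepstrogram(call, window, ...),
    mfcc_logfbank = logfbank_mfcc(call, bank = bank, window = window, ...)
  )
}

#' Stack feature matrices into a batch array
#'
#' @param features List of `feature_matrix` objects of one kind.
#' @return Array of dim `(n_calls, frames, coefficients)`.
#' @export
feature_array <- function(features) {
  stopifnot(length(features) > 0L)
  d <- dim(features[[1L]])
  out <- array(0, c(length(features), d[1L], d[2L]))
  for (i in seq_along(features)) out[i, , ] <- features[[i]]
  out
}

#' Write a feature archive
#'
#' One plain-text matrix file per call plus a tab-separated manifest naming
#' each file, its kind and its provenance.
#'
#' @param features List of `feature_matrix` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_feature_archive <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    file <- sprintf("call_%05d.tsv", i)
    utils::write.table(unclass(f), file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    data.frame(file = file, kind = attr(f, "kind"),
               n_frames = attr(f, "n_frames"),
               source_id = attr(f, "source_id"), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature archive written by [write_feature_archive()]
#' @param dir Archive directory.
#' @return List of `feature_matrix` objects.
#' @export
read_feature_archive <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(file.path(dir, manifest$file[i]),
                                     sep = "\t"))
    dimnames(m) <- NULL
    feature_matrix(m, manifest$kind[i], manifest$n_frames[i],
                   manifest$source_id[i])
  })
}
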