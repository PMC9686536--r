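# End-to-end orchestration: recordings -> filter -> endpoint detection ->
# per-call features -> chick-safe split -> training -> per-call scoring ->
# majority-vote sexing. These helpers process one recording at a time so a
# whole study never needs to sit in memory as audio.

#' Detect and featurize every call in one recording
#'
#' @param clip An [audio_clip] (raw; high-pass filtering is applied here).
#' @param kind Feature kind (see [call_features()]).
#' @param filter_spec A `filter_spec`; designed at the clip's rate if `NULL`.
#' @param det_config A [detector_config()].
#' @param window A [window_spec()].
#' @param bank Optional `mel_filter_bank`.
#' @param max_calls Cap on the number of (earliest) calls featurized.
#' @return List with `segments` (a `call_segments` table) and `features`
#'   (list of `feature_matrix`, one per segment).
#' @export
featurize_recording <- function(clip, kind = "mfcc_logfbank",
                                filter_spec = NULL,
                                det_config = detector_config(),
                                window = window_spec(), bank = NULL,
                                max_calls = Inf) {
  if (is.null(filter_spec))
    filter_spec <- design_highpass(sample_rate = clip$sample_rate)
  filtered <- apply_filter(clip, filter_spec)
  seg <- detect_in_recording(filtered, det_config, window)
  if (nrow(seg) > max_calls) seg <- seg[seq_len(max_calls), , drop = FALSE]
  feats <- lapply(seq_len(nrow(seg)), function(i) {
    call_features(extract_call_audio(filtered, seg[i, ]), kind,
                  window = window, bank = bank,
                  target_frames = det_config$max_frames)
  })
  list(segments = seg, features = feats)
}

#' Featurize a whole synthetic (or recorded) study
#'
#' Reads each chick's WAV, filters, detects and featurizes its calls.
#'
#' @param metadata Data frame with `chick_id`, `sex`, `wav` (and optionally
#'   `breed`), one row per chick, as produced by [generate_study()].
#' @param kind Feature kind.
#' @param ... Passed to [featurize_recording()].
#' @return List with `calls` (data frame: chick_id, breed, sex, call_index,
#'   segment extents) and `features` (list of `feature_matrix` aligned with
#'   `calls` rows).
#' @export
featurize_study <- function(metadata, kind = "mfcc_logfbank", ...) {
  calls <- list()
  features <- list()
  for (i in seq_len(nrow(metadata))) {
    clip <- read_wav(metadata$wav[i], source_id = metadata$chick_id[i])
    fr <- featurize_recording(clip, kind, ...)
    n <- nrow(fr$segments)
    if (n == 0L) next
    calls[[length(calls) + 1L]] <- data.frame(
      chick_id = metadata$chick_id[i],
      breed = if ("breed" %in% names(metadata)) metadata$breed[i] else NA,
      sex = metadata$sex[i],
      call_index = seq_len(n),
      start_sample = fr$segments$start_sample,
      end_sample = fr$segments$end_sample,
      stringsAsFactors = FALSE
    )
    features <- c(features, fr$features)
  }
  list(calls = do.call(rbind, c(calls, make.row.names = FALSE)),
       features = features)
}

manifest_array <- function(manifest_part, calls, features) {
  key <- paste(calls$chick_id, calls$call_index)
  ix <- match(paste(manifest_part$chick_id, manifest_part$call_index), key)
  if (any(is.na(ix))) stop("manifest refers to unknown calls")
  list(x = feature_array(features[ix]),
       y = as.numeric(manifest_part$sex == "cock"))
}

#' Train and evaluate one feature/architecture combination on a study
#'
#' Builds the chick-safe split, trains the classifier, scores the held-out
#' test calls, and majority-votes each test chick's sex over its first
#' `n_votes` detected calls.
#'
#' @param study_features Output of [featurize_study()].
#' @param architecture Classifier family (see [model_config()]).
#' @param width_multiplier Desk-scale width factor (default 0.25).
#' @param n_votes Calls per chick for voting (default 41).
#' @param test_fraction Held-out chick fraction per sex (default 0.2).
#' @param train_cfg A [train_config()].
#' @param seed Seed for the split and model initialization.
#' @return List with `call_accuracy`, `chick_accuracy`, `votes` (per-chick
#'   decisions), `history`, `manifest`, and the trained `model`.
#' @export
run_study_evaluation <- function(study_features, architecture = "cnn",
                                 width_multiplier = 0.25, n_votes = 41L,
                                 test_fraction = 0.2,
                                 train_cfg = train_config(max_epochs = 60,
                                                          patience = 15),
                                 seed = 1L) {
  calls <- study_features$calls
  features <- study_features$features
  manifest <- split_by_chick(calls, test_fraction, seed = seed,
                             test_calls_per_chick = n_votes)
  tr <- manifest_array(manifest$train, calls, features)
  va <- manifest_array(manifest$validation, calls, features)
  te <- manifest_array(manifest$test, calls, features)
  shape <- dim(tr$x)[2:3]
  model <- build_model(model_config(architecture,
                                    width_multiplier = width_multiplier,
                                    seed = seed), shape)
  model <- train(model, tr$x, tr$y, va$x, va$y, train_cfg)
  pred <- predict_calls(model, te$x)
  truth <- ifelse(te$y == 1, "cock", "hen")
  ev <- evaluate_predictions(truth, pred$label, manifest$test$chick_id)
  votes <- list()
  for (cid in manifest$test_chick_ids) {
    ix <- which(calls$chick_id == cid)
    ix <- ix[order(calls$call_index[ix])]
    if (length(ix) < n_votes) next
    votes[[cid]] <- sex_chick(model, features[ix], n_votes, chick_id = cid,
                              true_sex = calls$sex[ix[1L]])
  }
  correct <- vapply(votes, function(v) v$decided_sex == v$true_sex,
                    logical(1))
  list(call_accuracy = ev$call_accuracy,
       chick_accuracy = mean(correct),
       votes = votes, confusion = ev$confusion,
       history = model$history, manifest = manifest, model = model)
}

#' End-to-end synthetic sexing benchmark
#'
#' Generates a single-breed synthetic study with the given sex offset, runs
#' the full pipeline, and reports call- and chick-level accuracy. With the
#' default 400 Hz offset the sexes are cleanly separable; with offset 0 the
#' classes are identical by construction and accuracy sits at chance.
#'
#' @param n_chicks_per_sex Chicks per sex (default 20).
#' @param sex_offset_hz Planted acoustic sex difference (default 400).
#' @param feature_kind Feature family (default `"mfcc_logfbank"`).
#' @param architecture Classifier family (default `"cnn"`).
#' @param calls_per_chick Calls per recording (default 45).
#' @param width_multiplier,test_fraction,train_cfg,seed Passed through.
#' @return As [run_study_evaluation()], plus the study `metadata`.
#' @export
run_sexing_benchmark <- function(n_chicks_per_sex = 20, sex_offset_hz = 400,
                                 feature_kind = "mfcc_logfbank",
                                 architecture = "cnn", calls_per_chick = 45,
                                 width_multiplier = 0.25,
                                 test_fraction = 0.2,
                                 train_cfg = train_config(max_epochs = 60,
                                                          patience = 15),
                                 seed = 1L) {
  study <- generate_study(n_chicks_per_sex,
                          breed_profiles = c(synth = sex_offset_hz),
                          calls_per_chick = calls_per_chick, seed = seed)
  on.exit(unlink(study$dir, recursive = TRUE), add = TRUE)
  sf <- featurize_study(study$metadata, feature_kind)
  out <- run_study_evaluation(sf, architecture = architecture,
                              width_multiplier = width_multiplier,
                              test_fraction = test_fraction,
                              train_cfg = train_cfg, seed = seed)
  out$metadata <- study$metadata
  out
}

#' Cross-comparison grid
#'
#' Runs every breed-profile x feature x architecture combination of a
#' synthetic study at desk scale, mirroring the cross-comparison design
#' (each breed trained and tested on its own chicks).
#'
#' @param n_chicks_per_sex Chicks per sex per breed.
#' @param breed_profiles Named offsets as in [generate_study()].
#' @param features Feature kinds to include.
#' @param architectures Architectures to include.
#' @param ... Passed to [run_study_evaluation()].
#' @param seed Study seed.
#' @return Data frame: breed, feature, architecture, call_accuracy,
#'   chick_accuracy.
#' @export
run_experiment_grid <- function(n_chicks_per_sex = 6,
                                breed_profiles = c(synthA = 400,
                                                   synthB = 250,
                                                   synthC = 100),
                                features = c("mfcc_logfbank"),
                                architectures = c("cnn", "gru"),
                                seed = 1L, ...) {
  study <- generate_study(n_chicks_per_sex, breed_profiles, seed = seed)
  on.exit(unlink(study$dir, recursive = TRUE), add = TRUE)
  rows <- list()
  for (kind in features) {
    sf <- featurize_study(study$metadata, kind)
    for (breed in names(breed_profiles)) {
      keep <- sf$calls$breed == breed
      sub <- list(calls = sf$calls[keep, , drop = FALSE],
                  features = sf$features[keep])
      for (arch in architectures) {
        res <- run_study_evaluation(sub, architecture = arch, seed = seed,
                                    ...)
        rows[[length(rows) + 1L]] <- data.frame(
          breed = breed, feature = kind, architecture = arch,
          call_accuracy = res$call_accuracy,
          chick_accuracy = res$chick_accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
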