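# Chick-level dataset construction and sex decisions. The central rule is
# identity safety: calls of one bird are highly self-similar, so letting a
# bird's calls straddle the training and test sets inflates test accuracy.
# Splits are therefore made by chick, never by call, and each bird's sex is
# decided by majority vote over 41 of its calls (odd, hence tie-free).

#' Split a call table by chick identity
#'
#' Test chicks are sampled per sex at `test_fraction`; training and
#' validation calls are drawn only from the remaining (training) chicks at a
#' 5:1 ratio, and call counts are balanced between the sexes within every
#' partition. No chick identity ever appears in both the test and the
#' train/validation partitions.
#'
#' @param calls Data frame with columns `chick_id`, `sex` (`"cock"`/`"hen"`)
#'   and `call_index`; one row per call.
#' @param test_fraction Fraction of chicks per sex held out as test chicks
#'   (default 0.2, the full-scale study proportion).
#' @param seed Integer seed; a fixed seed reproduces the manifest exactly.
#' @param test_calls_per_chick Calls sampled per test chick for call-level
#'   scoring (default 41, the voting inventory).
#' @return A `split_manifest`: list of `train`, `validation`, `test` call
#'   tables, the test chick ids, and per-partition counts by sex.
#' @export
split_by_chick <- function(calls, test_fraction = 0.2, seed = 1L,
                           test_calls_per_chick = 41L) {
  stopifnot(all(c("chick_id", "sex", "call_index") %in% names(calls)))
  sexes <- c("cock", "hen")
  if (!all(calls$sex %in% sexes)) stop("sex must be 'cock' or 'hen'")
  chicks <- unique(calls[, c("chick_id", "sex")])
  n_by_sex <- table(factor(chicks$sex, sexes))
  if (any(n_by_sex < 2L)) stop("need at least 2 chicks per sex")
  n_test <- pmax(1L, round(test_fraction * as.integer(n_by_sex)))
  if (any(n_test >= as.integer(n_by_sex)))
    stop("test_fraction ", test_fraction, " leaves an empty training ",
         "partition for at least one sex")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  test_ids <- unlist(lapply(seq_along(sexes), function(i) {
    ids <- chicks$chick_id[chicks$sex == sexes[i]]
    sample(ids, n_test[i])
  }))
  pool <- calls[!(calls$chick_id %in% test_ids), , drop = FALSE]
  # balanced train/validation counts: 5:1 within each sex, equal across sexes
  n_pool <- min(table(factor(pool$sex, sexes)))
  n_val <- n_pool %/% 6L
  n_train <- 5L * n_val
  if (n_val < 1L) stop("too few training-chick calls to form a validation set")
  take <- function(df, n) df[sample.int(nrow(df), n), , drop = FALSE]
  tr <- list(); va <- list(); te <- list()
  for (s in sexes) {
    ps <- pool[pool$sex == s, , drop = FALSE]
    pick <- sample.int(nrow(ps), n_train + n_val)
    tr[[s]] <- ps[pick[seq_len(n_train)], , drop = FALSE]
    va[[s]] <- ps[pick[n_train + seq_len(n_val)], , drop = FALSE]
  }
  test_calls <- calls[calls$chick_id %in% test_ids, , drop = FALSE]
  te <- lapply(split(test_calls, test_calls$chick_id), function(df) {
    df <- df[order(df$call_index), , drop = FALSE]
    utils::head(df, test_calls_per_chick)
  })
  manifest <- list(train = do.call(rbind, c(tr, make.row.names = FALSE)),
                   validation = do.call(rbind, c(va, make.row.names = FALSE)),
                   test = do.call(rbind, c(unname(te),
                                           make.row.names = FALSE)),
                   test_chick_ids = sort(test_ids))
  manifest$counts <- sapply(manifest[c("train", "validation", "test")],
                            function(df) table(factor(df$sex, sexes)))
  class(manifest) <- "split_manifest"
  leak <- intersect(unique(c(manifest$train$chick_id,
                             manifest$validation$chick_id)),
                    manifest$test$chick_id)
  if (length(leak) > 0L)
    stop("internal error: chick identity leakage: ",
         paste(leak, collapse = ", "))
  manifest
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("<split_manifest>\n")
  print(x$counts)
  cat("test chicks:", length(x$test_chick_ids), "\n")
  invisible(x)
}

#' Majority vote over per-call labels
#'
#' The decided sex is the label with strictly more votes; the label count
#' must be odd (41 in the study protocol) so a tie is impossible.
#'
#' @param labels Character vector of per-call labels (`"cock"`/`"hen"`).
#' @param chick_id Optional identifier carried into the result.
#' @param true_sex Optional ground truth carried into the result.
#' @return A `vote_result`: `n_calls`, `cock_votes`, `hen_votes`,
#'   `decided_sex`, per-call labels, and the identifiers.
#' @export
majority_vote <- function(labels, chick_id = NA_character_,
                          true_sex = NULL) {
  n <- length(labels)
  if (n %% 2L == 0L)
    stop("majority voting needs an odd number of calls (got ", n,
         "): a tie would be possible")
  if (!all(labels %in% c("cock", "hen")))
    stop("labels must be 'cock' or 'hen'")
  cock <- sum(labels == "cock")
  structure(list(chick_id = chick_id, n_calls = n, cock_votes = cock,
                 hen_votes = n - cock,
                 decided_sex = if (cock > n - cock) "cock" else "hen",
                 labels = labels, true_sex = true_sex),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result %s: %d cock / %d hen -> %s%s>\n", x$chick_id,
              x$cock_votes, x$hen_votes, x$decided_sex,
              if (is.null(x$true_sex)) "" else
                paste0(" (true ", x$true_sex, ")")))
  invisible(x)
}

#' Decide one chick's sex
#'
#' Classifies the chick's first `n_votes` calls (earliest by detection time)
#' and majority-votes the per-call labels.
#'
#' @param model A trained `chick_classifier`.
#' @param features List of the chick's per-call `feature_matrix` objects in
#'   detection order.
#' @param n_votes Number of calls to vote over (default 41, must be odd).
#' @param chick_id,true_sex Carried into the result.
#' @return A `vote_result`.
#' @export
sex_chick <- function(model, features, n_votes = 41L,
                      chick_id = NA_character_, true_sex = NULL) {
  if (n_votes %% 2L == 0L) stop("n_votes must be odd")
  if (length(features) < n_votes)
    stop("insufficient calls for chick ", chick_id, ": has ",
         length(features), ", needs ", n_votes, " (short by ",
         n_votes - length(features), ")")
  x <- feature_array(features[seq_len(n_votes)])
  pred <- predict_calls(model, x)
  majority_vote(pred$label, chick_id = chick_id, true_sex = true_sex)
}

#' Evaluate call-level and chick-level accuracy
#'
#' @param truth Character vector of true per-call sexes.
#' @param predicted Character vector of predicted per-call labels, same
#'   order and length as `truth`.
#' @param chick_id Optional per-call chick identifiers; when given,
#'   chick-level accuracy is computed by majority vote within each chick
#'   (over the first odd number of its calls).
#' @return List with `call_accuracy`, `confusion` (truth x prediction
#'   table), and -- when `chick_id` is given -- `chick_accuracy` and a
#'   per-chick decision table.
#' @export
evaluate_predictions <- function(truth, predicted, chick_id = NULL) {
  if (length(truth) != length(predicted))
    stop("evaluation error: ", length(predicted), " predictions for ",
         length(truth), " truths")
  if (any(is.na(predicted)))
    stop("evaluation error: missing predictions at positions ",
         paste(utils::head(which(is.na(predicted)), 5L), collapse = ", "))
  out <- list(
    call_accuracy = mean(truth == predicted),
    confusion = table(truth = truth, predicted = predicted)
  )
  if (!is.null(chick_id)) {
    per <- lapply(split(seq_along(truth), chick_id), function(ix) {
      n <- length(ix)
      n_odd <- if (n %% 2L == 1L) n else n - 1L
      v <- majority_vote(predicted[ix][seq_len(n_odd)],
                         chick_id = chick_id[ix][1L],
                         true_sex = truth[ix][1L])
      data.frame(chick_id = v$chick_id, true_sex = v$true_sex,
                 decided_sex = v$decided_sex, n_calls = v$n_calls,
                 cock_votes = v$cock_votes, stringsAsFactors = FALSE)
    })
    decisions <- do.call(rbind, c(per, make.row.names = FALSE))
    out$chick_decisions <- decisions
    out$chick_accuracy <- mean(decisions$true_sex == decisions$decided_sex)
  }
  out
}
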