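make_call_table <- function(n_chicks_per_sex = 10, calls_per_chick = 45) {
  chicks <- expand.grid(i = seq_len(n_chicks_per_sex),
                        sex = c("cock", "hen"), stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(chicks)), function(r) {
    data.frame(chick_id = sprintf("%s%02d", chicks$sex[r], chicks$i[r]),
               sex = chicks$sex[r], call_index = seq_len(calls_per_chick),
               stringsAsFactors = FALSE)
  }))
}

test_that("splits are identity-safe: no chick straddles test and train", {
  calls <- make_call_table()
  for (seed in 1:10) {
    man <- split_by_chick(calls, 0.2, seed = seed)
    seen <- unique(c(man$train$chick_id, man$validation$chick_id))
    expect_length(intersect(seen, man$test$chick_id), 0)
    expect_length(intersect(seen, man$test_chick_ids), 0)
  }
})

test_that("splits balance the sexes and keep the 5:1 train:validation ratio", {
  man <- split_by_chick(make_call_table(), 0.2, seed = 3)
  expect_equal(man$counts["cock", "train"], man$counts["hen", "train"])
  expect_equal(man$counts["cock", "validation"],
               man$counts["hen", "validation"])
  expect_equal(sum(man$counts[, "train"]), 5 * sum(man$counts[, "validation"]))
  # test chicks per sex at the requested fraction
  expect_equal(length(man$test_chick_ids), 4)
})

test_that("split manifests are reproducible and reject bad fractions", {
  calls <- make_call_table(4)
  m1 <- split_by_chick(calls, 0.25, seed = 11)
  m2 <- split_by_chick(calls, 0.25, seed = 11)
  expect_identical(m1$test_chick_ids, m2$test_chick_ids)
  expect_identical(m1$train, m2$train)
  expect_error(split_by_chick(calls, 0.99, seed = 1), "empty")
  one <- calls[calls$chick_id %in% c("cock01", "hen01"), ]
  expect_error(split_by_chick(one, 0.2, seed = 1), "2 chicks per sex")
})

test_that("majority vote decides by strict majority and rejects even counts", {
  v <- majority_vote(rep("cock", 41))
  expect_equal(v$decided_sex, "cock")
  expect_equal(v$cock_votes, 41)
  v2 <- majority_vote(c(rep("cock", 21), rep("hen", 20)))
  expect_equal(v2$decided_sex, "cock")
  expect_equal(v2$cock_votes + v2$hen_votes, 41)
  v3 <- majority_vote(c(rep("cock", 20), rep("hen", 21)))
  expect_equal(v3$decided_sex, "hen")
  expect_error(majority_vote(rep("cock", 40)), "odd")
  expect_error(majority_vote(c("cock", "hen", "duck")), "cock")
})

test_that("voting amplifies per-call accuracy per the binomial tail", {
  # closed-form oracle: P(X >= 21), X ~ Bin(41, 0.7)
  tail_p <- stats::pbinom(20, 41, 0.7, lower.tail = FALSE)
  set.seed(19)
  n_rep <- 10000
  correct <- stats::rbinom(n_rep, 41, 0.7) >= 21
  mc <- mean(correct)
  se <- sqrt(tail_p * (1 - tail_p) / n_rep)
  expect_lt(abs(mc - tail_p), 3 * se)
  expect_gt(tail_p, 0.99)  # voting lifts 0.7 per-call far above itself
})

test_that("chick-level accuracy dominates per-call accuracy above chance", {
  for (p in c(0.6, 0.7, 0.85)) {
    expect_gte(stats::pbinom(20, 41, p, lower.tail = FALSE), p)
  }
})

test_that("sex_chick votes the first 41 calls and reports shortfalls", {
  m <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 1),
                   c(110, 52))
  feats <- lapply(1:41, function(i) {
    chicksex:::feature_matrix(matrix(0.1 * i, 110, 52), "mfcc_logfbank",
                              110, "f")
  })
  v <- sex_chick(m, feats, chick_id = "c1", true_sex = "hen")
  expect_s3_class(v, "vote_result")
  expect_equal(v$n_calls, 41)
  expect_equal(v$cock_votes + v$hen_votes, 41)
  expect_error(sex_chick(m, feats[1:30]), "short by 11")
  expect_error(sex_chick(m, feats, n_votes = 40), "odd")
})

test_that("vote decisions are invariant to call order", {
  labels <- c(rep("cock", 25), rep("hen", 16))
  set.seed(4)
  for (i in 1:5) {
    expect_equal(majority_vote(sample(labels))$decided_sex, "cock")
  }
})

test_that("evaluation reports call accuracy, confusion and chick votes", {
  truth <- rep(c("cock", "hen"), each = 10)
  expect_equal(evaluate_predictions(truth, truth)$call_accuracy, 1)
  allc <- evaluate_predictions(truth, rep("cock", 20))
  expect_equal(allc$call_accuracy, 0.5)
  set.seed(1)
  pred <- ifelse(stats::runif(20) < 0.8, truth, ifelse(truth == "cock",
                                                       "hen", "cock"))
  ids <- rep(c("a", "b", "c", "d"), each = 5)
  ev <- evaluate_predictions(truth, pred, ids)
  expect_true(ev$chick_accuracy >= 0 && ev$chick_accuracy <= 1)
  expect_equal(nrow(ev$chick_decisions), 4)
  # permutation invariance
  perm <- sample(20)
  ev2 <- evaluate_predictions(truth[perm], pred[perm], ids[perm])
  expect_equal(ev2$call_accuracy, ev$call_accuracy)
  expect_equal(ev2$chick_accuracy, ev$chick_accuracy)
  expect_error(evaluate_predictions(truth, pred[1:10]), "evaluation error")
  expect_error(evaluate_predictions(truth, rep(NA_character_, 20)),
               "missing predictions")
})
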