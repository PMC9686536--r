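test_that("CNN parameter count matches the closed-form layer arithmetic", {
  cf <- 8L
  m <- build_model(model_config("cnn", width_multiplier = cf / 64),
                   c(110, 52))
  # pooling geometry: 110x52 -> 36x17 -> 12x5 -> 4x1
  flat <- 4 * 1 * cf
  expected <- (3 * 3 * 1 * cf + cf) + 2 * (3 * 3 * cf * cf + cf) +
    (flat * 64 + 64) + (64 * 32 + 32) + (32 * 1 + 1)
  expect_equal(count_params(m), expected)
})

test_that("the residual network uses 3/4/6/3 bottleneck stages", {
  m <- build_model(model_config("resnet50", width_multiplier = 0.0625),
                   c(110, 52))
  expect_equal(m$block_counts, c(3L, 4L, 6L, 3L))
  ns <- asNamespace("chicksex")
  n_res <- sum(vapply(ns$flatten_layers(m$net), inherits, logical(1),
                      "nn_residual"))
  expect_equal(n_res, 16L)
})

test_that("builds are deterministic under a fixed seed", {
  ns <- asNamespace("chicksex")
  for (arch in c("cnn", "gru", "crnn", "twostream", "resnet50")) {
    cfg <- model_config(arch, width_multiplier = 0.0625, seed = 42)
    w1 <- ns$get_weights_tree(build_model(cfg, c(110, 52))$net)
    w2 <- ns$get_weights_tree(build_model(cfg, c(110, 52))$net)
    expect_identical(w1, w2)
  }
})

test_that("every architecture accepts all three feature widths", {
  ns <- asNamespace("chicksex")
  for (arch in c("cnn", "gru", "crnn", "twostream", "resnet50")) {
    for (d in c(513, 160, 52)) {
      m <- build_model(model_config(arch, width_multiplier = 0.0625, seed = 1),
                       c(110, d))
      z <- ns$nn_forward(m$net, array(0, c(2, 110, d)))
      expect_equal(dim(z), c(2L, 1L))
    }
  }
  expect_error(model_config("mlp"))
})

test_that("analytic gradients match finite differences away from kinks", {
  ns <- asNamespace("chicksex")
  for (arch in c("cnn", "gru", "crnn", "twostream")) {
    m <- build_model(model_config(arch, conv_filters = 3, gru_units = 3,
                                  seed = 5), c(33, 30))
    set.seed(9)
    x <- array(stats::rnorm(3 * 33 * 30), c(3, 33, 30))
    y <- c(1, 0, 1)
    loss_at <- function() {
      z <- as.numeric(ns$nn_forward(m$net, x, train = FALSE))
      ns$bce_with_logits(z, y)
    }
    z <- as.numeric(ns$nn_forward(m$net, x, train = FALSE))
    dz <- matrix((ns$sigmoid(z) - y) / 3, ncol = 1)
    ns$nn_backward(m$net, dz)
    for (l in ns$flatten_layers(m$net)) {
      for (nm in l$param_names) {
        g <- l[[paste0("d", nm)]]
        W <- l[[nm]]
        for (k in sample(length(W), min(2, length(W)))) {
          eps <- 1e-5
          Wk <- W
          Wk[k] <- W[k] + eps
          assign(nm, Wk, envir = l)
          lp <- loss_at()
          Wk[k] <- W[k] - eps
          assign(nm, Wk, envir = l)
          lm <- loss_at()
          assign(nm, W, envir = l)
          num <- (lp - lm) / (2 * eps)
          expect_lt(abs(num - g[k]) / max(1e-5, abs(num) + abs(g[k])), 1e-4)
        }
      }
    }
  }
})

test_that("a small CNN separates a separable fixture quickly", {
  tr <- separable_set(160, 1)
  va <- separable_set(60, 2)
  m <- build_model(model_config("cnn", width_multiplier = 0.125, seed = 1),
                   c(110, 52))
  m <- train(m, tr$x, tr$y, va$x, va$y,
             train_config(max_epochs = 50, patience = 15, seed = 1))
  expect_gte(m$history$best_val_acc, 0.95)
  expect_lte(m$history$stopped_epoch, 50)
})

test_that("shuffled labels leave validation accuracy at chance", {
  tr <- separable_set(160, 1, shuffle_labels = TRUE)
  va <- separable_set(200, 2, shuffle_labels = TRUE)
  m <- build_model(model_config("cnn", width_multiplier = 0.125, seed = 1),
                   c(110, 52))
  m <- train(m, tr$x, tr$y, va$x, va$y,
             train_config(max_epochs = 8, patience = 8, seed = 1))
  expect_lt(abs(m$history$best_val_acc - 0.5), 0.1)
})

test_that("early stopping halts after `patience` epochs without improvement", {
  tr <- separable_set(40, 1)
  va <- separable_set(20, 2)
  m <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 1),
                   c(110, 52))
  # zero learning rate: validation accuracy can never increase after epoch 1
  m <- train(m, tr$x, tr$y, va$x, va$y,
             train_config(max_epochs = 50, patience = 1, learning_rate = 0,
                          seed = 1))
  expect_equal(m$history$stopped_epoch, 2L)
  expect_equal(m$history$best_epoch, 1L)
})

test_that("the best epoch is never dominated by an earlier epoch", {
  tr <- separable_set(80, 3)
  va <- separable_set(40, 4)
  m <- build_model(model_config("gru", width_multiplier = 0.125, seed = 2),
                   c(110, 52))
  m <- train(m, tr$x, tr$y, va$x, va$y,
             train_config(max_epochs = 12, patience = 5, seed = 2))
  h <- m$history$metrics
  expect_equal(m$history$best_val_acc, max(h$val_acc))
  expect_equal(h$val_acc[m$history$best_epoch], max(h$val_acc))
})

test_that("training with a fixed seed is exactly reproducible", {
  tr <- separable_set(60, 5)
  va <- separable_set(30, 6)
  run <- function() {
    m <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 7),
                     c(110, 52))
    m <- train(m, tr$x, tr$y, va$x, va$y,
               train_config(max_epochs = 5, patience = 5, seed = 7))
    m$history$metrics
  }
  expect_identical(run(), run())
})

test_that("predictions are sigmoid probabilities, deterministic at inference", {
  tr <- separable_set(60, 5)
  m <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 1),
                   c(110, 52))
  p <- predict_calls(m, tr$x)
  expect_true(all(p$prob_cock >= 0 & p$prob_cock <= 1))
  expect_true(all(p$label %in% c("cock", "hen")))
  dup <- tr$x[c(1, 1, 2, 2), , , drop = FALSE]
  pd <- predict_calls(m, dup)
  expect_identical(pd$prob_cock[1], pd$prob_cock[2])
  expect_identical(pd$prob_cock[3], pd$prob_cock[4])
  expect_error(predict_calls(m, array(0, c(2, 110, 60))), "shape")
})

test_that("degenerate training inputs raise data errors", {
  tr <- separable_set(20, 1)
  m <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 1),
                   c(110, 52))
  expect_error(train(m, tr$x[0, , , drop = FALSE], numeric(0), tr$x, tr$y),
               "empty")
  expect_error(train(m, tr$x, tr$y[1:5], tr$x, tr$y), "inconsistent")
  m2 <- build_model(model_config("cnn", width_multiplier = 0.0625, seed = 1),
                    c(110, 160))
  expect_error(train(m2, tr$x, tr$y, tr$x, tr$y), "shape")
})

test_that("model weights round-trip and can seed a resnet build", {
  m <- build_model(model_config("resnet50", width_multiplier = 0.0625,
                                seed = 3), c(110, 52))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model_weights(m, path)
  m2 <- build_model(model_config("resnet50", width_multiplier = 0.0625,
                                 pretrained = path, seed = 99), c(110, 52))
  ns <- asNamespace("chicksex")
  expect_identical(ns$get_weights_tree(m$net), ns$get_weights_tree(m2$net))
  expect_error(model_config("cnn", pretrained = "x.rds"), "resnet50")
})
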