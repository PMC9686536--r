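# The five classifier families. Every architecture consumes a batch of
# feature matrices (n, 110, D) for any D in {513, 160, 52} and ends in the
# shared head: dense 64 -> relu -> dropout 0.2 -> dense 32 -> relu ->
# dense 1, trained as a sigmoid probability (cock = 1, hen = 0) with binary
# cross-entropy and Adam.

#' Classifier configuration
#'
#' @param architecture One of `"cnn"`, `"gru"`, `"crnn"`, `"twostream"`,
#'   `"resnet50"`.
#' @param conv_filters Convolution cores per layer at full scale (default 64).
#' @param gru_units Units per GRU layer at full scale (default 64).
#' @param width_multiplier Scale in (0, 1\] applied to `conv_filters`,
#'   `gru_units` and the residual-stage widths, so the same architectures run
#'   at desk scale; 1 reproduces the full-size networks.
#' @param pretrained `FALSE`, or (resnet50 only) a path to a weights file
#'   written by [save_model_weights()] used to initialize the network.
#' @param seed Integer seed for the parameter initialization.
#' @return A `model_config`.
#' @export
model_config <- function(architecture = c("cnn", "gru", "crnn", "twostream",
                                          "resnet50"),
                         conv_filters = 64, gru_units = 64,
                         width_multiplier = 1, pretrained = FALSE,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]")
  if (!identical(pretrained, FALSE) && architecture != "resnet50")
    stop("pretrained initialization is only available for resnet50")
  structure(list(architecture = architecture,
                 conv_filters = conv_filters, gru_units = gru_units,
                 width_multiplier = width_multiplier,
                 pretrained = pretrained, seed = as.integer(seed)),
            class = "model_config")
}

head_layers <- function(n_in) {
  list(l_dense(n_in, 64), l_relu(), l_dropout(0.2),
       l_dense(64, 32), l_relu(), l_dense(32, 1))
}

conv_stack <- function(cf, with_flatten = TRUE) {
  out <- list(l_expand(1),
              l_conv(1, cf), l_relu(), l_pool(3),
              l_conv(cf, cf), l_relu(), l_pool(3),
              l_conv(cf, cf), l_relu(), l_pool(3))
  if (with_flatten) out <- c(out, list(l_flatten()))
  out
}

probe_width <- function(layers, feature_shape) {
  x <- array(0, c(1L, feature_shape[1L], feature_shape[2L]))
  ncol(nn_forward(l_seq(layers), x, train = FALSE))
}

bottleneck <- function(in_c, width, stride) {
  out_c <- 4L * width
  body <- l_seq(list(
    l_conv(in_c, width, k = 1, stride = stride), l_bn(width), l_relu(),
    l_conv(width, width, k = 3), l_bn(width), l_relu(),
    l_conv(width, out_c, k = 1), l_bn(out_c)
  ))
  proj <- if (in_c != out_c || stride != 1L)
    l_seq(list(l_conv(in_c, out_c, k = 1, stride = stride), l_bn(out_c)))
  l_residual(body, proj)
}

resnet_layers <- function(wm) {
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * wm)))
  blocks <- c(3L, 4L, 6L, 3L)
  stem_c <- widths[1L]
  layers <- list(l_expand(3),
                 l_conv(3, stem_c, k = 7, stride = 2), l_bn(stem_c), l_relu(),
                 l_pool(3, stride = 2))
  in_c <- stem_c
  for (s in seq_len(4L)) {
    stride <- if (s == 1L) 1L else 2L
    for (b in seq_len(blocks[s])) {
      layers <- c(layers, list(bottleneck(in_c, widths[s],
                                          if (b == 1L) stride else 1L)))
      in_c <- 4L * widths[s]
    }
  }
  c(layers, list(l_gap()))
}

#' Build a classifier
#'
#' Architectures (at full scale): `cnn` = 3 x \[conv 64(3x3) -> maxpool 3x3\]
#' -> flatten -> head; `gru` = 2 stacked GRU(64) layers, last step -> head;
#' `crnn` = the conv stack -> time flatten -> 2 x GRU(64) -> head;
#' `twostream` = conv branch and GRU branch side by side, concatenated ->
#' head; `resnet50` = 7x7/2 stem, 4 stages of (3, 4, 6, 3) bottleneck blocks
#' with batch normalization, input replicated to 3 channels, global average
#' pool -> head.
#'
#' @param config A [model_config()].
#' @param feature_shape `c(frames, coefficients)` of the input feature
#'   matrices, e.g. `c(110, 52)`.
#' @return A `chick_classifier`.
#' @export
build_model <- function(config = model_config(), feature_shape = c(110, 52)) {
  stopifnot(inherits(config, "model_config"), length(feature_shape) == 2L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  wm <- config$width_multiplier
  cf <- max(1L, as.integer(round(config$conv_filters * wm)))
  gu <- max(1L, as.integer(round(config$gru_units * wm)))
  D <- feature_shape[2L]
  block_counts <- NULL
  layers <- switch(config$architecture,
    cnn = {
      stack <- conv_stack(cf)
      c(stack, head_layers(probe_width(stack, feature_shape)))
    },
    gru = c(list(l_gru(D, gu, return_seq = TRUE), l_gru(gu, gu)),
            head_layers(gu)),
    crnn = {
      stack <- c(conv_stack(cf, with_flatten = FALSE), list(l_timeflatten()))
      x <- array(0, c(1L, feature_shape[1L], feature_shape[2L]))
      w <- dim(nn_forward(l_seq(stack), x, train = FALSE))[3L]
      c(stack, list(l_gru(w, gu, return_seq = TRUE), l_gru(gu, gu)),
        head_layers(gu))
    },
    twostream = {
      conv_b <- l_seq(conv_stack(cf))
      gru_b <- l_seq(list(l_gru(D, gu, return_seq = TRUE), l_gru(gu, gu)))
      wc <- probe_width(list(conv_b), feature_shape)
      c(list(l_par(list(conv_b, gru_b))), head_layers(wc + gu))
    },
    resnet50 = {
      block_counts <- c(3L, 4L, 6L, 3L)
      stack <- resnet_layers(wm)
      c(stack, head_layers(probe_width(stack, feature_shape)))
    }
  )
  net <- l_seq(layers)
  model <- structure(
    list(net = net, config = config,
         feature_shape = as.integer(feature_shape),
         block_counts = block_counts,
         param_count = layer_param_count(net)),
    class = "chick_classifier"
  )
  if (!identical(config$pretrained, FALSE))
    load_model_weights(model, config$pretrained)
  model
}

#' @export
print.chick_classifier <- function(x, ...) {
  cat(sprintf("<chick_classifier %s: input %d x %d, %s parameters%s>\n",
              x$config$architecture, x$feature_shape[1L], x$feature_shape[2L],
              format(x$param_count, big.mark = ","),
              if (is.null(x$block_counts)) "" else
                paste0(", blocks ", paste(x$block_counts, collapse = "/"))))
  invisible(x)
}

#' Training configuration
#'
#' Early stopping monitors validation accuracy: if it has not increased for
#' `patience` epochs, training stops and the parameters of the best epoch are
#' restored.
#'
#' @param max_epochs Epoch cap (default 2000; the recurrent models converge
#'   slowest).
#' @param patience Early-stopping patience in epochs (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3; other Adam moments at
#'   their usual defaults).
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(max_epochs = 2000, patience = 100, batch_size = 32,
                         learning_rate = 1e-3, seed = 1L) {
  if (patience < 1) stop("patience must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

predict_logits <- function(model, x, chunk = 256L) {
  n <- dim(x)[1L]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e] <- nn_forward(model$net, x[s:e, , , drop = FALSE], train = FALSE)
  }
  out
}

#' Train a classifier
#'
#' Adam optimization of binary cross-entropy with validation-accuracy early
#' stopping; the reported model carries the best epoch's parameters. Fully
#' reproducible under a fixed `config$seed`.
#'
#' @param model A `chick_classifier` from [build_model()].
#' @param x,y Training features (`n` x frames x coefficients array) and
#'   binary labels (cock = 1, hen = 0).
#' @param x_val,y_val Validation set, monitored for early stopping.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The model, with `$history` (per-epoch losses/accuracies,
#'   `best_epoch`, `stopped_epoch`) attached.
#' @export
train <- function(model, x, y, x_val, y_val, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "chick_classifier"),
            inherits(config, "train_config"))
  n <- dim(x)[1L]
  if (n == 0L || length(y) != n) stop("empty or inconsistent training set")
  if (dim(x_val)[1L] == 0L) stop("empty validation set")
  if (!all(dim(x)[2:3] == model$feature_shape))
    stop("feature shape ", paste(dim(x)[2:3], collapse = "x"),
         " does not match model input ",
         paste(model$feature_shape, collapse = "x"))
  y <- as.numeric(y)
  y_val <- as.numeric(y_val)
  set.seed(config$seed)
  layers <- flatten_layers(model$net)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best_acc <- -Inf
  best_epoch <- 0L
  best_w <- NULL
  step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    tl <- 0; ta <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      e <- min(n, s + config$batch_size - 1L)
      bi <- idx[s:e]
      xb <- x[bi, , , drop = FALSE]
      yb <- y[bi]
      z <- as.numeric(nn_forward(model$net, xb, train = TRUE))
      if (any(!is.finite(z)))
        stop("training failure: non-finite activations at epoch ", epoch)
      p <- sigmoid(z)
      loss <- bce_with_logits(z, yb)
      tl <- tl + loss * length(bi)
      ta <- ta + sum((p > 0.5) == (yb > 0.5))
      dz <- matrix((p - yb) / length(bi), ncol = 1L)
      nn_backward(model$net, dz)
      step <- step + 1L
      adam_step(layers, config$learning_rate, step)
    }
    zv <- predict_logits(model, x_val)
    vl <- bce_with_logits(zv, y_val)
    va <- mean((sigmoid(zv) > 0.5) == (y_val > 0.5))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                   train_acc = ta / n, val_loss = vl,
                                   val_acc = va))
    if (verbose)
      message(sprintf("epoch %3d loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tl / n, ta / n, vl, va))
    if (va > best_acc) {
      best_acc <- va
      best_epoch <- epoch
      best_w <- get_weights_tree(model$net)
    }
    if (epoch - best_epoch >= config$patience) break
  }
  if (!is.null(best_w)) set_weights_tree(model$net, best_w)
  model$history <- structure(list(metrics = hist, best_epoch = best_epoch,
                                  stopped_epoch = nrow(hist),
                                  best_val_acc = best_acc),
                             class = "train_history")
  model$trained <- TRUE
  model
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history: %d epochs, best epoch %d (val acc %.3f)>\n",
              x$stopped_epoch, x$best_epoch, x$best_val_acc))
  invisible(x)
}

#' Per-call predictions
#'
#' @param model A trained `chick_classifier`.
#' @param x Feature batch: `n` x frames x coefficients array, a single
#'   `feature_matrix`, or a list of them.
#' @return Data frame with `prob_cock` (sigmoid probability) and `label`
#'   (`"cock"` if probability > 0.5, else `"hen"`).
#' @export
predict_calls <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- feature_array(list(x))
  if (is.list(x)) x <- feature_array(x)
  if (length(dim(x)) != 3L || !all(dim(x)[2:3] == model$feature_shape))
    stop("feature batch shape does not match model input ",
         paste(model$feature_shape, collapse = "x"))
  p <- sigmoid(predict_logits(model, x))
  data.frame(prob_cock = p, label = ifelse(p > 0.5, "cock", "hen"),
             stringsAsFactors = FALSE)
}

#' Save / load model weights
#'
#' Weights (and batchnorm running statistics) round-trip through an RDS
#' file; a weights file for a matching architecture can seed a new build via
#' `model_config(pretrained = path)`.
#'
#' @param model A `chick_classifier`.
#' @param path Weights file.
#' @return `path` (save) or the model (load), invisibly.
#' @export
save_model_weights <- function(model, path) {
  saveRDS(get_weights_tree(model$net), path)
  invisible(path)
}

#' @rdname save_model_weights
#' @export
load_model_weights <- function(model, path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  set_weights_tree(model$net, readRDS(path))
  invisible(model)
}

#' Total trainable parameter count
#' @param model A `chick_classifier`.
#' @return Integer count of trainable parameters.
#' @export
count_params <- function(model) model$param_count
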