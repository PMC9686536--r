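# Minimal reverse-mode neural-network layers. Layers are environments holding
# parameters (W, b, ...), their gradients (dW, db, ...) and a forward cache;
# nn_forward()/nn_backward() dispatch on class. Batch layout is column-major
# R arrays with the batch first: (n, T, D) for sequences, (n, H, W, C) for
# images, (n, k) for dense activations. Convolutions use im2col so the inner
# loop is one BLAS matrix product per batch.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$param_names)) e$param_names <- character(0)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dy) UseMethod("nn_backward")

# He-style gaussian init
w_init <- function(n_in, n_out, fan_in = n_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

## ---- dense ----------------------------------------------------------------

l_dense <- function(n_in, n_out) {
  new_layer("dense", W = w_init(n_in, n_out), b = rep(0, n_out),
            param_names = c("W", "b"))
}

#' @export
nn_forward.nn_dense <- function(layer, x, train = FALSE) {
  layer$x <- x
  x %*% layer$W + rep(layer$b, each = nrow(x))
}

#' @export
nn_backward.nn_dense <- function(layer, dy) {
  layer$dW <- crossprod(layer$x, dy)
  layer$db <- colSums(dy)
  dy %*% t(layer$W)
}

## ---- activations / dropout ------------------------------------------------

l_relu <- function() new_layer("relu")

#' @export
nn_forward.nn_relu <- function(layer, x, train = FALSE) {
  layer$mask <- x > 0
  x * layer$mask
}

#' @export
nn_backward.nn_relu <- function(layer, dy) dy * layer$mask

l_dropout <- function(p) new_layer("dropout", p = p)

#' @export
nn_forward.nn_dropout <- function(layer, x, train = FALSE) {
  if (!train || layer$p <= 0) {
    layer$mask <- NULL
    return(x)
  }
  m <- (stats::runif(length(x)) > layer$p) / (1 - layer$p)
  dim(m) <- dim(x)
  layer$mask <- m
  x * m
}

#' @export
nn_backward.nn_dropout <- function(layer, dy) {
  if (is.null(layer$mask)) dy else dy * layer$mask
}

## ---- shape plumbing -------------------------------------------------------

# (n, d1, d2, ...) -> (n, prod)
l_flatten <- function() new_layer("flatten")

#' @export
nn_forward.nn_flatten <- function(layer, x, train = FALSE) {
  layer$in_dim <- dim(x)
  dim(x) <- c(dim(x)[1L], prod(dim(x)[-1L]))
  x
}

#' @export
nn_backward.nn_flatten <- function(layer, dy) {
  dim(dy) <- layer$in_dim
  dy
}

# (n, T, D) -> (n, T, D, k): replicate a single-channel matrix across k
# channels (k = 3 feeds the matrix to the 3-channel residual network).
l_expand <- function(k) new_layer("expand", k = k)

#' @export
nn_forward.nn_expand <- function(layer, x, train = FALSE) {
  array(x, c(dim(x), layer$k))
}

#' @export
nn_backward.nn_expand <- function(layer, dy) {
  d <- dim(dy)
  dim(dy) <- c(prod(d[-4L]), d[4L])
  dx <- rowSums(dy)
  dim(dx) <- d[-4L]
  dx
}

# (n, T, W, C) -> (n, T, W*C): "time flatten", temporal order preserved.
l_timeflatten <- function() new_layer("timeflatten")

#' @export
nn_forward.nn_timeflatten <- function(layer, x, train = FALSE) {
  layer$in_dim <- dim(x)
  dim(x) <- c(dim(x)[1L], dim(x)[2L], prod(dim(x)[3:4]))
  x
}

#' @export
nn_backward.nn_timeflatten <- function(layer, dy) {
  dim(dy) <- layer$in_dim
  dy
}

## ---- convolution ----------------------------------------------------------

# 2-D convolution, "same" padding, odd or even kernel, arbitrary stride.
# W is stored as a (k*k*in_c) x out_c matrix matching the im2col layout.
l_conv <- function(in_c, out_c, k = 3, stride = 1) {
  new_layer("conv",
            W = w_init(k * k * in_c, out_c, fan_in = k * k * in_c),
            b = rep(0, out_c),
            k = as.integer(k), stride = as.integer(stride),
            in_c = as.integer(in_c), out_c = as.integer(out_c),
            param_names = c("W", "b"))
}

conv_geometry <- function(H, W, k, s) {
  oh <- as.integer(ceiling(H / s)); ow <- as.integer(ceiling(W / s))
  ph <- max((oh - 1L) * s + k - H, 0L); pw <- max((ow - 1L) * s + k - W, 0L)
  list(oh = oh, ow = ow,
       pt = ph %/% 2L, pb = ph - ph %/% 2L,
       pl = pw %/% 2L, pr = pw - pw %/% 2L)
}

# Linear indices into the padded (n, PH, PW, C) array of the (ki, kj) patch
# slice, in the column-major order of an (n, oh, ow, C) block. One list entry
# per kernel offset; cached per (n, geometry) on the layer.
patch_indices <- function(n, PH, PW, C, k, s, oh, ow) {
  rows <- seq(0L, by = s, length.out = oh)
  cols <- seq(0L, by = s, length.out = ow)
  ch <- seq(0L, length.out = C)
  idx <- vector("list", k * k)
  o <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      o <- o + 1L
      base_r <- (rows + ki - 1L) * n
      base_c <- (cols + kj - 1L) * (n * PH)
      base_ch <- ch * (n * PH * PW)
      idx[[o]] <- rep(seq_len(n), times = oh * ow * C) +
        rep(rep(base_r, each = n), times = ow * C) +
        rep(rep(base_c, each = n * oh), times = C) +
        rep(base_ch, each = n * oh * ow)
    }
  }
  idx
}

conv_indices <- function(layer, n, H, Wd, C, g) {
  key <- paste(n, H, Wd, C, sep = "x")
  if (is.null(layer$idx_cache)) layer$idx_cache <- list()
  if (is.null(layer$idx_cache[[key]]))
    layer$idx_cache[[key]] <- patch_indices(n, H + g$pt + g$pb,
                                            Wd + g$pl + g$pr, C,
                                            layer$k, layer$stride, g$oh, g$ow)
  layer$idx_cache[[key]]
}

#' @export
nn_forward.nn_conv <- function(layer, x, train = FALSE) {
  d <- dim(x)
  n <- d[1L]; H <- d[2L]; Wd <- d[3L]; C <- d[4L]
  k <- layer$k
  g <- conv_geometry(H, Wd, k, layer$stride)
  xp <- array(0, c(n, H + g$pt + g$pb, Wd + g$pl + g$pr, C))
  xp[, g$pt + seq_len(H), g$pl + seq_len(Wd), ] <- x
  idx <- conv_indices(layer, n, H, Wd, C, g)
  nb <- n * g$oh * g$ow
  P <- matrix(0, nb, k * k * C)
  for (o in seq_len(k * k))
    P[, (o - 1L) * C + seq_len(C)] <- xp[idx[[o]]]
  out <- P %*% layer$W + rep(layer$b, each = nb)
  dim(out) <- c(n, g$oh, g$ow, layer$out_c)
  layer$P <- P
  layer$geom <- g
  layer$in_dim <- d
  out
}

#' @export
nn_backward.nn_conv <- function(layer, dy) {
  g <- layer$geom; d <- layer$in_dim
  n <- d[1L]; H <- d[2L]; Wd <- d[3L]; C <- d[4L]
  k <- layer$k
  dim(dy) <- c(n * g$oh * g$ow, layer$out_c)
  layer$dW <- crossprod(layer$P, dy)
  layer$db <- colSums(dy)
  dP <- dy %*% t(layer$W)
  dxp <- numeric(n * (H + g$pt + g$pb) * (Wd + g$pl + g$pr) * C)
  idx <- conv_indices(layer, n, H, Wd, C, g)
  for (o in seq_len(k * k)) {
    io <- idx[[o]]
    dxp[io] <- dxp[io] + dP[, (o - 1L) * C + seq_len(C)]
  }
  dim(dxp) <- c(n, H + g$pt + g$pb, Wd + g$pl + g$pr, C)
  dxp[, g$pt + seq_len(H), g$pl + seq_len(Wd), , drop = FALSE]
}

## ---- max pooling ----------------------------------------------------------

# size x size max pooling, stride = size unless given, valid (floor) extent.
l_pool <- function(size = 3, stride = size) {
  new_layer("pool", size = as.integer(size), stride = as.integer(stride))
}

pool_geometry <- function(H, W, k, s) {
  list(oh = as.integer((H - k) %/% s + 1L), ow = as.integer((W - k) %/% s + 1L))
}

pool_indices <- function(layer, n, H, Wd, C, g) {
  key <- paste(n, H, Wd, C, sep = "x")
  if (is.null(layer$idx_cache)) layer$idx_cache <- list()
  if (is.null(layer$idx_cache[[key]]))
    layer$idx_cache[[key]] <- patch_indices(n, H, Wd, C, layer$size,
                                            layer$stride, g$oh, g$ow)
  layer$idx_cache[[key]]
}

#' @export
nn_forward.nn_pool <- function(layer, x, train = FALSE) {
  d <- dim(x)
  k <- layer$size
  g <- pool_geometry(d[2L], d[3L], k, layer$stride)
  if (g$oh < 1L || g$ow < 1L)
    stop("pooling window (", k, ") larger than input (", d[2L], "x", d[3L], ")")
  idx <- pool_indices(layer, d[1L], d[2L], d[3L], d[4L], g)
  out <- x[idx[[1L]]]
  argmax <- rep.int(1L, length(out))
  for (o in seq(2L, k * k)) {
    v <- x[idx[[o]]]
    gt <- v > out
    out[gt] <- v[gt]
    argmax[gt] <- o
  }
  dim(out) <- c(d[1L], g$oh, g$ow, d[4L])
  layer$argmax <- argmax
  layer$geom <- g
  layer$in_dim <- d
  out
}

#' @export
nn_backward.nn_pool <- function(layer, dy) {
  d <- layer$in_dim
  k <- layer$size
  g <- layer$geom
  idx <- pool_indices(layer, d[1L], d[2L], d[3L], d[4L], g)
  dx <- numeric(prod(d))
  dyv <- as.numeric(dy)
  for (o in seq_len(k * k)) {
    sel <- layer$argmax == o
    io <- idx[[o]][sel]
    dx[io] <- dx[io] + dyv[sel]
  }
  dim(dx) <- d
  dx
}

## ---- batch normalization --------------------------------------------------

# Per-channel batchnorm over (n, H, W); running stats for inference.
l_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", gamma = rep(1, C), beta = rep(0, C),
            run_mean = rep(0, C), run_var = rep(1, C),
            momentum = momentum, eps = eps, C = as.integer(C),
            param_names = c("gamma", "beta"))
}

#' @export
nn_forward.nn_bn <- function(layer, x, train = FALSE) {
  d <- dim(x)
  C <- layer$C
  xm <- x
  dim(xm) <- c(prod(d[-length(d)]), C)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  istd <- 1 / sqrt(va + layer$eps)
  N <- nrow(xm)
  xhat <- (xm - rep(mu, each = N)) * rep(istd, each = N)
  out <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  layer$xhat <- xhat
  layer$istd <- istd
  layer$train_mode <- train
  layer$in_dim <- d
  dim(out) <- d
  out
}

#' @export
nn_backward.nn_bn <- function(layer, dy) {
  d <- layer$in_dim
  C <- layer$C
  dim(dy) <- c(prod(d[-length(d)]), C)
  N <- nrow(dy)
  layer$dgamma <- colSums(dy * layer$xhat)
  layer$dbeta <- colSums(dy)
  if (isTRUE(layer$train_mode)) {
    dx <- (dy - rep(layer$dbeta / N, each = N) -
             layer$xhat * rep(layer$dgamma / N, each = N)) *
      rep(layer$gamma * layer$istd, each = N)
  } else {
    dx <- dy * rep(layer$gamma * layer$istd, each = N)
  }
  dim(dx) <- d
  dx
}

## ---- global average pooling ----------------------------------------------

l_gap <- function() new_layer("gap")

#' @export
nn_forward.nn_gap <- function(layer, x, train = FALSE) {
  d <- dim(x)
  layer$in_dim <- d
  x3 <- x
  dim(x3) <- c(d[1L], d[2L] * d[3L], d[4L])
  out <- matrix(0, d[1L], d[4L])
  for (j in seq_len(d[2L] * d[3L])) out <- out + x3[, j, ]
  out / (d[2L] * d[3L])
}

#' @export
nn_backward.nn_gap <- function(layer, dy) {
  d <- layer$in_dim
  hw <- d[2L] * d[3L]
  dx <- array(0, c(d[1L], hw, d[4L]))
  g <- dy / hw
  for (j in seq_len(hw)) dx[, j, ] <- g
  dim(dx) <- d
  dx
}

## ---- GRU ------------------------------------------------------------------

# Gated recurrent unit: z = sig(xWz + hUz + bz), r = sig(xWr + hUr + br),
# c = tanh(xWh + (r*h)Uh + bh), h' = (1-z)*h + z*c. Input (n, T, D);
# returns the full sequence (n, T, H) or the last step (n, H).
l_gru <- function(n_in, units, return_seq = FALSE) {
  sc <- sqrt(1 / n_in); sh <- sqrt(1 / units)
  rw <- function(a, b, s) matrix(stats::rnorm(a * b, sd = s), a, b)
  new_layer("gru",
            Wz = rw(n_in, units, sc), Wr = rw(n_in, units, sc),
            Wh = rw(n_in, units, sc),
            Uz = rw(units, units, sh), Ur = rw(units, units, sh),
            Uh = rw(units, units, sh),
            bz = rep(0, units), br = rep(0, units), bh = rep(0, units),
            units = as.integer(units), n_in = as.integer(n_in),
            return_seq = return_seq,
            param_names = c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh",
                            "bz", "br", "bh"))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @export
nn_forward.nn_gru <- function(layer, x, train = FALSE) {
  d <- dim(x)
  n <- d[1L]; Tt <- d[2L]
  H <- layer$units
  h <- matrix(0, n, H)
  layer$cache <- vector("list", Tt)
  if (layer$return_seq) seq_out <- array(0, c(n, Tt, H))
  for (t in seq_len(Tt)) {
    xt <- x[, t, , drop = TRUE]
    if (n == 1L) xt <- matrix(xt, 1L)
    z <- sigmoid(sweep(xt %*% layer$Wz + h %*% layer$Uz, 2L, layer$bz, "+"))
    r <- sigmoid(sweep(xt %*% layer$Wr + h %*% layer$Ur, 2L, layer$br, "+"))
    cc <- tanh(sweep(xt %*% layer$Wh + (r * h) %*% layer$Uh, 2L, layer$bh, "+"))
    h_new <- (1 - z) * h + z * cc
    layer$cache[[t]] <- list(x = xt, z = z, r = r, cc = cc, h_prev = h)
    h <- h_new
    if (layer$return_seq) seq_out[, t, ] <- h
  }
  layer$in_dim <- d
  if (layer$return_seq) seq_out else h
}

#' @export
nn_backward.nn_gru <- function(layer, dy) {
  d <- layer$in_dim
  n <- d[1L]; Tt <- d[2L]; D <- d[3L]
  H <- layer$units
  zero <- function(a, b) matrix(0, a, b)
  dWz <- zero(D, H); dWr <- zero(D, H); dWh <- zero(D, H)
  dUz <- zero(H, H); dUr <- zero(H, H); dUh <- zero(H, H)
  dbz <- rep(0, H); dbr <- rep(0, H); dbh <- rep(0, H)
  dx <- array(0, d)
  dh <- if (layer$return_seq) zero(n, H) else dy
  for (t in rev(seq_len(Tt))) {
    if (layer$return_seq) dh <- dh + matrix(dy[, t, ], n, H)
    cc_ <- layer$cache[[t]]
    z <- cc_$z; r <- cc_$r; cc <- cc_$cc; h_prev <- cc_$h_prev; xt <- cc_$x
    dcc <- dh * z
    dz <- dh * (cc - h_prev)
    dh_prev <- dh * (1 - z)
    dcc_pre <- dcc * (1 - cc^2)
    dz_pre <- dz * z * (1 - z)
    drh <- dcc_pre %*% t(layer$Uh)
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    dr_pre <- dr * r * (1 - r)
    dWh <- dWh + crossprod(xt, dcc_pre)
    dUh <- dUh + crossprod(r * h_prev, dcc_pre)
    dbh <- dbh + colSums(dcc_pre)
    dWz <- dWz + crossprod(xt, dz_pre)
    dUz <- dUz + crossprod(h_prev, dz_pre)
    dbz <- dbz + colSums(dz_pre)
    dWr <- dWr + crossprod(xt, dr_pre)
    dUr <- dUr + crossprod(h_prev, dr_pre)
    dbr <- dbr + colSums(dr_pre)
    dh_prev <- dh_prev + dz_pre %*% t(layer$Uz) + dr_pre %*% t(layer$Ur)
    dx[, t, ] <- dcc_pre %*% t(layer$Wh) + dz_pre %*% t(layer$Wz) +
      dr_pre %*% t(layer$Wr)
    dh <- dh_prev
  }
  layer$dWz <- dWz; layer$dWr <- dWr; layer$dWh <- dWh
  layer$dUz <- dUz; layer$dUr <- dUr; layer$dUh <- dUh
  layer$dbz <- dbz; layer$dbr <- dbr; layer$dbh <- dbh
  dx
}

## ---- composites -----------------------------------------------------------

l_seq <- function(layers) new_layer("seq", layers = layers)

#' @export
nn_forward.nn_seq <- function(layer, x, train = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, train)
  x
}

#' @export
nn_backward.nn_seq <- function(layer, dy) {
  for (l in rev(layer$layers)) dy <- nn_backward(l, dy)
  dy
}

# Residual block: out = relu(body(x) + shortcut(x)); shortcut is the
# identity or a projection (1x1 conv + bn).
l_residual <- function(body, proj = NULL) {
  new_layer("residual", body = body, proj = proj)
}

#' @export
nn_forward.nn_residual <- function(layer, x, train = FALSE) {
  b <- nn_forward(layer$body, x, train)
  s <- if (is.null(layer$proj)) x else nn_forward(layer$proj, x, train)
  out <- b + s
  layer$mask <- out > 0
  out * layer$mask
}

#' @export
nn_backward.nn_residual <- function(layer, dy) {
  dy <- dy * layer$mask
  dx <- nn_backward(layer$body, dy)
  ds <- if (is.null(layer$proj)) dy else nn_backward(layer$proj, dy)
  dx + ds
}

# Parallel branches fed the same input, outputs (n, k_i) concatenated.
l_par <- function(branches) new_layer("par", branches = branches)

#' @export
nn_forward.nn_par <- function(layer, x, train = FALSE) {
  outs <- lapply(layer$branches, nn_forward, x = x, train = train)
  layer$widths <- vapply(outs, ncol, integer(1))
  do.call(cbind, outs)
}

#' @export
nn_backward.nn_par <- function(layer, dy) {
  off <- 0L
  dx <- NULL
  for (i in seq_along(layer$branches)) {
    w <- layer$widths[i]
    g <- nn_backward(layer$branches[[i]], dy[, off + seq_len(w), drop = FALSE])
    dx <- if (is.null(dx)) g else dx + g
    off <- off + w
  }
  dx
}

## ---- parameter bookkeeping ------------------------------------------------

# Flatten a layer tree into the list of primitive layers (those with params
# or state of their own).
flatten_layers <- function(layer) {
  if (inherits(layer, "nn_seq"))
    return(unlist(lapply(layer$layers, flatten_layers), recursive = FALSE))
  if (inherits(layer, "nn_residual")) {
    out <- flatten_layers(layer$body)
    if (!is.null(layer$proj)) out <- c(out, flatten_layers(layer$proj))
    return(c(out, list(layer)))
  }
  if (inherits(layer, "nn_par"))
    return(unlist(lapply(layer$branches, flatten_layers), recursive = FALSE))
  list(layer)
}

layer_param_count <- function(layer) {
  sum(vapply(flatten_layers(layer), function(l) {
    sum(vapply(l$param_names, function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

get_weights_tree <- function(layer) {
  lapply(flatten_layers(layer), function(l) {
    w <- lapply(l$param_names, function(nm) l[[nm]])
    names(w) <- l$param_names
    if (inherits(l, "nn_bn")) {
      w$run_mean <- l$run_mean
      w$run_var <- l$run_var
    }
    w
  })
}

set_weights_tree <- function(layer, weights) {
  ls <- flatten_layers(layer)
  stopifnot(length(ls) == length(weights))
  for (i in seq_along(ls)) {
    for (nm in names(weights[[i]])) assign(nm, weights[[i]][[nm]], envir = ls[[i]])
  }
  invisible(layer)
}

## ---- Adam -----------------------------------------------------------------

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in layers) {
    for (nm in l$param_names) {
      g <- l[[paste0("d", nm)]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", nm)
      vkey <- paste0("adam_v_", nm)
      m <- if (is.null(l[[mkey]])) g * 0 else l[[mkey]]
      v <- if (is.null(l[[vkey]])) g * 0 else l[[vkey]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mkey, m, envir = l)
      assign(vkey, v, envir = l)
      assign(nm, l[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = l)
    }
  }
}
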