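# The two sliding-window pixel classifiers: a four-class gland/background x
# benign/malignant network ("object" variant) and a binary gland-separator
# network ("separator" variant). Both are LeNet-style stacks of K = 7 weighted
# layers: four valid convolutions (ReLU), 2x2 max-pooling after the first
# three, and three fully connected layers ending in a softmax. Forward and
# backward passes are written against BLAS matrix products; the batch axis is
# the first dimension of every activation array (N, H, W, C).

#' Construct a network specification
#'
#' Low-level constructor validating the fixed topology (four convolutional +
#' three fully connected weighted layers, max-pooling after convolutions 1-3).
#' [build_network()] supplies the canonical full-scale filter counts; this
#' constructor also admits reduced instances of the same topology for
#' desk-scale experiments.
#'
#' @param variant `"object"` (four output classes) or `"separator"` (two).
#' @param input_size odd patch edge length the network is applied to.
#' @param conv_filters integer vector of 4 filter counts.
#' @param conv_kernels integer vector of 4 odd kernel sizes.
#' @param fc_units integer vector of 2 hidden fully connected layer sizes.
#' @param n_classes number of output units (defaults to 4 for `"object"`,
#'   2 for `"separator"`).
#' @return object of class `"network_spec"`.
#' @export
network_spec <- function(variant = c("object", "separator"),
                         input_size = 101L,
                         conv_filters = c(80L, 96L, 128L, 160L),
                         conv_kernels = if (match.arg(variant) == "object")
                           c(11L, 7L, 5L, 3L) else c(9L, 7L, 5L, 3L),
                         fc_units = c(1024L, 512L),
                         n_classes = if (match.arg(variant) == "object") 4L else 2L) {
  variant <- match.arg(variant)
  if (length(conv_filters) != 4L || length(conv_kernels) != 4L)
    stop("the architecture has exactly four convolutional layers", call. = FALSE)
  if (length(fc_units) != 2L)
    stop("the architecture has two hidden fully connected layers", call. = FALSE)
  layers <- list()
  size <- as.integer(input_size)
  channels <- 1L
  for (k in 1:4) {
    size <- size - conv_kernels[k] + 1L  # valid convolution
    if (size < 1L)
      stop(sprintf("feature map collapses at conv layer %d (size %d)", k, size),
           call. = FALSE)
    layers[[length(layers) + 1L]] <-
      list(kind = "conv", kernel = as.integer(conv_kernels[k]),
           filters = as.integer(conv_filters[k]), in_channels = channels,
           out_size = size)
    channels <- as.integer(conv_filters[k])
    if (k <= 3L) {
      size <- size %/% 2L  # 2x2 max-pool, stride 2, floor
      if (size < 1L)
        stop(sprintf("feature map collapses at pool layer %d", k), call. = FALSE)
      layers[[length(layers) + 1L]] <- list(kind = "pool", out_size = size)
    }
  }
  flat <- size * size * channels
  units <- c(fc_units, n_classes)
  for (u in units) {
    layers[[length(layers) + 1L]] <- list(kind = "fc", units = as.integer(u),
                                          in_units = as.integer(flat))
    flat <- as.integer(u)
  }
  structure(list(variant = variant, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), layers = layers,
                 K = 7L),
            class = "network_spec")
}

#' Build the canonical Object-Net or Separator-Net specification
#'
#' The object variant convolves the 101 x 101 input patch with 80 filters
#' (11 x 11), 96 (7 x 7), 128 (5 x 5) and 160 (3 x 3), pooling 2 x 2 after the
#' first three convolutions, followed by fully connected layers of 1024, 512
#' and 4 units (softmax). The separator variant differs only in the first
#' convolution (64 filters, 9 x 9) and its two output units. Spatial sizes for
#' the object variant chain 101 -> 91 -> 45 -> 39 -> 19 -> 15 -> 7 -> 5 under
#' valid convolution and floor pooling.
#'
#' @param variant `"object"` or `"separator"`.
#' @return a `"network_spec"`.
#' @export
build_network <- function(variant = c("object", "separator")) {
  variant <- match.arg(variant)
  if (variant == "object")
    network_spec("object", 101L, c(80L, 96L, 128L, 160L), c(11L, 7L, 5L, 3L),
                 c(1024L, 512L), 4L)
  else
    network_spec("separator", 101L, c(64L, 96L, 128L, 160L), c(9L, 7L, 5L, 3L),
                 c(1024L, 512L), 2L)
}

#' Spatial feature-map sizes of a network spec
#'
#' @param spec a `"network_spec"`.
#' @return named integer vector of the spatial edge length after every conv
#'   and pool layer.
#' @export
spec_feature_sizes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- integer(0)
  for (l in spec$layers)
    if (l$kind %in% c("conv", "pool"))
      sizes <- c(sizes, stats::setNames(l$out_size, l$kind))
  sizes
}

#' Total trainable parameter count of a network spec
#' @param spec a `"network_spec"`.
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- 0
  for (l in spec$layers) {
    if (l$kind == "conv")
      n <- n + l$kernel^2 * l$in_channels * l$filters + l$filters
    else if (l$kind == "fc")
      n <- n + l$in_units * l$units + l$units
  }
  n
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec '%s': input %dx%d, %d classes, %s parameters\n",
              x$variant, x$input_size, x$input_size, x$n_classes,
              format(n_parameters(x), big.mark = ",")))
  for (l in x$layers) {
    if (l$kind == "conv")
      cat(sprintf("  conv %d@%dx%d -> %dx%d\n", l$filters, l$kernel, l$kernel,
                  l$out_size, l$out_size))
    else if (l$kind == "pool")
      cat(sprintf("  pool 2x2      -> %dx%d\n", l$out_size, l$out_size))
    else cat(sprintf("  fc   %d\n", l$units))
  }
  invisible(x)
}

#' Initialise network parameters
#'
#' Scaled-uniform fan-in initialisation: weights drawn from
#' `U(-sqrt(6/fan_in), sqrt(6/fan_in))`, biases zero.
#'
#' @param spec a `"network_spec"`.
#' @param seed optional RNG seed.
#' @return object of class `"network"` holding `spec` and `params`.
#' @export
init_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  params <- .with_seed(seed, lapply(spec$layers, function(l) {
    if (l$kind == "conv") {
      fan_in <- l$kernel^2 * l$in_channels
      lim <- sqrt(6 / fan_in)
      list(W = array(stats::runif(l$kernel^2 * l$in_channels * l$filters,
                                  -lim, lim),
                     dim = c(l$kernel, l$kernel, l$in_channels, l$filters)),
           b = numeric(l$filters))
    } else if (l$kind == "fc") {
      lim <- sqrt(6 / l$in_units)
      list(W = matrix(stats::runif(l$in_units * l$units, -lim, lim),
                      l$in_units, l$units),
           b = numeric(l$units))
    } else NULL
  }))
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = NULL),
            class = "network")
}

# --- layer primitives -------------------------------------------------------

# X: (N, H, W, C); W: (k, k, C, F). Valid convolution via accumulation of
# k^2 shifted matrix products.
.conv_forward <- function(X, W, b) {
  d <- dim(X); N <- d[1L]; H <- d[2L]; Wd <- d[3L]; C <- d[4L]
  k <- dim(W)[1L]; F <- dim(W)[4L]
  oh <- H - k + 1L; ow <- Wd - k + 1L
  Y <- matrix(rep(b, each = N * oh * ow), N * oh * ow, F)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    Xs <- X[, di:(di + oh - 1L), dj:(dj + ow - 1L), , drop = FALSE]
    dim(Xs) <- c(N * oh * ow, C)
    Y <- Y + Xs %*% matrix(W[di, dj, , ], C, F)
  }
  dim(Y) <- c(N, oh, ow, F)
  Y
}

.conv_backward <- function(X, W, dY) {
  d <- dim(X); N <- d[1L]; C <- d[4L]
  k <- dim(W)[1L]; F <- dim(W)[4L]
  oh <- dim(dY)[2L]; ow <- dim(dY)[3L]
  dYm <- dY; dim(dYm) <- c(N * oh * ow, F)
  dW <- array(0, dim = dim(W))
  dX <- array(0, dim = d)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    Xs <- X[, di:(di + oh - 1L), dj:(dj + ow - 1L), , drop = FALSE]
    dim(Xs) <- c(N * oh * ow, C)
    dW[di, dj, , ] <- crossprod(Xs, dYm)
    dXs <- dYm %*% t(matrix(W[di, dj, , ], C, F))
    dim(dXs) <- c(N, oh, ow, C)
    dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), ] <-
      dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), , drop = FALSE] + dXs
  }
  list(dW = dW, db = colSums(dYm), dX = dX)
}

# 2x2 max-pool, stride 2, floor (trailing odd row/col dropped).
.pool_forward <- function(X) {
  d <- dim(X); N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  oh <- H %/% 2L; ow <- W %/% 2L
  i1 <- seq.int(1L, 2L * oh, by = 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * ow, by = 2L); j2 <- j1 + 1L
  a <- X[, i1, j1, , drop = FALSE]; b <- X[, i2, j1, , drop = FALSE]
  cc <- X[, i1, j2, , drop = FALSE]; dd <- X[, i2, j2, , drop = FALSE]
  Y <- pmax(a, b, cc, dd)
  # argmax masks with first-wins tie break, for the backward pass
  m1 <- a == Y
  m2 <- b == Y & !m1
  m3 <- cc == Y & !m1 & !m2
  m4 <- dd == Y & !m1 & !m2 & !m3
  list(Y = Y, masks = list(m1, m2, m3, m4), in_dim = d)
}

.pool_backward <- function(cache, dY) {
  d <- cache$in_dim
  oh <- dim(dY)[2L]; ow <- dim(dY)[3L]
  i1 <- seq.int(1L, 2L * oh, by = 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * ow, by = 2L); j2 <- j1 + 1L
  dX <- array(0, dim = d)
  dX[, i1, j1, ] <- dY * cache$masks[[1L]]
  dX[, i2, j1, ] <- dY * cache$masks[[2L]]
  dX[, i1, j2, ] <- dY * cache$masks[[3L]]
  dX[, i2, j2, ] <- dY * cache$masks[[4L]]
  dX
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Patches arrive in [0, 255]; the network operates on centred unit-scale input.
.prepare_input <- function(patches) patches / 255 - 0.5

# Forward pass. X: (N, h, w, 1) already normalised. Returns probabilities and,
# if keep_cache, the per-layer activations needed for backprop.
.net_forward <- function(net, X, dropout = 0, keep_cache = FALSE,
                         rng_masks = NULL) {
  layers <- net$spec$layers
  cache <- vector("list", length(layers))
  flat_dim <- NULL
  A <- X
  flat <- FALSE
  n_fc <- sum(vapply(layers, function(l) l$kind == "fc", logical(1)))
  fc_i <- 0L
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    p <- net$params[[li]]
    if (l$kind == "conv") {
      if (keep_cache) cache[[li]] <- list(X = A)
      Z <- .conv_forward(A, p$W, p$b)
      A <- pmax(Z, 0)
      if (keep_cache) cache[[li]]$Z <- Z
    } else if (l$kind == "pool") {
      pf <- .pool_forward(A)
      if (keep_cache) cache[[li]] <- pf
      A <- pf$Y
    } else {  # fc
      fc_i <- fc_i + 1L
      if (!flat) {
        dimA <- dim(A)
        dim(A) <- c(dimA[1L], prod(dimA[-1L]))
        flat <- TRUE
        if (keep_cache) flat_dim <- dimA
      }
      if (keep_cache) cache[[li]] <- list(X = A)
      Z <- sweep(A %*% p$W, 2L, p$b, "+")
      if (fc_i < n_fc) {
        A <- pmax(Z, 0)
        if (keep_cache) cache[[li]]$Z <- Z
        if (dropout > 0) {
          mask <- if (!is.null(rng_masks)) rng_masks[[fc_i]] else
            (matrix(stats::runif(length(A)), nrow(A)) >= dropout) / (1 - dropout)
          A <- A * mask
          if (keep_cache) cache[[li]]$mask <- mask
        }
      } else {
        A <- Z  # logits
      }
    }
  }
  probs <- .softmax(A)
  if (keep_cache)
    list(probs = probs, logits = A, cache = cache, flat_dim = flat_dim)
  else probs
}

# Backward pass; y: integer class indices 1..L. Returns gradients per layer.
.net_backward <- function(net, fwd, y) {
  layers <- net$spec$layers
  N <- nrow(fwd$probs)
  G <- fwd$probs
  G[cbind(seq_len(N), y)] <- G[cbind(seq_len(N), y)] - 1
  G <- G / N
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    cc <- fwd$cache[[li]]
    if (l$kind == "fc") {
      if (!is.null(cc$mask)) G <- G * cc$mask
      if (!is.null(cc$Z)) G <- G * (cc$Z > 0)  # applied for hidden fc below? no-op for output
      grads[[li]] <- list(dW = crossprod(cc$X, G), db = colSums(G))
      G <- G %*% t(net$params[[li]]$W)
      # if the next layer down is spatial, unflatten
      if (li > 1L && layers[[li - 1L]]$kind != "fc")
        dim(G) <- fwd$flat_dim
    } else if (l$kind == "pool") {
      G <- .pool_backward(cc, G)
    } else {  # conv
      G <- G * (cc$Z > 0)
      bw <- .conv_backward(cc$X, net$params[[li]]$W, G)
      grads[[li]] <- list(dW = bw$dW, db = bw$db)
      G <- bw$dX
    }
  }
  grads
}

#' Training configuration for the pixel classifiers
#'
#' Defaults follow the published schedule: initial learning rate
#' `eta0 = 0.0025` decaying linearly to `0.2 * eta0` at epoch 100 (constant
#' after), momentum rising linearly from 0.8 to 0.99 over the first 50 epochs,
#' weight decay 0.005, dropout 0.5 on the hidden fully connected layers,
#' minibatches of 200, and early stopping after 20 epochs without improvement
#' of the validation error.
#'
#' @param eta0 initial learning rate.
#' @param lr_floor_frac fraction of `eta0` at which the linear decay saturates.
#' @param lr_saturate_epoch epoch at which the decay saturates.
#' @param momentum_start,momentum_end,momentum_saturate_epoch momentum ramp.
#' @param weight_decay L2 weight decay coefficient.
#' @param dropout dropout rate on hidden fully connected layers, in (0, 1).
#' @param batch_size minibatch size.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard cap on training epochs.
#' @param seed RNG seed for shuffling, dropout and initialisation.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(eta0 = 0.0025, lr_floor_frac = 0.2,
                         lr_saturate_epoch = 100L,
                         momentum_start = 0.8, momentum_end = 0.99,
                         momentum_saturate_epoch = 50L,
                         weight_decay = 0.005, dropout = 0.5,
                         batch_size = 200L, patience = 20L,
                         max_epochs = 500L, seed = NULL) {
  stopifnot(eta0 > 0, weight_decay >= 0, dropout > 0, dropout < 1,
            batch_size >= 1, patience >= 1)
  structure(list(eta0 = eta0, lr_floor_frac = lr_floor_frac,
                 lr_saturate_epoch = as.integer(lr_saturate_epoch),
                 momentum_start = momentum_start, momentum_end = momentum_end,
                 momentum_saturate_epoch = as.integer(momentum_saturate_epoch),
                 weight_decay = weight_decay, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "train_config")
}

.lr_at <- function(config, epoch) {
  t <- min(epoch, config$lr_saturate_epoch) / config$lr_saturate_epoch
  config$eta0 * (1 - (1 - config$lr_floor_frac) * t)
}

.momentum_at <- function(config, epoch) {
  t <- min(epoch, config$momentum_saturate_epoch) / config$momentum_saturate_epoch
  config$momentum_start + (config$momentum_end - config$momentum_start) * t
}

# dataset -> list(X = (N,h,w,1) normalised array, y = class indices 1..L)
.dataset_tensors <- function(dataset, classes) {
  stopifnot(inherits(dataset, "patch_dataset"))
  y <- match(dataset$labels, classes)
  if (anyNA(y))
    stop("dataset contains class values not covered by the network", call. = FALSE)
  d <- dim(dataset$patches)
  X <- aperm(dataset$patches, c(3L, 1L, 2L))
  dim(X) <- c(d[3L], d[1L], d[2L], 1L)
  list(X = .prepare_input(X), y = y)
}

.error_rate <- function(net, X, y, batch = 1024L) {
  n <- dim(X)[1L]
  wrong <- 0L
  for (s in seq.int(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    p <- .net_forward(net, X[s:e, , , , drop = FALSE])
    wrong <- wrong + sum(max.col(p, ties.method = "first") != y[s:e])
  }
  wrong / n
}

#' Train a pixel-classifier network
#'
#' Minibatch stochastic gradient descent with momentum, weight decay and
#' dropout, minimising the softmax cross-entropy. Training stops when the
#' validation error has not improved for `config$patience` epochs (or at
#' `config$max_epochs`); the parameters from the best-validation epoch are
#' returned. Class values found in the training labels are mapped in sorted
#' order onto the output units and must match the spec's class count.
#'
#' @param spec a `"network_spec"` (or an initialised `"network"`).
#' @param train,valid `"patch_dataset"` objects for training and validation.
#' @param config a [train_config()].
#' @return a trained `"network"` with elements `history` (data.frame of epoch,
#'   train_error, valid_error), `best_epoch`, and `classes` (class value per
#'   output unit).
#' @export
train_network <- function(spec, train, valid, config = train_config()) {
  net <- if (inherits(spec, "network")) spec else
    init_network(spec, seed = config$seed)
  classes <- sort(unique(train$labels))
  if (length(classes) != net$spec$n_classes)
    stop(sprintf("dataset has %d classes but the network has %d output units",
                 length(classes), net$spec$n_classes), call. = FALSE)
  tr <- .dataset_tensors(train, classes)
  va <- .dataset_tensors(valid, classes)
  n <- dim(tr$X)[1L]

  vel <- lapply(net$params, function(p)
    if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0))
  history <- data.frame(epoch = integer(0), train_error = numeric(0),
                        valid_error = numeric(0))
  best <- list(error = Inf, epoch = 0L, params = net$params)

  .with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- .lr_at(config, epoch - 1L)
      mu <- .momentum_at(config, epoch - 1L)
      ord <- sample.int(n)
      for (s in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- tr$X[idx, , , , drop = FALSE]
        fwd <- .net_forward(net, Xb, dropout = config$dropout, keep_cache = TRUE)
        loss <- -mean(log(pmax(fwd$probs[cbind(seq_along(idx), tr$y[idx])], 1e-12)))
        if (!is.finite(loss))
          stop("training diverged: non-finite loss", call. = FALSE)
        grads <- .net_backward(net, fwd, tr$y[idx])
        for (li in seq_along(net$params)) {
          if (is.null(net$params[[li]])) next
          g <- grads[[li]]
          vel[[li]]$W <- mu * vel[[li]]$W -
            lr * (g$dW + config$weight_decay * net$params[[li]]$W)
          vel[[li]]$b <- mu * vel[[li]]$b - lr * g$db
          net$params[[li]]$W <- net$params[[li]]$W + vel[[li]]$W
          net$params[[li]]$b <- net$params[[li]]$b + vel[[li]]$b
        }
      }
      tr_err <- .error_rate(net, tr$X, tr$y)
      va_err <- .error_rate(net, va$X, va$y)
      history <- rbind(history, data.frame(epoch = epoch, train_error = tr_err,
                                           valid_error = va_err))
      if (va_err < best$error) {
        best <- list(error = va_err, epoch = epoch, params = net$params)
      }
      if (epoch - best$epoch >= config$patience) break
    }
  })

  net$params <- best$params
  net$trained <- TRUE
  net$history <- history
  net$best_epoch <- best$epoch
  net$classes <- classes
  net
}

#' @export
print.network <- function(x, ...) {
  state <- if (isTRUE(x$trained))
    sprintf("trained (best epoch %d, valid error %.3f)", x$best_epoch,
            x$history$valid_error[x$best_epoch])
  else "untrained"
  cat(sprintf("network '%s' (%s)\n", x$spec$variant, state))
  invisible(x)
}

#' Predict class probabilities for a set of patches
#'
#' @param net a trained `"network"`.
#' @param patches `h x w x n` array of patches in `[0, 255]`, or a
#'   `"patch_dataset"`.
#' @return `n x L` matrix of class probabilities (columns follow
#'   `net$classes` when the network was trained).
#' @export
predict_patches <- function(net, patches) {
  stopifnot(inherits(net, "network"))
  if (inherits(patches, "patch_dataset")) patches <- patches$patches
  if (length(dim(patches)) == 2L)
    patches <- array(patches, dim = c(dim(patches), 1L))
  d <- dim(patches)
  X <- aperm(patches, c(3L, 1L, 2L))
  dim(X) <- c(d[3L], d[1L], d[2L], 1L)
  .net_forward(net, .prepare_input(X))
}

#' Sliding-window prediction of per-pixel probability maps
#'
#' Classifies every pixel of a structure channel by sliding the network's
#' input window across the image (stride 1 by default); border pixels are
#' handled by mirror padding, so the output maps have exactly the input's
#' spatial size. Patches are processed in batches through the same forward
#' pass used at training time.
#'
#' @param net a trained `"network"`.
#' @param channel `H x W` structure channel in `[0, 255]` at the network's
#'   training scale.
#' @param stride pixel stride (default 1); strided outputs are filled by
#'   nearest-neighbour replication so maps keep the input size.
#' @param batch_size patches per forward batch.
#' @return `H x W x L` array of per-pixel class probabilities summing to 1
#'   over the last axis, with attribute `scale` copied from the channel.
#' @export
predict_maps <- function(net, channel, stride = 1L, batch_size = 1024L) {
  stopifnot(inherits(net, "network"))
  if (!isTRUE(net$trained)) stop("network is untrained", call. = FALSE)
  .assert_raster(channel)
  ps <- net$spec$input_size
  r <- (ps - 1L) %/% 2L
  padded <- .pad_mirror(channel, r)
  H <- nrow(channel); W <- ncol(channel)
  rows <- seq.int(1L, H, by = stride)
  cols <- seq.int(1L, W, by = stride)
  centers <- as.matrix(expand.grid(r = rows, c = cols))
  L <- net$spec$n_classes
  probs <- matrix(0, nrow(centers), L)
  off <- seq.int(0L, ps - 1L)
  for (s in seq.int(1L, nrow(centers), by = batch_size)) {
    e <- min(s + batch_size - 1L, nrow(centers))
    nb <- e - s + 1L
    X <- array(0, dim = c(nb, ps, ps, 1L))
    for (i in seq_len(nb)) {
      ct <- centers[s + i - 1L, ]
      X[i, , , 1L] <- padded[ct[1L] + off, ct[2L] + off]
    }
    probs[s:e, ] <- .net_forward(net, .prepare_input(X))
  }
  maps <- array(0, dim = c(length(rows), length(cols), L))
  for (l in seq_len(L))
    maps[, , l] <- matrix(probs[, l], length(rows), length(cols))
  if (stride > 1L) {
    full <- array(0, dim = c(H, W, L))
    # nearest source row/col for each output pixel
    rsel <- findInterval(seq_len(H), rows)
    csel <- findInterval(seq_len(W), cols)
    for (l in seq_len(L)) full[, , l] <- maps[rsel, csel, l]
    maps <- full
  }
  attr(maps, "scale") <- attr(channel, "scale")
  maps
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single RDS file embedding the spec, parameters,
#' training history and class mapping.
#'
#' @param net a `"network"`.
#' @param path file path.
#' @return `load_network` returns the `"network"`; `save_network` returns
#'   `path` invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "network")) stop("not a network checkpoint", call. = FALSE)
  net
}
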