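# Minimal feed-forward network engine used by the MLP/CNN/LCNN
# architectures: dense, batch-normalization, dropout, activation, 1-D
# convolution, locally connected and max-pooling layers, trained with Adam
# on squared error and early stopping on a validation split.
#
# Activations are plain n x d matrices. Convolutional layers interpret the
# columns as positions x channels in position-major layout
# (pos1: ch1..chC, pos2: ch1..chC, ...), so pooling/conv operate on
# contiguous column slices. Batch normalization is applied per feature
# column (running statistics tracked for inference).

nn_layer_dense <- function(d_in, d_out, init_scale = 1) {
  # He-style init keeps early training stable for relu; the output layer is
  # zero-initialized so an untrained network predicts the (centred) mean
  list(type = "dense",
       W = matrix(stats::rnorm(d_in * d_out, 0, init_scale * sqrt(2 / d_in)),
                  d_in, d_out),
       b = rep(0, d_out), d_out = d_out)
}

nn_layer_bn <- function(d) {
  list(type = "bn", gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d),
       momentum = 0.9, eps = 1e-5, d_out = d)
}

nn_layer_act <- function(d, fun = c("relu", "tanh")) {
  list(type = "act", fun = match.arg(fun), d_out = d)
}

nn_layer_dropout <- function(d, rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, d_out = d)
}

# 1-D convolution: length positions x channels in, filters out
nn_layer_conv <- function(length_in, channels, filters, kernel, stride) {
  l_out <- floor((length_in - kernel) / stride) + 1
  if (l_out < 1)
    stop("input too short for this kernel/stride configuration", call. = FALSE)
  fan_in <- kernel * channels
  list(type = "conv",
       W = matrix(stats::rnorm(fan_in * filters, 0, sqrt(2 / fan_in)),
                  fan_in, filters),
       b = rep(0, filters),
       length_in = length_in, channels = channels, filters = filters,
       kernel = kernel, stride = stride, length_out = l_out,
       d_out = l_out * filters)
}

# locally connected: like conv but with unshared per-position weights
nn_layer_local <- function(length_in, channels, filters, kernel, stride) {
  l_out <- floor((length_in - kernel) / stride) + 1
  if (l_out < 1)
    stop("input too short for this kernel/stride configuration", call. = FALSE)
  fan_in <- kernel * channels
  W <- lapply(seq_len(l_out), function(t)
    matrix(stats::rnorm(fan_in * filters, 0, sqrt(2 / fan_in)),
           fan_in, filters))
  list(type = "local", W = W, b = matrix(0, l_out, filters),
       length_in = length_in, channels = channels, filters = filters,
       kernel = kernel, stride = stride, length_out = l_out,
       d_out = l_out * filters)
}

nn_layer_maxpool <- function(length_in, channels, pool = 2) {
  l_out <- max(1L, floor(length_in / pool))
  list(type = "maxpool", pool = pool, length_in = length_in,
       channels = channels, length_out = l_out, d_out = l_out * channels)
}

# column indices of position t (1-based) for position-major layout
.pos_cols <- function(t, channels) ((t - 1) * channels + 1):(t * channels)

nn_forward_layer <- function(layer, A, training = TRUE) {
  switch(layer$type,
    dense = {
      Z <- sweep(A %*% layer$W, 2, layer$b, `+`)
      list(out = Z, cache = list(A = A), layer = layer)
    },
    bn = {
      if (training) {
        mu <- colMeans(A)
        v <- colMeans(sweep(A, 2, mu)^2)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean; v <- layer$run_var
      }
      xc <- sweep(A, 2, mu)
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, istd, `*`)
      Z <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
      list(out = Z, cache = list(xhat = xhat, istd = istd, xc = xc), layer = layer)
    },
    act = {
      Z <- if (layer$fun == "relu") pmax(A, 0) else tanh(A)
      list(out = Z, cache = list(A = A, Z = Z), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- matrix(stats::rbinom(length(A), 1, 1 - layer$rate),
                       nrow(A)) / (1 - layer$rate)
        list(out = A * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = A, cache = list(mask = NULL), layer = layer)
      }
    },
    conv = {
      # im2col: gather all patches into one (n*length_out) x (kernel*channels)
      # matrix so the convolution is a single matrix product
      n <- nrow(A)
      L <- layer$length_out
      KC <- layer$kernel * layer$channels
      Fl <- layer$filters
      patches <- lapply(seq_len(L), function(t) {
        start <- (t - 1) * layer$stride + 1
        unlist(lapply(start:(start + layer$kernel - 1),
                      .pos_cols, channels = layer$channels))
      })
      M <- A[, unlist(patches), drop = FALSE]
      B <- matrix(aperm(array(M, c(n, KC, L)), c(1, 3, 2)), n * L, KC)
      Zb <- sweep(B %*% layer$W, 2, layer$b, `+`)
      Z <- matrix(aperm(array(Zb, c(n, L, Fl)), c(1, 3, 2)), n, L * Fl)
      list(out = Z, cache = list(B = B, patches = patches, d_in = ncol(A)),
           layer = layer)
    },
    local = {
      n <- nrow(A)
      Z <- matrix(0, n, layer$d_out)
      patches <- vector("list", layer$length_out)
      for (t in seq_len(layer$length_out)) {
        start <- (t - 1) * layer$stride + 1
        cols <- unlist(lapply(start:(start + layer$kernel - 1),
                              .pos_cols, channels = layer$channels))
        patches[[t]] <- cols
        Z[, .pos_cols(t, layer$filters)] <-
          sweep(A[, cols, drop = FALSE] %*% layer$W[[t]], 2,
                layer$b[t, ], `+`)
      }
      list(out = Z, cache = list(A = A, patches = patches), layer = layer)
    },
    maxpool = {
      n <- nrow(A)
      Z <- matrix(-Inf, n, layer$d_out)
      argmax <- matrix(0L, n, layer$d_out)
      for (t in seq_len(layer$length_out)) {
        members <- ((t - 1) * layer$pool + 1):min(t * layer$pool, layer$length_in)
        for (ch in seq_len(layer$channels)) {
          cand <- vapply(members, function(p) (p - 1) * layer$channels + ch, 0)
          sub <- A[, cand, drop = FALSE]
          j <- max.col(sub, ties.method = "first")
          out_col <- (t - 1) * layer$channels + ch
          Z[, out_col] <- sub[cbind(seq_len(n), j)]
          argmax[, out_col] <- cand[j]
        }
      }
      list(out = Z, cache = list(argmax = argmax, d_in = ncol(A)), layer = layer)
    },
    stop("unknown layer type ", layer$type))
}

nn_backward_layer <- function(layer, cache, dZ) {
  switch(layer$type,
    dense = list(dA = dZ %*% t(layer$W),
                 grads = list(W = crossprod(cache$A, dZ), b = colSums(dZ))),
    bn = {
      n <- nrow(dZ)
      dgamma <- colSums(dZ * cache$xhat)
      dbeta <- colSums(dZ)
      dxhat <- sweep(dZ, 2, layer$gamma, `*`)
      # standard batchnorm backward
      dA <- sweep(dxhat -
                    matrix(colMeans(dxhat), n, ncol(dZ), byrow = TRUE) -
                    sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`),
                  2, cache$istd, `*`)
      list(dA = dA, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dA <- if (layer$fun == "relu") dZ * (cache$A > 0) else dZ * (1 - cache$Z^2)
      list(dA = dA, grads = NULL)
    },
    dropout = {
      dA <- if (is.null(cache$mask)) dZ else dZ * cache$mask
      list(dA = dA, grads = NULL)
    },
    conv = {
      n <- nrow(dZ)
      L <- layer$length_out
      Fl <- layer$filters
      dZb <- matrix(aperm(array(dZ, c(n, Fl, L)), c(1, 3, 2)), n * L, Fl)
      dW <- crossprod(cache$B, dZb)
      db <- colSums(dZb)
      dBig <- dZb %*% t(layer$W)        # (n*L) x (kernel*channels)
      dA <- matrix(0, n, cache$d_in)
      for (t in seq_len(L)) {
        rows <- (t - 1) * n + seq_len(n)
        cols <- cache$patches[[t]]
        dA[, cols] <- dA[, cols] + dBig[rows, , drop = FALSE]
      }
      list(dA = dA, grads = list(W = dW, b = db))
    },
    local = {
      dW <- vector("list", layer$length_out)
      db <- matrix(0, layer$length_out, layer$filters)
      dA <- matrix(0, nrow(dZ), ncol(cache$A))
      for (t in seq_len(layer$length_out)) {
        cols <- cache$patches[[t]]
        dZt <- dZ[, .pos_cols(t, layer$filters), drop = FALSE]
        dW[[t]] <- crossprod(cache$A[, cols, drop = FALSE], dZt)
        db[t, ] <- colSums(dZt)
        dA[, cols] <- dA[, cols] + dZt %*% t(layer$W[[t]])
      }
      list(dA = dA, grads = list(W = dW, b = db))
    },
    maxpool = {
      dA <- matrix(0, nrow(dZ), cache$d_in)
      n <- nrow(dZ)
      for (col in seq_len(ncol(dZ))) {
        idx <- cbind(seq_len(n), cache$argmax[, col])
        dA[idx] <- dA[idx] + dZ[, col]
      }
      list(dA = dA, grads = NULL)
    })
}

nn_forward <- function(net, X, training = TRUE) {
  caches <- vector("list", length(net$layers))
  A <- X
  for (i in seq_along(net$layers)) {
    st <- nn_forward_layer(net$layers[[i]], A, training)
    net$layers[[i]] <- st$layer      # updated running stats
    caches[[i]] <- st$cache
    A <- st$out
  }
  list(out = A, caches = caches, net = net)
}

# Adam state is a flat list parallel to (layer, param name)
nn_adam_init <- function(net) {
  lapply(net$layers, function(l) {
    ps <- intersect(names(l), c("W", "b", "gamma", "beta"))
    stats::setNames(lapply(ps, function(p) {
      v <- l[[p]]
      zero <- if (is.list(v)) lapply(v, function(x) x * 0) else v * 0
      list(m = zero, v = zero)
    }), ps)
  })
}

.adam_update <- function(param, grad, state, lr, beta1, beta2, eps, t) {
  if (is.list(param)) {
    for (i in seq_along(param)) {
      r <- .adam_update(param[[i]], grad[[i]], list(m = state$m[[i]], v = state$v[[i]]),
                        lr, beta1, beta2, eps, t)
      param[[i]] <- r$param; state$m[[i]] <- r$state$m; state$v[[i]] <- r$state$v
    }
    return(list(param = param, state = state))
  }
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Neural architecture specification
#'
#' Describes one of the three supported architectures:
#' * `mlp` — `n_blocks` repetitions of dense / batch-norm / activation /
#'   dropout, then a linear output unit; takes the (standardized) additive
#'   encoding.
#' * `cnn` — `n_blocks` of 1-D convolution / batch-norm / activation /
#'   dropout, then max-pooling, flattening, one dense block and the output
#'   unit; takes the one-hot encoding (3 channels per marker).
#' * `lcnn` — one locally connected layer (unshared per-region filters) with
#'   batch-norm / activation / dropout and max-pooling, then `n_blocks`
#'   dense blocks and the output unit; one-hot input.
#'
#' @param family `"mlp"`, `"cnn"` or `"lcnn"`.
#' @param n_blocks number of repeated blocks (>= 1).
#' @param units dense-layer width.
#' @param filters convolution filters per layer.
#' @param kernel_size,stride convolution geometry (positions).
#' @param pool max-pool width (positions).
#' @param dropout dropout rate in `[0, 1)`.
#' @param activation `"relu"` or `"tanh"`.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @export
nn_architecture <- function(family = c("mlp", "cnn", "lcnn"),
                            n_blocks = 1, units = 32, filters = 8,
                            kernel_size = 3, stride = 2, pool = 2,
                            dropout = 0.1, activation = "relu",
                            learning_rate = 1e-3, batch_size = 32,
                            epochs = 200, patience = 10) {
  family <- match.arg(family)
  stopifnot(n_blocks >= 1, dropout >= 0, dropout < 1)
  structure(list(family = family, n_blocks = n_blocks, units = units,
                 filters = filters, kernel_size = kernel_size,
                 stride = stride, pool = pool, dropout = dropout,
                 activation = activation, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs,
                 patience = patience),
            class = "gs_nn_arch")
}

nn_build <- function(arch, d_in, channels = 1) {
  layers <- list()
  add <- function(l) layers[[length(layers) + 1]] <<- l
  if (arch$family == "mlp") {
    d <- d_in
    for (b in seq_len(arch$n_blocks)) {
      add(nn_layer_dense(d, arch$units)); d <- arch$units
      add(nn_layer_bn(d))
      add(nn_layer_act(d, arch$activation))
      add(nn_layer_dropout(d, arch$dropout))
    }
    add(nn_layer_dense(d, 1, init_scale = 0))
  } else if (arch$family == "cnn") {
    len <- d_in %/% channels
    ch <- channels
    for (b in seq_len(arch$n_blocks)) {
      cv <- nn_layer_conv(len, ch, arch$filters, arch$kernel_size, arch$stride)
      add(cv); len <- cv$length_out; ch <- arch$filters
      add(nn_layer_bn(len * ch))
      add(nn_layer_act(len * ch, arch$activation))
      add(nn_layer_dropout(len * ch, arch$dropout))
    }
    mp <- nn_layer_maxpool(len, ch, arch$pool)
    add(mp)
    d <- mp$d_out
    add(nn_layer_dense(d, arch$units)); d <- arch$units
    add(nn_layer_bn(d)); add(nn_layer_act(d, arch$activation))
    add(nn_layer_dropout(d, arch$dropout))
    add(nn_layer_dense(d, 1, init_scale = 0))
  } else { # lcnn
    len <- d_in %/% channels
    lc <- nn_layer_local(len, channels, arch$filters, arch$kernel_size, arch$stride)
    add(lc); len <- lc$length_out; ch <- arch$filters
    add(nn_layer_bn(len * ch))
    add(nn_layer_act(len * ch, arch$activation))
    add(nn_layer_dropout(len * ch, arch$dropout))
    mp <- nn_layer_maxpool(len, ch, arch$pool)
    add(mp)
    d <- mp$d_out
    for (b in seq_len(arch$n_blocks)) {
      add(nn_layer_dense(d, arch$units)); d <- arch$units
      add(nn_layer_bn(d)); add(nn_layer_act(d, arch$activation))
      add(nn_layer_dropout(d, arch$dropout))
    }
    add(nn_layer_dense(d, 1, init_scale = 0))
  }
  list(layers = layers, d_in = d_in, channels = channels)
}

#' Build and train a neural network
#'
#' Assembles the architecture, trains with Adam on mean squared error,
#' monitors the loss on a held-out validation split and stops once it has
#' not improved for `patience` epochs, restoring the best weights.
#' Deterministic for a fixed seed.
#'
#' @param arch a [nn_architecture()] specification.
#' @param X input matrix; for `cnn`/`lcnn` a one-hot matrix in
#'   position-major layout (see [onehot_tensor()]).
#' @param y numeric response.
#' @param validation_split fraction of samples held out for early-stopping
#'   monitoring (ignored when `X_val` is given).
#' @param X_val,y_val explicit validation data.
#' @param channels channels per position (3 for one-hot genotype input,
#'   1 for additive input).
#' @param seed integer seed.
#' @param early_stopping disable to always run `epochs` epochs.
#' @return A `gs_nn` fit with the trained network, training history and
#'   the epoch of the restored weights.
#' @export
fit_nn <- function(arch, X, y, validation_split = 0.2,
                   X_val = NULL, y_val = NULL, channels = 1,
                   seed = 1L, early_stopping = TRUE) {
  stopifnot(inherits(arch, "gs_nn_arch"))
  X <- as.matrix(X); y <- as.numeric(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(X)
  if (is.null(X_val)) {
    n_val <- max(1L, floor(validation_split * n))
    vi <- sample.int(n, n_val)
    X_val <- X[vi, , drop = FALSE]; y_val <- y[vi]
    X_tr <- X[-vi, , drop = FALSE]; y_tr <- y[-vi]
  } else {
    X_tr <- X; y_tr <- y
    X_val <- as.matrix(X_val); y_val <- as.numeric(y_val)
  }
  # standardize the response on the training portion: the zero-initialized
  # output layer then starts as a mean predictor and training must earn any
  # deviation from it
  y_center <- mean(y_tr)
  y_scale <- stats::sd(y_tr)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y_tr <- (y_tr - y_center) / y_scale
  y_val <- (y_val - y_center) / y_scale
  net <- nn_build(arch, ncol(X), channels)
  adam <- nn_adam_init(net)
  t_step <- 0
  best <- list(loss = Inf, layers = net$layers, epoch = 0)
  wait <- 0
  history <- numeric(0)
  n_tr <- nrow(X_tr)
  for (epoch in seq_len(arch$epochs)) {
    ord <- sample.int(n_tr)
    bs <- min(arch$batch_size, n_tr)
    starts <- seq(1, n_tr, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, n_tr)]
      if (length(idx) < 2) next   # batch norm needs >= 2 samples
      fw <- nn_forward(net, X_tr[idx, , drop = FALSE], training = TRUE)
      net <- fw$net
      pred <- as.numeric(fw$out)
      dZ <- matrix(2 * (pred - y_tr[idx]) / length(idx), ncol = 1)
      t_step <- t_step + 1
      for (i in rev(seq_along(net$layers))) {
        bw <- nn_backward_layer(net$layers[[i]], fw$caches[[i]], dZ)
        dZ <- bw$dA
        if (!is.null(bw$grads)) {
          for (p in names(bw$grads)) {
            r <- .adam_update(net$layers[[i]][[p]], bw$grads[[p]],
                              adam[[i]][[p]], arch$learning_rate,
                              0.9, 0.999, 1e-8, t_step)
            net$layers[[i]][[p]] <- r$param
            adam[[i]][[p]] <- r$state
          }
        }
      }
    }
    val_pred <- nn_forward(net, X_val, training = FALSE)$out
    val_loss <- mean((as.numeric(val_pred) - y_val)^2)
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, layers = net$layers, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (early_stopping && wait >= arch$patience) break
    }
  }
  net$layers <- best$layers
  structure(list(net = net, arch = arch, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 epochs_run = length(history), seed = as.integer(seed),
                 y_center = y_center, y_scale = y_scale),
            class = "gs_nn")
}

#' @export
predict.gs_nn <- function(object, newdata, ...) {
  raw <- as.numeric(nn_forward(object$net, as.matrix(newdata),
                               training = FALSE)$out)
  object$y_center + object$y_scale * raw
}

#' @export
print.gs_nn <- function(x, ...) {
  cat(sprintf("<gs_nn> %s, %d layers, best epoch %d/%d (val MSE %.4g)\n",
              x$arch$family, length(x$net$layers), x$best_epoch,
              x$epochs_run, x$best_val_loss))
  invisible(x)
}

#' One-hot genotype matrix in position-major channel layout
#'
#' Expands a genotype matrix to 3 indicator channels per marker (states
#' 0/1/2), laid out position-major (`marker1: s0 s1 s2, marker2: ...`) as
#' expected by the convolutional layers. Unobserved states yield all-zero
#' channels, so every row sums to the marker count.
#'
#' @param G a `gs_genotypes` object or a 0/1/2 matrix.
#' @return numeric matrix with `3 * n_markers` columns.
#' @export
onehot_tensor <- function(G) {
  V <- if (inherits(G, "gs_genotypes")) G$values else as.matrix(G)
  n <- nrow(V); m <- ncol(V)
  out <- matrix(0, n, 3 * m)
  for (s in 0:2) out[, seq(1 + s, 3 * m, by = 3)][V == s] <- 1
  colnames(out) <- paste0(rep(colnames(V), each = 3), "_", rep(0:2, m))
  out
}
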