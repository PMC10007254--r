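# Trainable 1D-CNN built from a model_spec. Forward/backward passes run over
# (length, channels, batch) arrays with Rcpp kernels for convolution and
# pooling; batch norm, dense layers and the softmax head are plain matrix
# code. Hidden activations are rectified-linear (attached to batch-norm and
# hidden dense layers); the output is a softmax over classes.

#' Build a trainable network from a specification
#'
#' Convolution and dense weights use seeded He-normal initialization
#' (`sd = sqrt(2 / fan_in)`), biases zero, batch-norm scale 1 / shift 0 with
#' unit running variance. The same spec and seed always produce identical
#' initial parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the initializer.
#' @return an object of class `cnn_network`.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  sh <- infer_shapes(spec)
  in_ch <- c(spec$input_channels, sh$channels[-nrow(sh)])
  params <- with_seed(seed, {
    P <- list()
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      if (l$kind == "conv1d") {
        fan_in <- l$filter_size * in_ch[i]
        P[[l$name]] <- list(
          W = matrix(rnorm(l$n_filters * fan_in, sd = sqrt(2 / fan_in)),
                     l$n_filters, fan_in),
          b = numeric(l$n_filters))
      } else if (l$kind == "batch_norm") {
        ch <- sh$channels[i]
        P[[l$name]] <- list(gamma = rep(1, ch), beta = numeric(ch),
                            run_mean = numeric(ch), run_var = rep(1, ch))
      } else if (l$kind == "dense") {
        fan_in <- in_ch[i]
        P[[l$name]] <- list(
          W = matrix(rnorm(fan_in * l$units, sd = sqrt(2 / fan_in)),
                     fan_in, l$units),
          b = numeric(l$units))
      }
    }
    P
  })
  structure(list(spec = spec, params = params, frozen = character(),
                 class_levels = NULL, seed = seed),
            class = "cnn_network")
}

#' @export
print.cnn_network <- function(x, ...) {
  cnt <- count_parameters(x$spec, x$frozen)
  cat(sprintf("<cnn_network> input %d, %d classes; %d parameters (%d trainable)\n",
              x$spec$input_len, x$spec$n_classes, cnt["total"],
              cnt["trainable"]))
  if (length(x$frozen))
    cat("  frozen:", paste(x$frozen, collapse = ", "), "\n")
  invisible(x)
}

# windows matrix (n x len) -> cube array (len, 1, n)
as_input_cube <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  array(t(X), dim = c(ncol(X), 1L, nrow(X)))
}

#' Forward pass
#'
#' @param net a `cnn_network`.
#' @param X windows matrix (one row per window) of `spec$input_len` columns.
#' @param train use batch statistics in unfrozen batch-norm layers and keep
#'   caches for the backward pass?
#' @return list with `probs` (n x n_classes softmax output) and, when
#'   `train = TRUE`, per-layer `caches`.
#' @export
network_forward <- function(net, X, train = FALSE) {
  spec <- net$spec
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != spec$input_len)
    stop("expected input length ", spec$input_len, ", got ", ncol(X))
  A <- as_input_cube(X)              # (len, ch, batch) until global pooling
  flat <- NULL                       # (batch, features) after global pooling
  caches <- vector("list", length(spec$layers))
  bn_momentum <- 0.9
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- net$params[[l$name]]
    frozen <- l$name %in% net$frozen
    if (l$kind == "conv1d") {
      if (train) caches[[i]] <- list(X = A)
      A <- nn_conv1d_fwd(A, p$W, p$b, l$filter_size, l$stride)
    } else if (l$kind == "batch_norm") {
      if (train && !frozen) {
        st <- nn_channel_stats(A)
        mu <- as.numeric(st$mean)
        v <- as.numeric(st$var)
      } else {
        mu <- p$run_mean
        v <- p$run_var
      }
      invstd <- 1 / sqrt(v + 1e-5)
      relu <- identical(l$activation, "relu")
      r <- nn_bn_fwd(A, p$gamma, p$beta, mu, invstd, relu)
      A <- r$Y
      if (train)
        caches[[i]] <- list(Y = r$Y, xhat = r$Xhat, invstd = invstd,
                            relu = relu,
                            batch_mu = if (!frozen) mu,
                            batch_var = if (!frozen) v,
                            used_batch_stats = !frozen)
    } else if (l$kind == "max_pool1d") {
      r <- nn_maxpool1d_fwd(A, l$filter_size, l$stride)
      if (train) caches[[i]] <- list(argmax = r$argmax, in_len = dim(A)[1])
      A <- r$Y
    } else if (l$kind == "avg_pool1d") {
      caches[[i]] <- list(in_len = dim(A)[1])
      A <- nn_avgpool1d_fwd(A, l$filter_size, l$stride)
    } else if (l$kind == "global_avg_pool") {
      d <- dim(A)
      caches[[i]] <- list(in_len = d[1])
      flat <- t(matrix(colMeans(matrix(A, nrow = d[1])),
                       nrow = d[2]))         # (batch, channels)
      A <- NULL
    } else if (l$kind == "dense") {
      if (is.null(flat)) {                   # no global pool: flatten channels
        d <- dim(A)
        flat <- t(matrix(A, nrow = d[1] * d[2]))
        A <- NULL
      }
      caches[[i]] <- list(X = flat)
      Z <- flat %*% p$W + rep(p$b, each = nrow(flat))
      if (identical(l$activation, "relu")) {
        mask <- Z > 0
        Z <- Z * mask
        caches[[i]]$mask <- mask
      } else if (identical(l$activation, "softmax")) {
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        Z <- E / rowSums(E)
      }
      flat <- Z
    }
  }
  list(probs = flat, caches = if (train) caches)
}

#' Backward pass: gradients of mean cross-entropy
#'
#' Returns per-layer gradients matching the parameter structure. Gradients
#' of frozen layers are reported as zero (their parameters receive no
#' update, and frozen batch-norm layers run in inference mode).
#'
#' @param net a `cnn_network`.
#' @param fwd result of `network_forward(net, X, train = TRUE)`.
#' @param y_onehot n x n_classes 0/1 matrix of true classes.
#' @return named list of gradient lists per parameterized layer.
#' @export
network_backward <- function(net, fwd, y_onehot) {
  spec <- net$spec
  caches <- fwd$caches
  n <- nrow(y_onehot)
  grads <- list()
  dflat <- (fwd$probs - y_onehot) / n      # grad at softmax pre-activation
  dA <- NULL
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    p <- net$params[[l$name]]
    cc <- caches[[i]]
    frozen <- l$name %in% net$frozen
    if (l$kind == "dense") {
      if (identical(l$activation, "relu")) dflat <- dflat * cc$mask
      grads[[l$name]] <- if (frozen) list(W = 0 * p$W, b = 0 * p$b)
        else list(W = crossprod(cc$X, dflat), b = colSums(dflat))
      dflat <- tcrossprod(dflat, p$W)
    } else if (l$kind == "global_avg_pool") {
      ch <- ncol(dflat)
      L <- cc$in_len
      dA <- array(0, dim = c(L, ch, n))
      dA[] <- rep(t(dflat) / L, each = L)  # recycle (ch x n) per length
      dflat <- NULL
    } else if (l$kind == "avg_pool1d") {
      dA <- nn_avgpool1d_bwd(dA, l$filter_size, l$stride, cc$in_len)
    } else if (l$kind == "max_pool1d") {
      dA <- nn_maxpool1d_bwd(dA, cc$argmax, cc$in_len)
    } else if (l$kind == "batch_norm") {
      r <- nn_bn_bwd(dA, cc$Y, cc$xhat, p$gamma, cc$invstd, cc$relu,
                     cc$used_batch_stats)
      grads[[l$name]] <- if (frozen)
        list(gamma = 0 * p$gamma, beta = 0 * p$beta)
      else list(gamma = as.numeric(r$dgamma), beta = as.numeric(r$dbeta))
      dA <- r$dX
    } else if (l$kind == "conv1d") {
      r <- nn_conv1d_bwd(cc$X, p$W, dA, l$filter_size, l$stride,
                         need_dx = i > 1)
      grads[[l$name]] <- if (frozen) list(W = 0 * p$W, b = 0 * p$b)
        else list(W = r$dW, b = as.numeric(r$db))
      dA <- r$dX
    }
  }
  grads
}

# Recompute exact BN running statistics over a data set with the final
# weights (exponential averages collected during training lag behind the
# drifting convolution weights; a closing pass removes the train/eval
# mismatch).
recalibrate_bn <- function(net, x, batch_size = 256) {
  n <- nrow(x)
  acc <- list()
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1)
    fwd <- network_forward(net, x[idx, , drop = FALSE], train = TRUE)
    w <- length(idx)
    for (i in seq_along(net$spec$layers)) {
      l <- net$spec$layers[[i]]
      if (l$kind != "batch_norm") next
      cc <- fwd$caches[[i]]
      if (is.null(cc) || !isTRUE(cc$used_batch_stats)) next
      a <- acc[[l$name]]
      if (is.null(a)) a <- list(w = 0, mu = 0, ex2 = 0)
      a$w <- a$w + w
      a$mu <- a$mu + w * cc$batch_mu
      a$ex2 <- a$ex2 + w * (cc$batch_var + cc$batch_mu^2)
      acc[[l$name]] <- a
    }
  }
  for (nm in names(acc)) {
    a <- acc[[nm]]
    mu <- a$mu / a$w
    net$params[[nm]]$run_mean <- mu
    net$params[[nm]]$run_var <- pmax(a$ex2 / a$w - mu^2, 0)
  }
  net
}

# update running BN statistics from a train-mode forward pass
bn_update_running <- function(net, fwd, momentum = 0.9) {
  for (i in seq_along(net$spec$layers)) {
    l <- net$spec$layers[[i]]
    if (l$kind != "batch_norm") next
    cc <- fwd$caches[[i]]
    if (is.null(cc) || !isTRUE(cc$used_batch_stats)) next
    p <- net$params[[l$name]]
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * cc$batch_mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * cc$batch_var
    net$params[[l$name]] <- p
  }
  net
}

#' Predicted class probabilities
#'
#' @param object a `cnn_network`.
#' @param newdata windows matrix.
#' @param ... unused.
#' @return n x n_classes matrix of softmax probabilities (columns named by
#'   the class levels the network was trained on, when available).
#' @export
predict.cnn_network <- function(object, newdata, ...) {
  P <- network_forward(object, newdata, train = FALSE)$probs
  if (!is.null(object$class_levels)) colnames(P) <- object$class_levels
  P
}

#' Runtime shape probe
#'
#' Runs a small batch through the network and records the actual output
#' shape of every layer, for comparison with [infer_shapes()].
#'
#' @param net a `cnn_network`.
#' @param batch probe batch size.
#' @return data.frame with `name`, `length`, `channels` per layer.
#' @export
network_probe_shapes <- function(net, batch = 2) {
  spec <- net$spec
  X <- matrix(0, batch, spec$input_len)
  A <- as_input_cube(X)
  flat <- NULL
  out <- data.frame(name = character(), length = integer(),
                    channels = integer())
  rec <- function(name, len, ch)
    rbind(out, data.frame(name = name, length = as.integer(len),
                          channels = as.integer(ch)))
  for (l in spec$layers) {
    p <- net$params[[l$name]]
    if (l$kind == "conv1d") {
      A <- nn_conv1d_fwd(A, p$W, p$b, l$filter_size, l$stride)
      out <- rec(l$name, dim(A)[1], dim(A)[2])
    } else if (l$kind == "batch_norm") {
      out <- rec(l$name, dim(A)[1], dim(A)[2])
    } else if (l$kind == "max_pool1d") {
      A <- nn_maxpool1d_fwd(A, l$filter_size, l$stride)$Y
      out <- rec(l$name, dim(A)[1], dim(A)[2])
    } else if (l$kind == "avg_pool1d") {
      A <- nn_avgpool1d_fwd(A, l$filter_size, l$stride)
      out <- rec(l$name, dim(A)[1], dim(A)[2])
    } else if (l$kind == "global_avg_pool") {
      flat <- matrix(0, batch, dim(A)[2])
      out <- rec(l$name, 1L, ncol(flat))
      A <- NULL
    } else if (l$kind == "dense") {
      flat <- matrix(0, batch, l$units)
      out <- rec(l$name, 1L, l$units)
    }
  }
  out
}
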