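# Small CNN engine: forward/backward passes for the layer types the
# classifier needs (same-padding conv + ReLU, 2x2 max pool, batch norm,
# inverted dropout, dense, softmax), with SGD and Adam optimizers.
# Convolution is im2col + BLAS gemm; the im2col/col2im/maxpool kernels are
# in C++. Arrays are (H, W, C, N); dense activations are (features, N);
# class probabilities are (4, N).

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      d <- dim(x)
      cols <- im2col_cpp(x, d, ly$k)
      pre <- ly$W %*% cols + ly$b
      mask <- pre > 0
      out_mat <- pre * mask
      x <- aperm(array(out_mat, c(ly$Cout, d[1], d[2], d[4])), c(2, 3, 1, 4))
      caches[[i]] <- list(cols = cols, mask = mask, in_dim = d)
    } else if (ly$type == "maxpool") {
      d <- dim(x)
      res <- maxpool_fwd_cpp(x, d)
      caches[[i]] <- list(idx = res$idx, in_dim = d)
      x <- res$out
    } else if (ly$type == "batchnorm") {
      # channel-wise stats over batch and space: reshape to (H*W*N, C)
      d <- dim(x)
      C <- d[3]; m <- d[1] * d[2] * d[4]
      xp <- aperm(x, c(1, 2, 4, 3))
      dim(xp) <- c(m, C)
      if (training) {
        mu <- colMeans(xp)
        va <- colMeans(xp^2) - mu^2
        xhat <- (xp - rep(mu, each = m)) / rep(sqrt(va + ly$eps), each = m)
        out <- xhat * rep(ly$gamma, each = m) + rep(ly$beta, each = m)
        net$layers[[i]]$running_mean <- ly$momentum * ly$running_mean +
          (1 - ly$momentum) * mu
        net$layers[[i]]$running_var <- ly$momentum * ly$running_var +
          (1 - ly$momentum) * va
        caches[[i]] <- list(xhat = xhat, var = va, in_dim = d)
      } else {
        out <- (xp - rep(ly$running_mean, each = m)) /
          rep(sqrt(ly$running_var + ly$eps), each = m) *
          rep(ly$gamma, each = m) + rep(ly$beta, each = m)
        caches[[i]] <- NULL
      }
      dim(out) <- c(d[1], d[2], d[4], d[3])
      x <- aperm(out, c(1, 2, 4, 3))
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
        caches[[i]] <- list(mask = keep)
        x <- x * keep
      } else caches[[i]] <- NULL
    } else if (ly$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(in_dim = d)
      dim(x) <- c(prod(d[1:3]), d[4])
    } else if (ly$type == "dense") {
      pre <- ly$W %*% x + ly$b
      if (ly$act == "relu") {
        mask <- pre > 0
        caches[[i]] <- list(x_in = x, mask = mask)
        x <- pre * mask
      } else if (ly$act == "softmax") {
        z <- sweep(pre, 2, apply(pre, 2, max))
        e <- exp(z)
        p <- sweep(e, 2, colSums(e), "/")
        caches[[i]] <- list(x_in = x)
        x <- p
      } else {
        caches[[i]] <- list(x_in = x, mask = NULL)
        x <- pre
      }
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches, net = net)
}

# Backward pass; `dfinal` is the gradient wrt the *pre-softmax logits* of
# the final dense layer, i.e. (p - y)/n for softmax + cross-entropy.
nn_backward <- function(net, caches, dfinal) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dout <- dfinal
  for (i in rev(seq_len(L))) {
    ly <- net$layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      dpre <- if (i == L) dout else if (ly$act == "relu") dout * cc$mask else dout
      grads[[i]] <- list(W = dpre %*% t(cc$x_in) + 2 * net$l2 * ly$W,
                         b = rowSums(dpre))
      dout <- crossprod(ly$W, dpre)
    } else if (ly$type == "flatten") {
      dim(dout) <- cc$in_dim
    } else if (ly$type == "dropout") {
      if (!is.null(cc)) dout <- dout * cc$mask
    } else if (ly$type == "batchnorm") {
      d <- cc$in_dim; C <- d[3]; m <- d[1] * d[2] * d[4]
      dp <- aperm(dout, c(1, 2, 4, 3))
      dim(dp) <- c(m, C)
      xh <- cc$xhat
      grads[[i]] <- list(gamma = colSums(dp * xh), beta = colSums(dp))
      dxh <- dp * rep(ly$gamma, each = m)
      inv <- 1 / sqrt(cc$var + ly$eps)
      dxm <- rep(inv / m, each = m) *
        (m * dxh - rep(colSums(dxh), each = m) -
           xh * rep(colSums(dxh * xh), each = m))
      dim(dxm) <- c(d[1], d[2], d[4], d[3])
      dout <- aperm(dxm, c(1, 2, 4, 3))
    } else if (ly$type == "maxpool") {
      dout <- maxpool_bwd_cpp(dout, cc$idx, cc$in_dim)
    } else if (ly$type == "conv") {
      d <- cc$in_dim
      dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), ly$Cout, d[1] * d[2] * d[4])
      dpre <- dmat * cc$mask
      grads[[i]] <- list(W = dpre %*% t(cc$cols) + 2 * net$l2 * ly$W,
                         b = rowSums(dpre))
      dout <- col2im_cpp(crossprod(ly$W, dpre), d, ly$k)
    }
  }
  grads
}

# Mean cross-entropy over the batch plus the L2 weight penalty.
nn_loss <- function(net, probs, y_onehot) {
  data_loss <- -sum(y_onehot * log(pmax(probs, 1e-12))) / ncol(probs)
  data_loss + net$l2 * nn_weight_sumsq(net)
}

nn_weight_sumsq <- function(net) {
  s <- 0
  for (ly in net$layers)
    if (ly$type %in% c("conv", "dense")) s <- s + sum(ly$W^2)
  s
}

#' Count trainable parameters of a model
#'
#' @param net model from [build_model()].
#' @return Integer parameter count (conv/dense weights and biases, batch
#'   norm scale and shift).
#' @export
n_params <- function(net) {
  s <- 0L
  for (ly in net$layers) {
    if (ly$type %in% c("conv", "dense")) s <- s + length(ly$W) + length(ly$b)
    if (ly$type == "batchnorm") s <- s + length(ly$gamma) + length(ly$beta)
  }
  s
}

optimizer_init <- function(net, hp) {
  zeros_like <- function(g) lapply(g, function(p) p * 0)
  slots <- lapply(net$layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) list(W = ly$W * 0, b = ly$b * 0)
    else if (ly$type == "batchnorm") list(gamma = ly$gamma * 0, beta = ly$beta * 0)
    else NULL
  })
  list(type = hp$optimizer, lr = hp$learning_rate, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
       m = slots, v = slots)
}

optimizer_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (pn in names(g)) {
      if (opt$type == "sgd") {
        net$layers[[i]][[pn]] <- net$layers[[i]][[pn]] - opt$lr * g[[pn]]
      } else {
        opt$m[[i]][[pn]] <- opt$beta1 * opt$m[[i]][[pn]] + (1 - opt$beta1) * g[[pn]]
        opt$v[[i]][[pn]] <- opt$beta2 * opt$v[[i]][[pn]] + (1 - opt$beta2) * g[[pn]]^2
        mhat <- opt$m[[i]][[pn]] / (1 - opt$beta1^opt$t)
        vhat <- opt$v[[i]][[pn]] / (1 - opt$beta2^opt$t)
        net$layers[[i]][[pn]] <- net$layers[[i]][[pn]] -
          opt$lr * mhat / (sqrt(vhat) + opt$eps)
      }
    }
  }
  list(net = net, opt = opt)
}

#' Predict class probabilities for a batch of preprocessed slices
#'
#' Inference-mode forward pass (batch norm uses running statistics, dropout
#' disabled), processed in mini-batches to bound memory.
#'
#' @param net model from [build_model()].
#' @param x array `(side, side, 1, n)` of preprocessed slices in `[0, 1]`.
#' @param batch_size mini-batch size for the forward passes.
#' @return `n x 4` matrix of phase probabilities (columns in canonical
#'   phase order, rows sum to 1).
#' @export
model_predict_probs <- function(net, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, phase_levels()))
  at <- 1L
  while (at <= n) {
    j <- min(at + batch_size - 1L, n)
    xb <- x[, , , at:j, drop = FALSE]
    out[at:j, ] <- t(nn_forward(net, xb, training = FALSE)$out)
    at <- j + 1L
  }
  out
}
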