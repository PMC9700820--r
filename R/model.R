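#' CNN hyperparameter record
#'
#' The full configuration of the slice classifier and its optimizer.
#' Defaults are the tuned best configuration: 5 conv layers, 5x5 kernels,
#' 32 first-layer filters, dense width 32, 256 px input, batch norm on,
#' no augmentation, Adam at 1.483e-3, dropout 2.045e-4, L2 0.01, 50 epochs,
#' batch size 5.
#'
#' `image_side` values below 256 are permitted for desk-scale testing;
#' `learning_rate = 0` is permitted (freezes weights, useful as a control).
#' `filters_first = 32` is accepted alongside 8 and 16.
#'
#' @param conv_layers number of convolutional blocks, 2..6.
#' @param kernel_side convolution kernel side, one of 3, 5, 7.
#' @param filters_first filters in the first block (8, 16 or 32); doubled
#'   each subsequent block, capped at 256.
#' @param dense_size width of the hidden dense layer (8, 16, 24 or 32).
#' @param image_side input side length in pixels; must be divisible by
#'   `2^conv_layers`.
#' @param dropout_rate dropout probability in `[0, 1e-2]`.
#' @param augmentation logical; enable random flip/rotation/translation
#'   during training.
#' @param batch_norm logical; add batch normalization to each block.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate step size in `[0, 1e-2]`.
#' @param l2 L2 penalty on conv and dense kernels (fixed at 0.01 in the
#'   reference configuration).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @return A validated `hyperparams` list.
#' @export
#' @examples
#' hp <- hyperparams(conv_layers = 2, kernel_side = 3, filters_first = 8,
#'                   dense_size = 16, image_side = 64)
hyperparams <- function(conv_layers = 5L, kernel_side = 5L,
                        filters_first = 32L, dense_size = 32L,
                        image_side = 256L, dropout_rate = 2.045e-4,
                        augmentation = FALSE, batch_norm = TRUE,
                        optimizer = c("adam", "sgd"),
                        learning_rate = 1.483e-3, l2 = 0.01,
                        epochs = 50L, batch_size = 5L) {
  optimizer <- match.arg(optimizer)
  bad <- function(m) stop_ctphase(m, "ctphase_config_error")
  if (!conv_layers %in% 2:6) bad("conv_layers must be in 2..6")
  if (!kernel_side %in% c(3, 5, 7)) bad("kernel_side must be 3, 5 or 7")
  if (!filters_first %in% c(8, 16, 32)) bad("filters_first must be 8, 16 or 32")
  if (!dense_size %in% c(8, 16, 24, 32)) bad("dense_size must be 8, 16, 24 or 32")
  if (image_side < 8) bad("image_side must be >= 8")
  if (dropout_rate < 0 || dropout_rate > 1e-2)
    bad("dropout_rate must be in [0, 1e-2]")
  if (learning_rate < 0 || learning_rate > 1e-2)
    bad("learning_rate must be in [0, 1e-2]")
  if (epochs < 1) bad("epochs must be >= 1")
  if (batch_size < 1) bad("batch_size must be >= 1")
  structure(list(conv_layers = as.integer(conv_layers),
                 kernel_side = as.integer(kernel_side),
                 filters_first = as.integer(filters_first),
                 dense_size = as.integer(dense_size),
                 image_side = as.integer(image_side),
                 dropout_rate = dropout_rate,
                 augmentation = isTRUE(augmentation),
                 batch_norm = isTRUE(batch_norm),
                 optimizer = optimizer,
                 learning_rate = learning_rate,
                 l2 = l2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "hyperparams")
}

#' Build the configurable CNN
#'
#' Constructs the slice classifier: `conv_layers` blocks of
#' (same-padding convolution with ReLU and L2-penalized kernels, 2x2 max
#' pooling, optional batch normalization, dropout), with filter counts
#' doubling per block from `filters_first` and capped at 256; then flatten,
#' a ReLU dense layer of width `dense_size`, and a 4-way softmax output
#' (one unit per contrast phase). Weights use He initialization from the
#' current RNG state, or from `seed` when given, so identical
#' (hyperparameters, seed) pairs produce identical initial weights.
#'
#' @param hp a [hyperparams()] record.
#' @param seed optional integer seed for weight initialization.
#' @return A `ctphase_model` list with the layer stack and `hp` attached.
#' @export
build_model <- function(hp, seed = NULL) {
  if (!inherits(hp, "hyperparams")) hp <- do.call(hyperparams, hp)
  if (hp$image_side %% 2^hp$conv_layers != 0)
    stop_ctphase(sprintf(
      "image_side %d is not divisible by 2^conv_layers = %d",
      hp$image_side, 2^hp$conv_layers), "ctphase_geometry_error")
  make <- function() {
    layers <- list()
    cin <- 1L
    for (i in seq_len(hp$conv_layers)) {
      cout <- as.integer(min(hp$filters_first * 2^(i - 1L), 256L))
      k <- hp$kernel_side
      sdv <- sqrt(2 / (k * k * cin))
      layers[[length(layers) + 1L]] <- list(
        type = "conv", k = k, Cin = cin, Cout = cout, act = "relu",
        W = matrix(rnorm(cout * k * k * cin, 0, sdv), cout),
        b = numeric(cout))
      layers[[length(layers) + 1L]] <- list(type = "maxpool")
      if (hp$batch_norm)
        layers[[length(layers) + 1L]] <- list(
          type = "batchnorm", gamma = rep(1, cout), beta = numeric(cout),
          running_mean = numeric(cout), running_var = rep(1, cout),
          momentum = 0.9, eps = 1e-5)
      layers[[length(layers) + 1L]] <- list(type = "dropout",
                                            rate = hp$dropout_rate)
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    feat <- (hp$image_side / 2^hp$conv_layers)^2 * cin
    layers[[length(layers) + 1L]] <- list(
      type = "dense", act = "relu",
      W = matrix(rnorm(hp$dense_size * feat, 0, sqrt(2 / feat)),
                 hp$dense_size),
      b = numeric(hp$dense_size))
    layers[[length(layers) + 1L]] <- list(
      type = "dense", act = "softmax",
      W = matrix(rnorm(4L * hp$dense_size, 0, sqrt(2 / hp$dense_size)), 4L),
      b = numeric(4L))
    structure(list(layers = layers, l2 = hp$l2, hp = hp),
              class = "ctphase_model")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Categorical cross-entropy loss
#'
#' Mean over observations of `-sum_c y_{o,c} * log(p_{o,c})`, the training
#' criterion of the slice classifier. Probabilities are clipped below at
#' 1e-12 before the logarithm.
#'
#' @param true_onehot `n x 4` one-hot matrix of true classes (rows sum to 1).
#' @param predicted_probs `n x 4` matrix of predicted probabilities.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' y <- diag(4)
#' categorical_cross_entropy(y, y)                    # 0
#' categorical_cross_entropy(y, matrix(0.25, 4, 4))   # log(4)
categorical_cross_entropy <- function(true_onehot, predicted_probs) {
  true_onehot <- as.matrix(true_onehot)
  predicted_probs <- as.matrix(predicted_probs)
  if (!identical(dim(true_onehot), dim(predicted_probs)))
    stop_ctphase("true_onehot and predicted_probs dimensions differ",
                 "ctphase_dimension_error")
  -sum(true_onehot * log(pmax(predicted_probs, 1e-12))) / nrow(true_onehot)
}

# Inverse-mapped bilinear warp: rotation by `angle` degrees about the image
# centre followed by translation (dx, dy) pixels; out-of-frame samples are 0.
warp_bilinear <- function(m, angle, dx, dy) {
  n <- nrow(m); w <- ncol(m)
  th <- angle * pi / 180
  cr <- (n + 1) / 2; cc <- (w + 1) / 2
  r <- matrix(seq_len(n), n, w)
  cl <- matrix(seq_len(w), n, w, byrow = TRUE)
  rc <- r - cr - dy; ccn <- cl - cc - dx
  sr <- cos(th) * rc - sin(th) * ccn + cr
  sc <- sin(th) * rc + cos(th) * ccn + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get(r0, c0) + (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) + fr * fc * get(r0 + 1, c0 + 1)
  matrix(v, n, w)
}

#' Random training-time augmentation of a slice
#'
#' Applies, each with independent probability 0.5: a horizontal flip, a
#' rotation uniform in +/-10 degrees, and a translation uniform in +/-5%
#' of the image side (per axis). Draws come from the R RNG, so the result
#' is deterministic given the RNG state; any of the three transforms can
#' also be forced through the explicit arguments.
#'
#' @param x square numeric matrix in `[0, 1]`.
#' @param flip logical, force (or suppress) the horizontal flip.
#' @param angle numeric degrees, force the rotation (0 = none).
#' @param shift numeric length-2 `(dx, dy)` pixel translation (0 = none).
#' @return Matrix of the same shape, values in `[0, 1]`.
#' @export
augment <- function(x, flip = NULL, angle = NULL, shift = NULL) {
  side <- nrow(x)
  if (is.null(flip)) flip <- runif(1) < 0.5
  if (is.null(angle)) angle <- if (runif(1) < 0.5) runif(1, -10, 10) else 0
  if (is.null(shift))
    shift <- if (runif(1) < 0.5) runif(2, -0.05, 0.05) * side else c(0, 0)
  if (flip) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  if (angle != 0 || any(shift != 0))
    x <- warp_bilinear(x, angle, shift[1], shift[2])
  pmin(pmax(x, 0), 1)
}

#' Save a trained model
#'
#' Writes the model in R's native serialization alongside a sidecar JSON of
#' the hyperparameters used.
#'
#' @param net a `ctphase_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(net, file.path(dir, "model.rds"))
  jsonlite::write_json(unclass(net$hp), file.path(dir, "hyperparams.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir directory containing `model.rds`.
#' @return The `ctphase_model`.
#' @export
load_model <- function(dir) {
  p <- file.path(dir, "model.rds")
  if (!file.exists(p))
    stop_ctphase(paste0("no model.rds under ", dir), "ctphase_model_error")
  readRDS(p)
}
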