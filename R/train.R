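#' Exam-level train/validation/test split configuration
#'
#' Splits always operate on whole exams, never on slices, so no exam can
#' leak slices across partitions. The test count is `ceiling(n *
#' test_fraction)` (396 exams at 20% gives 80 test exams); the validation
#' set is carved from the remaining training pool the same way.
#'
#' @param test_fraction fraction of exams held out for testing.
#' @param val_fraction_of_train fraction of the training pool held out for
#'   validation.
#' @param seed integer seed controlling the shuffle.
#' @return A `split_config` list.
#' @export
split_config <- function(test_fraction = 0.2, val_fraction_of_train = 0.2,
                         seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction_of_train <= 0 || val_fraction_of_train >= 1)
    stop_ctphase("split fractions must be in (0, 1)", "ctphase_config_error")
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)), class = "split_config")
}

#' Split exams into train / validation / test partitions
#'
#' @param exams list of exams (or any vector of exam identifiers).
#' @param cfg a [split_config()].
#' @return List with `train`, `val`, `test`: disjoint subsets of `exams`
#'   covering it completely; deterministic given `cfg$seed`.
#' @export
#' @examples
#' sp <- split_exams(paste0("exam_", 1:396), split_config(seed = 1))
#' length(sp$test)  # 80
split_exams <- function(exams, cfg = split_config()) {
  n <- length(exams)
  if (n < 5L)
    stop_ctphase("need at least 5 exams to split", "ctphase_split_error")
  n_test <- ceiling(n * cfg$test_fraction)
  perm <- with_seed(cfg$seed, sample.int(n))
  test_i <- perm[seq_len(n_test)]
  rest <- perm[-seq_len(n_test)]
  n_val <- ceiling(length(rest) * cfg$val_fraction_of_train)
  val_i <- rest[seq_len(n_val)]
  train_i <- rest[-seq_len(n_val)]
  if (!length(train_i) || !length(val_i) || !length(test_i))
    stop_ctphase("too few exams for three non-empty partitions",
                 "ctphase_split_error")
  list(train = exams[sort(train_i)], val = exams[sort(val_i)],
       test = exams[sort(test_i)])
}

onehot <- function(y, M = 4L) {
  out <- matrix(0, M, length(y))
  out[cbind(y, seq_along(y))] <- 1
  out
}

evaluate_dataset <- function(net, data, batch_size = 128L) {
  probs <- model_predict_probs(net, data$x, batch_size)
  yh <- onehot(data$y)
  loss <- categorical_cross_entropy(t(yh), probs) + net$l2 * nn_weight_sumsq(net)
  acc <- mean(max.col(probs, ties.method = "first") == data$y)
  list(loss = loss, accuracy = acc, probs = probs)
}

#' Train the CNN on a slice dataset
#'
#' Minimizes categorical cross-entropy (plus the L2 weight penalty) with
#' the configured optimizer for `hp$epochs` epochs at batch size
#' `hp$batch_size`, recording train/validation loss and accuracy after each
#' epoch. The returned model carries the weights of the best epoch, the one
#' with minimum validation loss (earlier epoch on ties).
#'
#' @param hp a [hyperparams()] record.
#' @param train,val slice datasets from [exams_to_dataset()]; they must be
#'   exam-disjoint (not checked here -- use [split_exams()]).
#' @param seed optional seed controlling weight initialization, shuffling,
#'   dropout and augmentation draws.
#' @param verbose print one line per epoch.
#' @return List: `model` (best-epoch weights), `history` (data.frame with
#'   one row per epoch), `best_epoch`.
#' @export
train_model <- function(hp, train, val, seed = NULL, verbose = FALSE) {
  if (!length(train$y) || !length(val$y))
    stop_ctphase("train and val datasets must be non-empty",
                 "ctphase_config_error")
  if (dim(train$x)[1] != hp$image_side)
    stop_ctphase(sprintf("data side %d does not match hp$image_side %d",
                         dim(train$x)[1], hp$image_side),
                 "ctphase_config_error")
  run <- function() {
    net <- build_model(hp)
    opt <- optimizer_init(net, hp)
    n <- length(train$y)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_accuracy = numeric(0), val_loss = numeric(0),
                       val_accuracy = numeric(0))
    best <- list(epoch = NA_integer_, val_loss = Inf, net = net)
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      tl <- 0; tc <- 0
      for (start in seq(1L, n, by = hp$batch_size)) {
        bi <- ord[start:min(start + hp$batch_size - 1L, n)]
        xb <- train$x[, , , bi, drop = FALSE]
        if (hp$augmentation)
          for (j in seq_along(bi)) xb[, , 1L, j] <- augment(xb[, , 1L, j])
        yb <- onehot(train$y[bi])
        fw <- nn_forward(net, xb, training = TRUE)
        net <- fw$net
        if (hp$learning_rate > 0) {
          grads <- nn_backward(net, fw$caches, (fw$out - yb) / length(bi))
          st <- optimizer_step(net, grads, opt)
          net <- st$net; opt <- st$opt
        }
        tl <- tl + nn_loss(net, fw$out, yb) * length(bi)
        tc <- tc + sum(max.col(t(fw$out), ties.method = "first") ==
                         train$y[bi])
      }
      ev <- evaluate_dataset(net, val)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = tl / n, train_accuracy = tc / n,
        val_loss = ev$loss, val_accuracy = ev$accuracy))
      if (ev$loss < best$val_loss)
        best <- list(epoch = ep, val_loss = ev$loss, net = net)
      if (verbose)
        message(sprintf(
          "epoch %d/%d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          ep, hp$epochs, tl / n, tc / n, ev$loss, ev$accuracy))
    }
    list(model = best$net, history = hist, best_epoch = best$epoch)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' k-fold cross-validation configuration
#'
#' @param k number of folds (>= 2); every exam appears in exactly one fold.
#' @param seed integer seed controlling fold assignment.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5L, seed = 1L) {
  if (k < 2L) stop_ctphase("k must be >= 2", "ctphase_config_error")
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' Exam-level k-fold cross-validation
#'
#' Partitions exams into `k` folds; for each fold, trains on the other
#' `k - 1` folds (with a small validation carve-out for epoch selection)
#' and evaluates on the held-out fold at the slice, volume and exam levels.
#' Per-metric aggregates are reported as mean and standard deviation over
#' folds.
#'
#' @param exams list of labeled `exam_study` objects.
#' @param hp a [hyperparams()] record.
#' @param cv a [cv_config()].
#' @param max_slices slice cap per volume.
#' @param verbose print per-fold progress.
#' @return List: `folds` (data.frame, one row per fold with
#'   `slice_accuracy`, `volume_accuracy`, `exam_accuracy`,
#'   `mean_phases_correct`, macro `precision`/`recall`/`f1` at volume
#'   level), `summary` (data.frame of mean and sd per metric).
#' @export
cross_validate <- function(exams, hp, cv = cv_config(), max_slices = 150L,
                           verbose = FALSE) {
  n <- length(exams)
  if (cv$k > n)
    stop_ctphase(sprintf("k = %d exceeds the number of exams (%d)", cv$k, n),
                 "ctphase_config_error")
  fold_of <- with_seed(cv$seed, sample(rep_len(seq_len(cv$k), n)))
  rows <- list()
  for (f in seq_len(cv$k)) {
    test_ex <- exams[fold_of == f]
    pool <- exams[fold_of != f]
    n_val <- max(1L, ceiling(length(pool) * 0.2))
    val_ex <- pool[seq_len(n_val)]
    train_ex <- pool[-seq_len(n_val)]
    tr <- exams_to_dataset(train_ex, hp$image_side, max_slices)
    va <- exams_to_dataset(val_ex, hp$image_side, max_slices)
    fit <- train_model(hp, tr, va, seed = cv$seed + f)
    ev <- evaluate_exams(fit$model, test_ex, max_slices)
    cm <- confusion(ev$volume$true, ev$volume$predicted)
    clm <- classification_metrics(cm)
    es <- exam_level_summary(ev$exam$assignments, ev$exam$truths)
    rows[[f]] <- data.frame(
      fold = f,
      slice_accuracy = mean(ev$slice$predicted == ev$slice$true),
      volume_accuracy = mean(ev$volume$predicted == ev$volume$true),
      exam_accuracy = es$exam_accuracy,
      mean_phases_correct = es$mean_fraction_correct,
      precision = mean(clm$per_class$precision),
      recall = mean(clm$per_class$recall),
      f1 = mean(clm$per_class$f1))
    if (verbose)
      message(sprintf("fold %d/%d: volume acc %.3f, exam acc %.3f",
                      f, cv$k, rows[[f]]$volume_accuracy,
                      rows[[f]]$exam_accuracy))
  }
  folds <- do.call(rbind, rows)
  mets <- setdiff(names(folds), "fold")
  summary <- data.frame(metric = mets,
                        mean = vapply(mets, function(m) mean(folds[[m]]),
                                      numeric(1)),
                        sd = vapply(mets, function(m) sd(folds[[m]]),
                                    numeric(1)))
  rownames(summary) <- NULL
  list(folds = folds, summary = summary)
}
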