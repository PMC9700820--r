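#' Hyperparameter search space
#'
#' The categorical choices and log-uniform continuous ranges of the CNN
#' search space, plus the Hyperband budget. Categorical fields are sampled
#' uniformly; dropout and learning rate are sampled as `10^U` with `U`
#' uniform over the log10 range, assigning equal probability to each order
#' of magnitude.
#'
#' Defaults: `R = 50` epochs (the fixed training budget) and `eta = 3`
#' (the customary halving factor). `image_side_choices` defaults to the
#' production sizes 256/512 but can be reduced for desk-scale runs.
#'
#' @param R maximum resource (epochs) allocated to one configuration.
#' @param eta halving factor (integer >= 2).
#' @param seed integer seed for sampling and trial ordering.
#' @param image_side_choices candidate input sizes.
#' @param filters_first_choices candidate first-layer filter counts.
#' @param dropout_range,learning_rate_range positive 2-vectors (lo, hi).
#' @return A `tuning_space` list.
#' @export
tuning_space <- function(R = 50L, eta = 3L, seed = 1L,
                         image_side_choices = c(256L, 512L),
                         filters_first_choices = c(8L, 16L),
                         dropout_range = c(1e-6, 1e-2),
                         learning_rate_range = c(1e-6, 1e-2)) {
  if (eta < 2L || R < eta)
    stop_ctphase("need R >= eta >= 2", "ctphase_config_error")
  if (any(dropout_range <= 0) || any(learning_rate_range <= 0))
    stop_ctphase("continuous ranges must have positive bounds",
                 "ctphase_config_error")
  structure(list(
    R = as.integer(R), eta = as.integer(eta), seed = as.integer(seed),
    conv_layers_choices = 2:6,
    kernel_side_choices = c(3L, 5L, 7L),
    filters_first_choices = filters_first_choices,
    dense_size_choices = c(8L, 16L, 24L, 32L),
    image_side_choices = image_side_choices,
    dropout_range = dropout_range,
    learning_rate_range = learning_rate_range), class = "tuning_space")
}

#' Hyperband bracket/rung schedule
#'
#' With `s_max = floor(log_eta(R))`, bracket `s` (from `s_max` down to 0)
#' starts `n = ceiling((s_max + 1) / (s + 1) * eta^s)` configurations at
#' `r = R * eta^(-s)` epochs; each successive-halving rung keeps the top
#' `floor(n_i / eta)` configurations and multiplies the epoch budget by
#' `eta`, so every bracket's final rung trains for exactly `R` epochs.
#'
#' @param R maximum resource (epochs).
#' @param eta halving factor.
#' @return List of brackets; each has `s` and a data.frame `rungs` with
#'   `rung`, `n_configs`, `epochs`.
#' @export
#' @examples
#' sch <- hyperband_schedule(27, 3)
#' sch[[1]]$rungs  # 27 configs at 1 epoch, down to 1 config at 27
hyperband_schedule <- function(R, eta) {
  if (eta < 2 || R < eta)
    stop_ctphase("need R >= eta >= 2", "ctphase_config_error")
  s_max <- floor(round(log(R) / log(eta), 10))
  lapply(s_max:0, function(s) {
    n <- ceiling((s_max + 1) / (s + 1) * eta^s)
    r <- R * eta^(-s)
    rungs <- data.frame(rung = 0:s,
                        n_configs = vapply(0:s, function(i)
                          as.integer(max(1, floor(n / eta^i))), integer(1)),
                        epochs = r * eta^(0:s))
    list(s = s, rungs = rungs)
  })
}

#' Sample one configuration from the search space
#'
#' Categorical fields are uniform over their choices; dropout and learning
#' rate are log-uniform (`10^U`). Draws come from the current RNG state,
#' so sampling is deterministic under a fixed seed.
#'
#' @param space a [tuning_space()].
#' @return A [hyperparams()] record (epochs set to `space$R`).
#' @export
sample_config <- function(space) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  log_unif <- function(rg) 10^runif(1, log10(rg[1]), log10(rg[2]))
  hyperparams(
    conv_layers = pick(space$conv_layers_choices),
    kernel_side = pick(space$kernel_side_choices),
    filters_first = pick(space$filters_first_choices),
    dense_size = pick(space$dense_size_choices),
    image_side = pick(space$image_side_choices),
    dropout_rate = log_unif(space$dropout_range),
    augmentation = runif(1) < 0.5,
    batch_norm = runif(1) < 0.5,
    optimizer = pick(c("adam", "sgd")),
    learning_rate = log_unif(space$learning_rate_range),
    epochs = space$R)
}

#' Run the Hyperband search
#'
#' Executes the [hyperband_schedule()], retraining configurations from
#' scratch at each rung's epoch budget and promoting the top
#' `floor(n/eta)` by validation accuracy (ties broken by lower validation
#' loss, then earlier trial). The best configuration is the final-rung
#' trial with the highest validation accuracy across brackets. Failed
#' trials are recorded and excluded from promotion; the run continues.
#'
#' @param space a [tuning_space()].
#' @param train_data,val_data slice datasets from [exams_to_dataset()]
#'   (exam-disjoint); may be NULL when `eval_fn` is supplied.
#' @param eval_fn optional `function(hp, epochs)` returning a list with
#'   `val_accuracy` and `val_loss`; defaults to training the CNN with
#'   [train_model()]. Supplying a surrogate makes schedule behaviour
#'   testable without full trainings.
#' @param verbose print bracket/rung progress.
#' @return List: `best` ([hyperparams()]), `trials` (data.frame: `trial`,
#'   `bracket`, `rung`, `epochs`, `val_accuracy`, `val_loss`, `failed`),
#'   `configs` (list of sampled [hyperparams()], indexed by config id).
#' @export
run_hyperband <- function(space, train_data = NULL, val_data = NULL,
                          eval_fn = NULL, verbose = FALSE) {
  if (is.null(eval_fn)) {
    if (is.null(train_data) || is.null(val_data) ||
        !length(train_data$y) || !length(val_data$y))
      stop_ctphase("train and val datasets must be non-empty",
                   "ctphase_config_error")
    eval_fn <- function(hp, epochs) {
      hp$epochs <- as.integer(max(1, ceiling(epochs)))
      fit <- train_model(hp, train_data, val_data)
      best <- fit$history[fit$best_epoch, ]
      list(val_accuracy = best$val_accuracy, val_loss = best$val_loss)
    }
  }
  sched <- hyperband_schedule(space$R, space$eta)
  with_seed(space$seed, {
    configs <- list()
    trials <- list()
    finalists <- list()
    trial_no <- 0L
    for (br in sched) {
      n0 <- br$rungs$n_configs[1]
      ids <- length(configs) + seq_len(n0)
      for (id in ids) configs[[id]] <- sample_config(space)
      active <- ids
      for (ri in seq_len(nrow(br$rungs))) {
        epochs <- br$rungs$epochs[ri]
        res <- lapply(active, function(id) {
          trial_no <<- trial_no + 1L
          r <- tryCatch(eval_fn(configs[[id]], epochs),
                        error = function(e) {
                          warning(sprintf("trial %d failed: %s", trial_no,
                                          conditionMessage(e)), call. = FALSE)
                          NULL
                        })
          failed <- is.null(r)
          trials[[length(trials) + 1L]] <<- data.frame(
            trial = trial_no, config = id, bracket = br$s,
            rung = br$rungs$rung[ri], epochs = epochs,
            val_accuracy = if (failed) NA_real_ else r$val_accuracy,
            val_loss = if (failed) NA_real_ else r$val_loss,
            failed = failed)
          list(id = id, failed = failed,
               acc = if (failed) -Inf else r$val_accuracy,
               loss = if (failed) Inf else r$val_loss,
               trial = trial_no)
        })
        if (verbose)
          message(sprintf("bracket s=%d rung %d: %d configs at %.3g epochs",
                          br$s, br$rungs$rung[ri], length(active), epochs))
        ok <- Filter(function(r) !r$failed, res)
        ord <- order(-vapply(ok, `[[`, numeric(1), "acc"),
                     vapply(ok, `[[`, numeric(1), "loss"),
                     vapply(ok, `[[`, integer(1), "trial"))
        ok <- ok[ord]
        if (ri < nrow(br$rungs)) {
          keep <- min(br$rungs$n_configs[ri + 1], length(ok))
          active <- vapply(ok[seq_len(keep)], `[[`, integer(1), "id")
          if (!length(active)) break
        } else {
          finalists <- c(finalists, ok)
        }
      }
    }
    if (!length(finalists))
      stop_ctphase("every Hyperband trial failed", "ctphase_tuning_error")
    ord <- order(-vapply(finalists, `[[`, numeric(1), "acc"),
                 vapply(finalists, `[[`, numeric(1), "loss"),
                 vapply(finalists, `[[`, integer(1), "trial"))
    best_id <- finalists[[ord[1]]]$id
    list(best = configs[[best_id]], best_config = best_id,
         trials = do.call(rbind, trials), configs = configs)
  })
}
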