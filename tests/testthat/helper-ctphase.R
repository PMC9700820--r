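# Shared fixtures and independent oracles. Fixtures are generated in code
# (no stored binaries); expensive ones are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_hp <- function(...) {
  args <- modifyList(list(
    conv_layers = 2L, kernel_side = 3L, filters_first = 8L,
    dense_size = 16L, image_side = 64L, dropout_rate = 1e-6,
    augmentation = FALSE, batch_norm = FALSE, optimizer = "adam",
    learning_rate = 1e-3, epochs = 10L, batch_size = 8L), list(...))
  do.call(hyperparams, args)
}

noiseless_exam <- function(seed = 7, slices = 8L, side = 64L) {
  cached(sprintf("noiseless_%d_%d_%d", seed, slices, side),
         generate_exam(phantom_config(1L, slices, side, noise_sigma = 0,
                                      seed = seed), 0L))
}

# mean pixel of a structure in one volume, via the exam's label map
struct_mean <- function(exam, vol_idx, struct) {
  sel <- exam$structure_map == ctphase:::STRUCT_CODES[[struct]]
  mean(exam$volumes[[vol_idx]]$pixels[sel])
}

vol_of_phase <- function(exam, phase) {
  which(vapply(exam$volumes, function(v) identical(v$true_phase, phase),
               logical(1)))
}

# Independent brute-force simulator of the greedy exam pairing: literally
# enumerates every remaining (volume, phase) pair each round and takes the
# maximum, with ties resolved by phase order then volume order.
greedy_oracle <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  vols <- seq_len(nrow(m)); phs <- seq_len(4L)
  out <- setNames(rep(NA_character_, nrow(m)), rownames(m))
  while (length(vols)) {
    best <- -Inf; bv <- NA; bp <- NA
    for (p in phs) for (v in vols) {   # phase-major: canonical tie order
      if (m[v, p] > best) { best <- m[v, p]; bv <- v; bp <- p }
    }
    out[bv] <- phase_levels()[bp]
    vols <- setdiff(vols, bv); phs <- setdiff(phs, bp)
  }
  out
}

# One small trained classifier on noise-free 32 px phantoms, shared across
# test files (training it once keeps the suite fast).
trained_tiny_model <- function() {
  cached("trained_tiny", {
    cfg <- phantom_config(n_exams = 14L, slices_per_volume = 8L,
                          image_side = 32L, noise_sigma = 0, seed = 41L)
    exams <- generate_exams(cfg)
    hp <- tiny_hp(image_side = 32L, batch_size = 4L, epochs = 12L,
                  batch_norm = TRUE)
    tr <- exams_to_dataset(exams[1:10], 32L)
    va <- exams_to_dataset(exams[11:12], 32L)
    fit <- train_model(hp, tr, va, seed = 8L)
    list(model = fit$model, fit = fit, exams = exams, cfg = cfg)
  })
}

random_prob_matrix <- function(n_vol = 4L) {
  m <- matrix(runif(n_vol * 4L), n_vol)
  m / rowSums(m)
}
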