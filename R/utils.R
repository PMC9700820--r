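#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so generators can be reproducible without clobbering
#' the session RNG.
#'
#' @param seed integer seed (must be below 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Approximately evenly spaced subsample indices
#'
#' Indices `round(linspace(1, n, m))` with duplicates removed; first and
#' last index always included.
#'
#' @param n number of available items.
#' @param m maximum number to keep.
#' @return Increasing integer vector of length `min(n, m)` or fewer.
#' @keywords internal
linspace_indices <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  if (n <= m) return(seq_len(n))
  idx <- round(seq(1, n, length.out = m))
  unique(as.integer(idx))
}

#' Bilinear image resize
#'
#' Resizes a numeric matrix to `side x side` with bilinear interpolation
#' (corner-aligned sampling grid). A no-op when the size already matches.
#'
#' @param m numeric matrix.
#' @param side target side length in pixels.
#' @return `side x side` numeric matrix.
#' @keywords internal
resize_bilinear <- function(m, side) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == side && nc == side) return(m)
  interp_axis <- function(n_src, n_dst) {
    if (n_src == 1L) return(list(lo = rep(1L, n_dst), hi = rep(1L, n_dst),
                                 f = rep(0, n_dst)))
    pos <- seq(1, n_src, length.out = n_dst)
    lo <- pmin(floor(pos), n_src - 1L)
    list(lo = as.integer(lo), hi = as.integer(lo + 1L), f = pos - lo)
  }
  ay <- interp_axis(nr, side)
  m2 <- m[ay$lo, , drop = FALSE] * (1 - ay$f) + m[ay$hi, , drop = FALSE] * ay$f
  ax <- interp_axis(nc, side)
  m3 <- m2[, ax$lo, drop = FALSE] * rep(1 - ax$f, each = side) +
    m2[, ax$hi, drop = FALSE] * rep(ax$f, each = side)
  m3
}

# All 24 permutations of 1:4, in lexicographic order.
permutations4 <- function() {
  out <- matrix(NA_integer_, 24L, 4L)
  i <- 0L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    i <- i + 1L
    out[i, ] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  out
}

stop_ctphase <- function(msg, class) {
  stop(structure(class = c(class, "ctphase_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
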