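#' Contrast phase labels
#'
#' The four contrast phases of a multiphase liver CT protocol, in canonical
#' acquisition order: unenhanced (pre-contrast), arterial (~35-45 s after
#' injection), portal-venous (~60-75 s) and delayed (~3 min). This order is
#' total and stable; it is also the deterministic tie-break order used
#' throughout the package.
#'
#' @return Character vector of the four phase names in canonical order.
#' @export
#' @examples
#' phase_levels()
phase_levels <- function() c("unenhanced", "arterial", "portal", "delayed")

#' Coerce to a phase factor
#'
#' @param x character vector (or factor) of phase names.
#' @return Factor with levels in canonical phase order.
#' @export
phase_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), phase_levels())
  if (length(bad))
    stop_ctphase(paste0("unknown phase label(s): ", paste(bad, collapse = ", ")),
                 "ctphase_label_error")
  factor(x, levels = phase_levels())
}
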