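#' Contrast kinetics table for the synthetic phantom
#'
#' Baseline attenuation (HU) and additive per-phase enhancement deltas (HU)
#' for each rendered structure. The values are not calibrated to any scanner;
#' they are chosen to respect the temporal ordering of a 4-phase liver
#' protocol: aortic enhancement peaks in the arterial phase, portal vein and
#' liver parenchyma peak in the portal phase, and excreted contrast makes the
#' urinary collecting system by far the brightest structure in the delayed
#' phase. Unenhanced deltas are all zero by definition.
#'
#' @return A data.frame with columns `structure`, `baseline`, and one delta
#'   column per phase (`unenhanced`, `arterial`, `portal`, `delayed`).
#' @export
#' @examples
#' kinetics_table()
kinetics_table <- function() {
  k <- data.frame(
    structure = c("air", "soft_tissue", "bone", "liver", "kidney_cortex",
                  "collecting_system", "aorta", "portal_vein"),
    baseline  = c(-1000, 40, 700, 55, 35, 10, 45, 45),
    unenhanced = 0,
    arterial  = c(0, 0, 0, 15, 100, 0, 250, 30),
    portal    = c(0, 0, 0, 55, 120, 0, 120, 130),
    delayed   = c(0, 0, 0, 25, 60, 300, 60, 60),
    stringsAsFactors = FALSE
  )
  rownames(k) <- k$structure
  k
}

#' Expected mean structure intensity per phase
#'
#' `baseline + delta` for every (structure, phase) pair: the centroids used
#' by the nearest-centroid reference classifier.
#'
#' @param kin kinetics table, as returned by [kinetics_table()].
#' @return Numeric matrix, structures x phases.
#' @keywords internal
kinetics_centroids <- function(kin = kinetics_table()) {
  m <- as.matrix(kin[, phase_levels()]) + kin$baseline
  rownames(m) <- kin$structure
  m
}
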