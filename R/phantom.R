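STRUCT_CODES <- c(air = 0L, soft_tissue = 1L, bone = 2L, liver = 3L,
                  kidney_cortex = 4L, collecting_system = 5L,
                  aorta = 6L, portal_vein = 7L)

MANUFACTURERS <- c("Philips", "GE Medical Systems", "Siemens Health", "Toshiba")
MANUFACTURER_WEIGHTS <- c(214, 91, 90, 2)

#' Phantom generator configuration
#'
#' Describes a synthetic multiphase abdominal CT dataset: each exam carries
#' exactly one volume per contrast phase, rendered as 2-D ellipse anatomy
#' with per-exam geometric jitter, per-phase enhancement from
#' [kinetics_table()], and i.i.d. Gaussian noise in HU.
#'
#' Defaults describe a desk-scale world: 64 px slices, 24 slices per volume
#' and 8 HU noise, small enough to train a CNN on one CPU while keeping the
#' four phases separable by their contrast kinetics.
#'
#' @param n_exams number of exams to generate.
#' @param slices_per_volume slices per phase volume (>= 4).
#' @param image_side slice side length in pixels (>= 32).
#' @param noise_sigma standard deviation of additive Gaussian noise, HU.
#' @param seed integer seed; together with the exam index it fully
#'   determines every pixel.
#' @param confounder_mode one of `"none"`, `"slow_excretion"`,
#'   `"portal_thrombosis"`.
#' @param confounder_fraction fraction of exams (in `[0, 1]`) to which the
#'   confounder is applied.
#' @return A `phantom_config` list.
#' @export
#' @examples
#' cfg <- phantom_config(n_exams = 2, slices_per_volume = 8, image_side = 64)
phantom_config <- function(n_exams, slices_per_volume = 24L, image_side = 64L,
                           noise_sigma = 8, seed = 1L,
                           confounder_mode = c("none", "slow_excretion",
                                               "portal_thrombosis"),
                           confounder_fraction = 0) {
  confounder_mode <- match.arg(confounder_mode)
  bad <- function(m) stop_ctphase(m, "ctphase_config_error")
  if (!is.numeric(n_exams) || length(n_exams) != 1L || n_exams < 1)
    bad("n_exams must be a positive integer")
  if (slices_per_volume < 4) bad("slices_per_volume must be >= 4")
  if (image_side < 32) bad("image_side must be >= 32")
  if (noise_sigma < 0) bad("noise_sigma must be non-negative")
  if (confounder_fraction < 0 || confounder_fraction > 1)
    bad("confounder_fraction must be in [0, 1]")
  structure(list(n_exams = as.integer(n_exams),
                 slices_per_volume = as.integer(slices_per_volume),
                 image_side = as.integer(image_side),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 confounder_mode = confounder_mode,
                 confounder_fraction = confounder_fraction),
            class = "phantom_config")
}

exam_seed <- function(seed, exam_index) {
  as.integer((abs(seed) %% 50021) * 40009 + exam_index * 7919 + 17) %% 2147483647L
}

ellipse_mask <- function(side, cx, cy, rx, ry) {
  x <- matrix(seq_len(side), side, side, byrow = TRUE)
  y <- matrix(seq_len(side), side, side)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

# Draw the per-exam anatomy as a structure-code label map (side, side, S).
# Positions are fractions of the image side; jitter is +/-10% on radii and
# +/-5 px on centres, with paired kidney / collecting-system jitter so the
# collecting system stays inside its kidney. The collecting system appears
# only in the caudal half of the slices (excreted contrast pools inferiorly).
phantom_structure_map <- function(side, n_slices) {
  jit_r <- function() runif(1, 0.9, 1.1)
  jit_p <- function() runif(2, -5, 5)
  s <- side
  base <- matrix(STRUCT_CODES[["air"]], s, s)
  paint <- function(map, code, cx, cy, rx, ry) {
    map[ellipse_mask(s, cx, cy, rx, ry)] <- code
    map
  }
  jb <- jit_p(); jl <- jit_p(); jk1 <- jit_p(); jk2 <- jit_p()
  js <- jit_p(); ja <- jit_p(); jp <- jit_p()
  base <- paint(base, STRUCT_CODES[["soft_tissue"]],
                0.50 * s + jb[1], 0.52 * s + jb[2],
                0.44 * s * jit_r(), 0.38 * s * jit_r())
  base <- paint(base, STRUCT_CODES[["liver"]],
                0.32 * s + jl[1], 0.40 * s + jl[2],
                0.23 * s * jit_r(), 0.22 * s * jit_r())
  kid <- list(c(0.30 * s + jk1[1], 0.70 * s + jk1[2]),
              c(0.70 * s + jk2[1], 0.70 * s + jk2[2]))
  for (kc in kid)
    base <- paint(base, STRUCT_CODES[["kidney_cortex"]],
                  kc[1], kc[2], 0.08 * s * jit_r(), 0.06 * s * jit_r())
  base <- paint(base, STRUCT_CODES[["bone"]],
                0.50 * s + js[1], 0.80 * s + js[2],
                0.06 * s * jit_r(), 0.06 * s * jit_r())
  base <- paint(base, STRUCT_CODES[["aorta"]],
                0.52 * s + ja[1] * 0.4, 0.66 * s + ja[2] * 0.4,
                0.035 * s * jit_r(), 0.035 * s * jit_r())
  base <- paint(base, STRUCT_CODES[["portal_vein"]],
                0.46 * s + jp[1] * 0.4, 0.50 * s + jp[2] * 0.4,
                0.030 * s * jit_r(), 0.030 * s * jit_r())
  caudal <- base
  rcs <- 0.030 * s * jit_r()
  for (kc in kid)
    caudal <- paint(caudal, STRUCT_CODES[["collecting_system"]],
                    kc[1], kc[2], rcs, rcs)
  map <- array(0L, dim = c(s, s, n_slices))
  caudal_from <- floor(n_slices / 2) + 1L
  for (z in seq_len(n_slices))
    map[, , z] <- if (z >= caudal_from) caudal else base
  map
}

#' Generate one synthetic multiphase exam
#'
#' Renders a 4-volume exam (one volume per contrast phase) from the exam's
#' randomized anatomy and the kinetics table, adds Gaussian noise, and
#' applies the configured confounder to this exam if its per-exam draw falls
#' below `confounder_fraction`. Fully reproducible from
#' `(config$seed, exam_index)`; the base pixel stream does not depend on the
#' confounder settings, so confounded and clean datasets share anatomy.
#'
#' @param config a [phantom_config()].
#' @param exam_index 0-based exam index, `< config$n_exams`.
#' @return An `exam_study` object: `exam_id`, `study_uid`, `volumes` (list of
#'   `volume_series` in randomized order, each with HU `pixels` of dim
#'   `(side, side, slices)` and a `true_phase`), the structure label map,
#'   `manufacturer` and the applied `confounder`.
#' @export
#' @examples
#' ex <- generate_exam(phantom_config(1, 8, 64, seed = 7), 0)
#' sapply(ex$volumes, function(v) v$true_phase)
generate_exam <- function(config, exam_index) {
  if (!inherits(config, "phantom_config"))
    config <- do.call(phantom_config, config)
  if (exam_index < 0 || exam_index >= config$n_exams)
    stop_ctphase("exam_index out of range", "ctphase_config_error")
  s <- config$image_side
  S <- config$slices_per_volume
  kin <- kinetics_table()
  base_lut <- kin$baseline[match(names(STRUCT_CODES), kin$structure)]
  exam <- with_seed(exam_seed(config$seed, exam_index), {
    map <- phantom_structure_map(s, S)
    manufacturer <- sample(MANUFACTURERS, 1, prob = MANUFACTURER_WEIGHTS)
    vol_order <- sample(4L)
    u_confound <- runif(1)
    volumes <- vector("list", 4L)
    for (ph_i in seq_len(4L)) {
      ph <- phase_levels()[ph_i]
      delta_lut <- kin[[ph]][match(names(STRUCT_CODES), kin$structure)]
      clean <- base_lut[map + 1L] + delta_lut[map + 1L]
      noise <- if (config$noise_sigma > 0)
        rnorm(length(clean), 0, config$noise_sigma) else 0
      pix <- array(clean + noise, dim = c(s, s, S))
      volumes[[ph_i]] <- structure(list(
        series_uid = sprintf("1.2.826.0.1.3680043.9717.%d.%d.%d",
                             config$seed, exam_index, ph_i),
        pixels = pix,
        z_positions = (seq_len(S) - 1) * 2.5,
        instance_numbers = seq_len(S),
        source_paths = NULL,
        manufacturer = manufacturer,
        series_description = "",
        true_phase = ph), class = "volume_series")
    }
    volumes <- volumes[vol_order]
    for (j in seq_along(volumes))
      volumes[[j]]$series_description <- sprintf("SERIES_%d", j)
    structure(list(
      exam_id = sprintf("EXAM_%04d", exam_index),
      study_uid = sprintf("1.2.826.0.1.3680043.9717.%d.%d",
                          config$seed, exam_index),
      volumes = volumes,
      structure_map = map,
      manufacturer = manufacturer,
      confounder = "none",
      confounder_draw = u_confound), class = "exam_study")
  })
  if (config$confounder_mode != "none" &&
      exam$confounder_draw < config$confounder_fraction)
    exam <- apply_confounder(exam, config$confounder_mode)
  exam
}

#' Generate all exams of a phantom configuration
#'
#' @param config a [phantom_config()].
#' @return List of `exam_study` objects of length `config$n_exams`.
#' @export
generate_exams <- function(config) {
  lapply(seq_len(config$n_exams) - 1L, function(i) generate_exam(config, i))
}

find_phase_volume <- function(exam, phase) {
  for (j in seq_along(exam$volumes))
    if (identical(exam$volumes[[j]]$true_phase, phase)) return(j)
  NA_integer_
}

#' Apply a documented failure-mode confounder to an exam
#'
#' Two confounders emulate reported real-world misclassification causes:
#' `slow_excretion` removes excreted contrast from the collecting system in
#' the delayed phase (slow cardiac output / renal excretion), making delayed
#' resemble portal; `portal_thrombosis` reduces portal-phase liver and
#' portal-vein enhancement to 25% of nominal, making portal resemble
#' delayed. Ground-truth labels are never changed: the confounder makes
#' phases look alike, it does not relabel them. Re-applying a mode already
#' applied to the exam is a no-op.
#'
#' @param exam an `exam_study` from [generate_exam()] (must carry its
#'   structure map).
#' @param mode `"none"`, `"slow_excretion"` or `"portal_thrombosis"`.
#' @return The modified `exam_study`.
#' @export
apply_confounder <- function(exam, mode) {
  if (identical(mode, "none")) return(exam)
  if (!mode %in% c("slow_excretion", "portal_thrombosis"))
    stop_ctphase(paste0("unknown confounder mode: ", mode),
                 "ctphase_config_error")
  if (identical(exam$confounder, mode)) return(exam)
  kin <- kinetics_table()
  if (mode == "slow_excretion") {
    j <- find_phase_volume(exam, "delayed")
    if (is.na(j))
      stop_ctphase("exam has no delayed volume", "ctphase_config_error")
    sel <- exam$structure_map == STRUCT_CODES[["collecting_system"]]
    exam$volumes[[j]]$pixels[sel] <-
      exam$volumes[[j]]$pixels[sel] - kin["collecting_system", "delayed"]
  } else {
    j <- find_phase_volume(exam, "portal")
    if (is.na(j))
      stop_ctphase("exam has no portal volume", "ctphase_config_error")
    for (st in c("liver", "portal_vein")) {
      sel <- exam$structure_map == STRUCT_CODES[[st]]
      exam$volumes[[j]]$pixels[sel] <-
        exam$volumes[[j]]$pixels[sel] - 0.75 * kin[st, "portal"]
    }
  }
  exam$confounder <- mode
  exam
}

#' Nearest-centroid reference phase classifier
#'
#' A deliberately simple decision rule used as the well-posedness oracle for
#' the phantom: for each volume it measures the mean pixel value inside each
#' structure mask and assigns the phase whose nominal centroids
#' (`baseline + delta` from [kinetics_table()]) are closest in squared
#' distance. At low noise and without confounders this rule is perfect,
#' which guarantees the CNN's learning task is well-posed.
#'
#' @param exam an `exam_study` carrying its structure map.
#' @return List with `predicted` (factor, one per volume), `true` (factor),
#'   and `dist` (volumes x phases squared-distance matrix).
#' @export
nearest_centroid_phase <- function(exam) {
  cen <- kinetics_centroids()
  structs <- rownames(cen)
  masks <- lapply(structs, function(st) exam$structure_map == STRUCT_CODES[[st]])
  names(masks) <- structs
  nv <- length(exam$volumes)
  d <- matrix(NA_real_, nv, length(phase_levels()),
              dimnames = list(NULL, phase_levels()))
  for (j in seq_len(nv)) {
    obs <- vapply(structs, function(st) mean(exam$volumes[[j]]$pixels[masks[[st]]]),
                  numeric(1))
    for (ph in phase_levels())
      d[j, ph] <- sum((obs - cen[, ph])^2)
  }
  pred <- phase_levels()[apply(d, 1, which.min)]
  list(predicted = phase_factor(pred),
       true = phase_factor(vapply(exam$volumes, function(v)
         v$true_phase %||% NA_character_, character(1))),
       dist = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom dataset as DICOM series
#'
#' Writes each volume as a DICOM Part-10 series (one file per slice, 16-bit
#' signed HU pixels, distinct SeriesInstanceUID per volume, monotone slice
#' positions) under `out_dir/<exam_id>/SERIES_<n>/`. SeriesDescription is a
#' deliberately uninformative `"SERIES_<n>"`, reproducing the real-world
#' premise that series naming carries no usable phase information. A
#' `manifest.json` mapping series UIDs to true phases is written alongside.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (`exam_id`, `series_uid`,
#'   `series_dir`, `true_phase`, `manufacturer`, `confounder`).
#' @export
write_phantom_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_ctphase(paste0("cannot create output directory: ", out_dir),
                 "ctphase_write_error")
  rows <- list()
  for (i in seq_len(config$n_exams) - 1L) {
    exam <- generate_exam(config, i)
    exam_dir <- file.path(out_dir, exam$exam_id)
    for (j in seq_along(exam$volumes)) {
      vol <- exam$volumes[[j]]
      series_dir <- file.path(exam_dir, vol$series_description)
      dir.create(series_dir, recursive = TRUE, showWarnings = FALSE)
      S <- dim(vol$pixels)[3]
      for (z in seq_len(S)) {
        dicom_write_slice(
          file.path(series_dir, sprintf("slice_%03d.dcm", z)),
          vol$pixels[, , z],
          meta = list(study_uid = exam$study_uid,
                      series_uid = vol$series_uid,
                      sop_uid = sprintf("%s.%d", vol$series_uid, z),
                      instance_number = vol$instance_numbers[z],
                      z_position = vol$z_positions[z],
                      series_description = vol$series_description,
                      manufacturer = exam$manufacturer))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        exam_id = exam$exam_id, series_uid = vol$series_uid,
        series_dir = file.path(exam$exam_id, vol$series_description),
        true_phase = vol$true_phase, manufacturer = exam$manufacturer,
        confounder = exam$confounder, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a written phantom dataset with ground-truth labels
#'
#' Reads `manifest.json`, loads each exam directory through [load_study()],
#' and joins the true phase labels onto the volumes by SeriesInstanceUID.
#'
#' @param dir dataset directory produced by [write_phantom_dataset()].
#' @return List of labeled `exam_study` objects.
#' @export
load_phantom_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop_ctphase(paste0("no manifest.json in ", dir), "ctphase_config_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  exams <- lapply(unique(manifest$exam_id), function(eid) {
    exam <- load_study(file.path(dir, eid))
    exam$exam_id <- eid
    rows <- manifest[manifest$exam_id == eid, ]
    for (j in seq_along(exam$volumes)) {
      hit <- match(exam$volumes[[j]]$series_uid, rows$series_uid)
      if (!is.na(hit)) exam$volumes[[j]]$true_phase <- rows$true_phase[hit]
    }
    exam$manufacturer <- rows$manufacturer[1]
    exam$confounder <- rows$confounder[1]
    exam
  })
  exams
}
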