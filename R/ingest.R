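#' Load a DICOM study directory into an exam
#'
#' Recursively reads every file under `study_dir`, groups readable DICOM
#' slices into volumes by SeriesInstanceUID, and orders slices within each
#' volume by ascending z position (ImagePositionPatient), breaking ties by
#' InstanceNumber. SeriesDescription is retained as metadata but is never
#' consulted for any phase decision -- series naming is unreliable across
#' scanners, which is the premise of the whole pipeline. Unreadable or
#' non-image files are skipped with a warning.
#'
#' @param study_dir directory containing one study's DICOM files.
#' @return An `exam_study`: `exam_id` (the StudyInstanceUID), `volumes`
#'   (list of `volume_series` with HU `pixels` arrays, z positions,
#'   instance numbers and source paths).
#' @export
load_study <- function(study_dir) {
  files <- list.files(study_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(dicom_read_slice(f), error = function(e) {
      warning(sprintf("skipping %s: %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(s)) { s$source_path <- f; slices[[length(slices) + 1L]] <- s }
  }
  if (!length(slices))
    stop_ctphase(paste0("no readable DICOM files under ", study_dir),
                 "ctphase_empty_study_error")
  study_uids <- unique(vapply(slices, `[[`, character(1), "study_uid"))
  study_uids <- study_uids[!is.na(study_uids)]
  if (length(study_uids) > 1L)
    stop_ctphase(paste0("directory contains multiple studies: ",
                        paste(study_uids, collapse = ", ")),
                 "ctphase_multi_study_error")
  series_uids <- vapply(slices, `[[`, character(1), "series_uid")
  volumes <- lapply(unique(series_uids), function(uid) {
    ss <- slices[series_uids == uid]
    z <- vapply(ss, `[[`, numeric(1), "z_position")
    inst <- vapply(ss, function(x) x$instance_number %||% NA_integer_,
                   integer(1))
    ord <- order(z, inst, na.last = TRUE)
    ss <- ss[ord]
    d <- dim(ss[[1]]$pixels)
    pix <- array(NA_real_, dim = c(d[1], d[2], length(ss)))
    for (i in seq_along(ss)) pix[, , i] <- ss[[i]]$pixels
    structure(list(
      series_uid = uid,
      pixels = pix,
      z_positions = z[ord],
      instance_numbers = inst[ord],
      source_paths = vapply(ss, `[[`, character(1), "source_path"),
      manufacturer = ss[[1]]$manufacturer,
      series_description = ss[[1]]$series_description,
      true_phase = NULL), class = "volume_series")
  })
  structure(list(exam_id = if (length(study_uids)) study_uids else basename(study_dir),
                 study_uid = if (length(study_uids)) study_uids else NA_character_,
                 volumes = volumes), class = "exam_study")
}

#' Subsample a volume to approximately evenly spaced slices
#'
#' Keeps all slices when the volume has at most `max_slices`; otherwise
#' keeps the slices at `round(linspace(first, last, max_slices))` after
#' de-duplication, preserving order. The first and last slices are always
#' retained. Idempotent: sampling a sampled volume returns it unchanged.
#'
#' @param volume a `volume_series`.
#' @param max_slices maximum slices to keep (default 150).
#' @return The subsampled `volume_series`.
#' @export
sample_slices <- function(volume, max_slices = 150L) {
  if (max_slices < 1L)
    stop_ctphase("max_slices must be >= 1", "ctphase_config_error")
  n <- dim(volume$pixels)[3]
  if (is.na(n) || n < 1L)
    stop_ctphase("empty volume", "ctphase_empty_volume_error")
  idx <- linspace_indices(n, max_slices)
  if (length(idx) == n) return(volume)
  volume$pixels <- volume$pixels[, , idx, drop = FALSE]
  volume$z_positions <- volume$z_positions[idx]
  volume$instance_numbers <- volume$instance_numbers[idx]
  if (!is.null(volume$source_paths))
    volume$source_paths <- volume$source_paths[idx]
  volume
}

#' Preprocess one slice into a model-ready array
#'
#' Clips HU to the `[-150, 250]` soft-tissue window, rescales linearly to
#' `[0, 1]`, and resizes to `image_side x image_side` with bilinear
#' interpolation. The window retains liver/vascular contrast-enhancement
#' dynamics while discarding bone and air extremes.
#'
#' @param pixels_hu numeric matrix of HU values.
#' @param image_side target side length in pixels.
#' @param hu_window length-2 numeric clipping window, default `c(-150, 250)`.
#' @return `image_side x image_side` matrix with values in `[0, 1]`.
#' @export
preprocess_slice <- function(pixels_hu, image_side, hu_window = c(-150, 250)) {
  if (!is.matrix(pixels_hu) || !all(is.finite(pixels_hu)))
    stop_ctphase("corrupt slice pixel data", "ctphase_decode_error")
  x <- pmin(pmax(pixels_hu, hu_window[1]), hu_window[2])
  x <- (x - hu_window[1]) / (hu_window[2] - hu_window[1])
  resize_bilinear(x, image_side)
}

#' Preprocess a whole volume
#'
#' [sample_slices()] then [preprocess_slice()] applied to each remaining
#' slice.
#'
#' @param volume a `volume_series`.
#' @param image_side target side length.
#' @param max_slices slice cap passed to [sample_slices()].
#' @return Array `(image_side, image_side, n_slices)` in `[0, 1]`.
#' @export
preprocess_volume <- function(volume, image_side, max_slices = 150L) {
  volume <- sample_slices(volume, max_slices)
  n <- dim(volume$pixels)[3]
  out <- array(NA_real_, dim = c(image_side, image_side, n))
  for (i in seq_len(n))
    out[, , i] <- preprocess_slice(volume$pixels[, , i], image_side)
  out
}

#' Flatten labeled exams into a slice-level training dataset
#'
#' @param exams list of labeled `exam_study` objects (every volume must
#'   carry a `true_phase`).
#' @param image_side model input side length.
#' @param max_slices slice cap per volume.
#' @return List: `x` array `(side, side, 1, n_slices)`, `y` integer class
#'   index in 1..4 (canonical phase order), `exam_id` and `series_uid`
#'   character vectors, one entry per slice.
#' @export
exams_to_dataset <- function(exams, image_side, max_slices = 150L) {
  vols <- list(); labs <- character(0); eids <- character(0); uids <- character(0)
  for (exam in exams) {
    for (vol in exam$volumes) {
      if (is.null(vol$true_phase))
        stop_ctphase("exams_to_dataset requires labeled volumes",
                     "ctphase_config_error")
      arr <- preprocess_volume(vol, image_side, max_slices)
      vols[[length(vols) + 1L]] <- arr
      n <- dim(arr)[3]
      labs <- c(labs, rep(vol$true_phase, n))
      eids <- c(eids, rep(exam$exam_id, n))
      uids <- c(uids, rep(vol$series_uid, n))
    }
  }
  n_total <- length(labs)
  x <- array(NA_real_, dim = c(image_side, image_side, 1L, n_total))
  at <- 0L
  for (arr in vols) {
    n <- dim(arr)[3]
    x[, , 1L, at + seq_len(n)] <- arr
    at <- at + n
  }
  list(x = x, y = as.integer(phase_factor(labs)),
       exam_id = eids, series_uid = uids)
}
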