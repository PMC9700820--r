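#' Per-slice phase probabilities for a volume
#'
#' Samples and preprocesses the volume's slices to the model's input
#' geometry, then runs an inference-mode forward pass.
#'
#' @param net a `ctphase_model`.
#' @param volume a `volume_series`.
#' @param max_slices slice cap passed to [sample_slices()].
#' @return `n_slices x 4` matrix of probabilities in slice order, columns
#'   in canonical phase order, each row summing to 1.
#' @export
predict_slices <- function(net, volume, max_slices = 150L) {
  if (!inherits(net, "ctphase_model"))
    stop_ctphase("net is not a ctphase_model", "ctphase_model_error")
  arr <- preprocess_volume(volume, net$hp$image_side, max_slices)
  d <- dim(arr)
  dim(arr) <- c(d[1], d[2], 1L, d[3])
  model_predict_probs(net, arr)
}

#' Volume-level prediction from slice scores
#'
#' The volume's phase is the one with the highest mean score across its
#' slices; exact ties are broken by canonical phase order.
#'
#' @param scores `n_slices x 4` matrix of per-slice probabilities.
#' @return A `volume_score` list: `mean_probs` (named length-4 vector),
#'   `predicted` (phase name), `confidence` (`max(mean_probs)`).
#' @export
#' @examples
#' s <- rbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.5, 0.2, 0.1))
#' predict_volume(s)$predicted  # "unenhanced"
predict_volume <- function(scores) {
  scores <- as.matrix(scores)
  if (!nrow(scores))
    stop_ctphase("no slice scores supplied", "ctphase_empty_input_error")
  if (ncol(scores) != 4L)
    stop_ctphase("scores must have 4 columns", "ctphase_dimension_error")
  mp <- colMeans(scores)
  names(mp) <- phase_levels()
  k <- which.max(mp)   # first maximum = canonical order on ties
  structure(list(mean_probs = mp, predicted = phase_levels()[k],
                 confidence = unname(mp[k])), class = "volume_score")
}

#' Bijective exam-level phase assignment by iterative greedy matching
#'
#' Repeatedly selects the globally highest mean-probability entry among all
#' (volume, phase) pairings whose volume and phase are both still
#' unassigned, assigns that pair, and repeats until every volume has a
#' phase; the final remaining pair is forced. Exact ties are broken by
#' canonical phase order, then by volume input order. The result is a
#' bijection: no two volumes share a phase, and with four volumes all four
#' phases are used. With fewer volumes (partial exams) only the winning
#' phases are assigned.
#'
#' A useful emergent property: when two volumes' argmax predictions collide,
#' the colliding phase goes to the volume with the higher score and the
#' other volume falls through to its best still-available option.
#'
#' @param mean_probs matrix with one row per volume (at most 4) and 4
#'   columns in canonical phase order; row names identify volumes
#'   (defaults `V1..Vn`).
#' @return Named character vector mapping volume id to phase name.
#' @export
#' @examples
#' m <- rbind(c(.9, .05, .03, .02), c(.8, .1, .05, .05),
#'            c(.1, .7, .1, .1), c(.05, .05, .5, .4))
#' assign_exam_phases(m)
assign_exam_phases <- function(mean_probs) {
  m <- as.matrix(mean_probs)
  if (nrow(m) > 4L)
    stop_ctphase("an exam has at most 4 volumes", "ctphase_protocol_error")
  if (ncol(m) != 4L || any(!is.finite(m)))
    stop_ctphase("mean_probs must be a complete (volumes x 4) matrix",
                 "ctphase_input_error")
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  vol_free <- rep(TRUE, nrow(m))
  ph_free <- rep(TRUE, 4L)
  out <- setNames(rep(NA_character_, nrow(m)), rownames(m))
  while (any(vol_free)) {
    sub <- m[vol_free, ph_free, drop = FALSE]
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    # ties: lowest phase index (canonical order), then lowest volume index
    hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
    v <- which(vol_free)[hit[1, 1]]
    p <- which(ph_free)[hit[1, 2]]
    out[v] <- phase_levels()[p]
    vol_free[v] <- FALSE
    ph_free[p] <- FALSE
  }
  out
}

#' Run the full pipeline over labeled exams
#'
#' Convenience evaluator used by cross-validation and end-to-end tests:
#' predicts every slice, aggregates to volume argmax predictions, and
#' reconciles each exam with [assign_exam_phases()].
#'
#' @param net a `ctphase_model`.
#' @param exams list of `exam_study` objects whose volumes carry
#'   `true_phase` labels.
#' @param max_slices slice cap per volume.
#' @return List of three levels: `slice` (`true`, `predicted` factors and
#'   `probs` matrix), `volume` (`true`, `predicted`, `mean_probs`,
#'   `exam_id`, `series_uid`), `exam` (`assignments`, `truths`: named lists
#'   of volume-to-phase maps keyed by exam id).
#' @export
evaluate_exams <- function(net, exams, max_slices = 150L) {
  sl_true <- character(0); sl_probs <- NULL
  vol_true <- character(0); vol_pred <- character(0)
  vol_mp <- NULL; vol_eid <- character(0); vol_uid <- character(0)
  assignments <- list(); truths <- list()
  for (exam in exams) {
    mp <- matrix(NA_real_, length(exam$volumes), 4L)
    rownames(mp) <- vapply(exam$volumes, `[[`, character(1), "series_uid")
    truth <- setNames(character(length(exam$volumes)), rownames(mp))
    for (j in seq_along(exam$volumes)) {
      vol <- exam$volumes[[j]]
      sc <- predict_slices(net, vol, max_slices)
      vs <- predict_volume(sc)
      mp[j, ] <- vs$mean_probs
      sl_true <- c(sl_true, rep(vol$true_phase, nrow(sc)))
      sl_probs <- rbind(sl_probs, sc)
      vol_true <- c(vol_true, vol$true_phase)
      vol_pred <- c(vol_pred, vs$predicted)
      vol_eid <- c(vol_eid, exam$exam_id)
      vol_uid <- c(vol_uid, vol$series_uid)
      truth[j] <- vol$true_phase
    }
    vol_mp <- rbind(vol_mp, mp)
    assignments[[exam$exam_id]] <- assign_exam_phases(mp)
    truths[[exam$exam_id]] <- truth
  }
  list(
    slice = list(true = phase_factor(sl_true),
                 predicted = phase_factor(
                   phase_levels()[max.col(sl_probs, ties.method = "first")]),
                 probs = sl_probs),
    volume = list(true = phase_factor(vol_true),
                  predicted = phase_factor(vol_pred),
                  mean_probs = vol_mp, exam_id = vol_eid,
                  series_uid = vol_uid),
    exam = list(assignments = assignments, truths = truths))
}

#' Sort an unsorted DICOM study into per-phase folders
#'
#' Loads the study, predicts every volume's phase with the model, assigns
#' phases bijectively across the exam, and copies each series' original
#' DICOM files into `out_dir/<phase>/`. SeriesDescription is carried into
#' the report but is never consulted for the decision.
#'
#' @param study_dir directory with the study's DICOM files.
#' @param net a `ctphase_model` (or a directory for [load_model()]).
#' @param out_dir output directory; one subfolder per assigned phase.
#' @param report_path optional path for a JSON report with per-volume mean
#'   probabilities, the assignment and per-slice scores.
#' @param max_slices slice cap per volume.
#' @return Invisibly, the report list.
#' @export
sort_study <- function(study_dir, net, out_dir, report_path = NULL,
                       max_slices = 150L) {
  if (is.character(net)) net <- load_model(net)
  exam <- load_study(study_dir)
  mp <- matrix(NA_real_, length(exam$volumes), 4L)
  rownames(mp) <- vapply(exam$volumes, `[[`, character(1), "series_uid")
  slice_scores <- list()
  for (j in seq_along(exam$volumes)) {
    sc <- predict_slices(net, exam$volumes[[j]], max_slices)
    mp[j, ] <- predict_volume(sc)$mean_probs
    slice_scores[[rownames(mp)[j]]] <- sc
  }
  assignment <- assign_exam_phases(mp)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(exam$volumes)) {
    vol <- exam$volumes[[j]]
    phase_dir <- file.path(out_dir, assignment[[vol$series_uid]])
    dir.create(phase_dir, showWarnings = FALSE)
    file.copy(vol$source_paths, phase_dir)
  }
  colnames(mp) <- phase_levels()
  report <- list(
    exam_id = exam$exam_id,
    volumes = lapply(seq_along(exam$volumes), function(j) list(
      series_uid = exam$volumes[[j]]$series_uid,
      series_description = exam$volumes[[j]]$series_description,
      n_slices = dim(exam$volumes[[j]]$pixels)[3],
      mean_probs = as.list(mp[j, ]),
      assigned_phase = unname(assignment[[exam$volumes[[j]]$series_uid]]))),
    assignment = as.list(assignment),
    slice_scores = lapply(slice_scores, function(s) unname(asplit(s, 1))))
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
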