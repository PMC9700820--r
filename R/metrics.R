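#' Confusion matrix and one-vs-rest counts
#'
#' @param true_labels,predicted_labels equal-length vectors of phase names
#'   (or factors with canonical levels).
#' @return A `ctphase_confusion` list: `matrix` (4x4, rows = true, columns
#'   = predicted), `counts` (data.frame with per-class TP, FP, TN, FN),
#'   `n` total observations.
#' @export
confusion <- function(true_labels, predicted_labels) {
  t_f <- phase_factor(true_labels)
  p_f <- phase_factor(predicted_labels)
  if (length(t_f) != length(p_f))
    stop_ctphase("label vectors must have equal length",
                 "ctphase_dimension_error")
  m <- table(true = t_f, predicted = p_f)
  m <- matrix(as.integer(m), 4L, 4L,
              dimnames = list(true = phase_levels(),
                              predicted = phase_levels()))
  n <- length(t_f)
  counts <- data.frame(class = phase_levels(),
                       tp = diag(m),
                       fp = colSums(m) - diag(m),
                       fn = rowSums(m) - diag(m))
  counts$tn <- n - counts$tp - counts$fp - counts$fn
  rownames(counts) <- NULL
  structure(list(matrix = m, counts = counts, n = n),
            class = "ctphase_confusion")
}

#' One-vs-rest classification metrics from confusion counts
#'
#' Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (their
#' harmonic mean), one-vs-rest accuracy `(TP+TN)/total`. Undefined 0/0
#' ratios return 0 and set the `undefined` flag. Also reports overall
#' accuracy (fraction of observations classified correctly) and unweighted
#' macro means.
#'
#' @param conf a `ctphase_confusion` from [confusion()].
#' @return List: `per_class` data.frame, `overall_accuracy`, `macro`
#'   (named vector of macro precision/recall/f1).
#' @export
classification_metrics <- function(conf) {
  if (!inherits(conf, "ctphase_confusion"))
    stop_ctphase("conf must come from confusion()", "ctphase_input_error")
  cc <- conf$counts
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(cc$tp, cc$tp + cc$fp)
  recall <- safe_div(cc$tp, cc$tp + cc$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(
    class = cc$class, precision = precision, recall = recall, f1 = f1,
    accuracy = (cc$tp + cc$tn) / conf$n,
    n = cc$tp + cc$fn,
    undefined = (cc$tp + cc$fp == 0) | (cc$tp + cc$fn == 0))
  if (any(per_class$undefined))
    warning("some per-class metrics are 0/0; reported as 0 and flagged",
            call. = FALSE)
  list(per_class = per_class,
       overall_accuracy = sum(cc$tp) / conf$n,
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

# AUC of scores for a binary membership vector, by trapezoidal integration
# of the ROC curve over unique score thresholds (equivalent to the
# midrank-tie-corrected Mann-Whitney statistic).
binary_auc <- function(is_pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- is_pos[ord]; s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)     # last index of each tied score group
  tps <- cumsum(y)[keep]
  fps <- cumsum(!y)[keep]
  tpr <- c(0, tps / sum(is_pos))
  fpr <- c(0, fps / sum(!is_pos))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' One-vs-rest ROC AUC per phase
#'
#' For each phase, the AUC of that phase's score column for the
#' phase-vs-rest problem (ROC = true positive rate against false positive
#' rate over all thresholds; ties handled by midrank). Classes absent from
#' the truth (or covering it entirely) get `NA` and are excluded from the
#' macro mean with a warning.
#'
#' @param true_labels vector of phase names.
#' @param score_vectors `n x 4` matrix of scores, columns in canonical
#'   phase order.
#' @return List: `per_class` named numeric vector of AUCs, `macro` mean
#'   over defined classes.
#' @export
roc_auc_ovr <- function(true_labels, score_vectors) {
  t_f <- phase_factor(true_labels)
  s <- as.matrix(score_vectors)
  if (nrow(s) != length(t_f) || ncol(s) != 4L)
    stop_ctphase("score_vectors must be n x 4 with n = length(true_labels)",
                 "ctphase_dimension_error")
  auc <- setNames(rep(NA_real_, 4L), phase_levels())
  for (k in seq_len(4L)) {
    pos <- t_f == phase_levels()[k]
    if (any(pos) && any(!pos)) auc[k] <- binary_auc(pos, s[, k])
  }
  if (anyNA(auc))
    warning("AUC undefined for class(es) absent from true labels: ",
            paste(names(auc)[is.na(auc)], collapse = ", "), call. = FALSE)
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Exam-level summary of phase assignments
#'
#' Counts, per exam, how many volume-to-phase pairs of the bijective
#' assignment match the truth (a 4-volume exam can score 0, 1, 2 or 4; a
#' score of 3 is impossible for a bijection). Reports the distribution of
#' correct counts, exam accuracy (fraction of exams with every volume
#' correct) and the mean fraction of correct phases per exam.
#'
#' @param assignments named list (keyed by exam id) of named
#'   volume-to-phase vectors as returned by [assign_exam_phases()].
#' @param truths named list with the same exam ids and volume names giving
#'   the true phases.
#' @return List: `histogram` (named counts over 0..4 correct),
#'   `exam_accuracy`, `mean_fraction_correct`, `n_exams`.
#' @export
exam_level_summary <- function(assignments, truths) {
  ids <- names(assignments)
  if (is.null(ids) || !setequal(ids, names(truths)))
    stop_ctphase("assignment and truth exam ids do not match",
                 "ctphase_join_error")
  correct <- integer(length(ids)); sizes <- integer(length(ids))
  for (i in seq_along(ids)) {
    a <- assignments[[ids[i]]]
    tr <- truths[[ids[i]]]
    if (!setequal(names(a), names(tr)))
      stop_ctphase(paste0("volume ids mismatch in exam ", ids[i]),
                   "ctphase_join_error")
    correct[i] <- sum(a[names(tr)] == tr)
    sizes[i] <- length(tr)
  }
  hist <- table(factor(correct, levels = 0:4))
  list(histogram = setNames(as.integer(hist), names(hist)),
       exam_accuracy = mean(correct == sizes),
       mean_fraction_correct = mean(correct / sizes),
       n_exams = length(ids))
}

report_metrics <- function(true_labels, predicted_labels, scores = NULL) {
  conf <- confusion(true_labels, predicted_labels)
  out <- classification_metrics(conf)
  out$confusion <- conf
  if (!is.null(scores)) {
    a <- roc_auc_ovr(true_labels, scores)
    out$per_class$auc <- unname(a$per_class[out$per_class$class])
    out$macro <- c(out$macro, auc = a$macro)
  }
  out$n <- conf$n
  out
}

#' Metrics report stratified by an exam attribute
#'
#' Recomputes the full metric suite within each stratum (e.g. scanner
#' manufacturer or disease status) alongside the global report. Missing
#' stratum values are grouped under `"unknown"`.
#'
#' @param true_labels,predicted_labels per-observation phase labels.
#' @param scores optional `n x 4` score matrix for AUC.
#' @param strata per-observation stratum values.
#' @return List: `global` report and `strata`, a named list of sub-reports.
#' @export
stratified_report <- function(true_labels, predicted_labels, scores = NULL,
                              strata = NULL) {
  global <- report_metrics(true_labels, predicted_labels, scores)
  subs <- list()
  if (!is.null(strata)) {
    strata <- as.character(strata)
    strata[is.na(strata) | !nzchar(strata)] <- "unknown"
    for (s in unique(strata)) {
      sel <- strata == s
      subs[[s]] <- report_metrics(
        true_labels[sel], predicted_labels[sel],
        if (!is.null(scores)) scores[sel, , drop = FALSE])
    }
  }
  list(global = global, strata = subs)
}
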