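random_labels <- function(n) sample(phase_levels(), n, replace = TRUE)

test_that("confusion counts match forced examples", {
  tl <- rep(phase_levels(), each = 10)
  cm <- confusion(tl, tl)
  expect_equal(diag(cm$matrix), setNames(rep(10L, 4), phase_levels()))
  expect_true(all(cm$counts$fp == 0) && all(cm$counts$fn == 0))
  # one observation: true unenhanced predicted portal
  cm1 <- confusion("unenhanced", "portal")
  cc <- cm1$counts
  expect_equal(cc$fn[cc$class == "unenhanced"], 1L)
  expect_equal(cc$fp[cc$class == "portal"], 1L)
  expect_equal(cc$tn[cc$class == "arterial"], 1L)
  expect_equal(cc$tn[cc$class == "delayed"], 1L)
  expect_error(confusion(c("portal", "bad"), c("portal", "portal")),
               class = "ctphase_label_error")
  expect_error(confusion(tl, tl[-1]), class = "ctphase_dimension_error")
})

test_that("confusion matches an independent brute-force tally", {
  set.seed(10)
  tl <- random_labels(2000); pl <- random_labels(2000)
  cm <- confusion(tl, pl)
  for (a in phase_levels()) for (b in phase_levels()) {
    tally <- sum(tl == a & pl == b)   # literal loop-free tally
    expect_identical(cm$matrix[a, b], as.integer(tally))
  }
  for (k in seq_len(4)) {
    cls <- phase_levels()[k]
    expect_equal(cm$counts$tp[k], sum(tl == cls & pl == cls))
    expect_equal(cm$counts$fp[k], sum(tl != cls & pl == cls))
    expect_equal(cm$counts$fn[k], sum(tl == cls & pl != cls))
    expect_equal(cm$counts$tn[k], sum(tl != cls & pl != cls))
    expect_equal(cm$counts$tp[k] + cm$counts$fp[k] + cm$counts$fn[k] +
                   cm$counts$tn[k], 2000L)
  }
  # accuracy identity: trace / total
  expect_equal(classification_metrics(cm)$overall_accuracy,
               sum(diag(cm$matrix)) / 2000)
})

test_that("classification metrics match their closed forms", {
  # TP=3 FP=1 TN=5 FN=1 -> P=R=F1=0.75, acc=0.8 (constructed labels)
  tl <- c(rep("arterial", 4), rep("portal", 6))
  pl <- c(rep("arterial", 3), "portal", rep("portal", 5), "arterial")
  # absent classes trip the (tested below) 0/0 warning; silence it here
  m <- suppressWarnings(classification_metrics(confusion(tl, pl)))
  row <- m$per_class[m$per_class$class == "arterial", ]
  expect_equal(row$precision, 0.75)
  expect_equal(row$recall, 0.75)
  expect_equal(row$f1, 0.75)
  expect_equal(row$accuracy, 0.8)
  # undefined 0/0 convention
  expect_warning(
    m0 <- classification_metrics(confusion(rep("portal", 3), rep("portal", 3))),
    "flagged")
  un <- m0$per_class[m0$per_class$class == "unenhanced", ]
  expect_equal(un$precision, 0)
  expect_true(un$undefined)
})

test_that("f1 equals 2PR/(P+R) on random confusions", {
  set.seed(11)
  for (i in 1:20) {
    m <- classification_metrics(confusion(random_labels(60), random_labels(60)))
    pc <- m$per_class
    ok <- pc$precision + pc$recall > 0
    expect_equal(pc$f1[ok], 2 * pc$precision[ok] * pc$recall[ok] /
                   (pc$precision[ok] + pc$recall[ok]))
  }
})

test_that("AUC: perfect separation gives 1, label-free scores give ~0.5", {
  tl <- rep(phase_levels(), each = 25)
  perfect <- ctphase:::onehot(as.integer(phase_factor(tl)))
  a <- roc_auc_ovr(tl, t(perfect))
  expect_equal(unname(a$per_class), rep(1, 4))
  set.seed(12)
  tl2 <- random_labels(4000)
  s <- matrix(runif(4000 * 4), ncol = 4)
  a2 <- roc_auc_ovr(tl2, s)
  expect_equal(unname(a2$per_class), rep(0.5, 4), tolerance = 0.05)
})

test_that("AUC equals the midrank Mann-Whitney statistic, with ties", {
  set.seed(13)
  tl <- random_labels(200)
  s <- round(matrix(runif(200 * 4), ncol = 4), 2)   # rounding forces ties
  a <- roc_auc_ovr(tl, s)
  for (k in seq_len(4)) {
    pos <- tl == phase_levels()[k]
    r <- rank(s[, k])                               # midranks
    u <- sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2
    expect_equal(unname(a$per_class[k]), u / (sum(pos) * sum(!pos)),
                 tolerance = 1e-12)
  }
})

test_that("AUC for a class absent from truth is NA and excluded", {
  tl <- rep(c("arterial", "portal"), 10)
  s <- matrix(runif(80), ncol = 4)
  expect_warning(a <- roc_auc_ovr(tl, s), "absent")
  expect_true(is.na(a$per_class[["unenhanced"]]))
  expect_false(is.na(a$macro))
})

test_that("exam summary: forced cases and bijection parity", {
  tr <- list(e1 = c(V1 = "unenhanced", V2 = "arterial",
                    V3 = "portal", V4 = "delayed"))
  perfect <- exam_level_summary(tr, tr)
  expect_equal(perfect$histogram, c(`0` = 0L, `1` = 0L, `2` = 0L,
                                    `3` = 0L, `4` = 1L))
  expect_equal(perfect$exam_accuracy, 1)
  # a single swap leaves exactly 2 correct
  swapped <- tr
  swapped$e1[c("V3", "V4")] <- c("delayed", "portal")
  one <- exam_level_summary(swapped, tr)
  expect_equal(one$histogram[["2"]], 1L)
  expect_equal(one$exam_accuracy, 0)
  expect_equal(one$mean_fraction_correct, 0.5)
  expect_error(exam_level_summary(swapped, list(e2 = tr$e1)),
               class = "ctphase_join_error")
})

test_that("correct-count distribution over all 24 permutations is exact", {
  truth <- setNames(phase_levels(), paste0("V", 1:4))
  perms <- ctphase:::permutations4()
  assignments <- lapply(seq_len(nrow(perms)), function(i)
    setNames(phase_levels()[perms[i, ]], paste0("V", 1:4)))
  names(assignments) <- paste0("e", seq_along(assignments))
  truths <- setNames(rep(list(truth), 24), names(assignments))
  s <- exam_level_summary(assignments, truths)
  expect_equal(s$histogram, c(`0` = 9L, `1` = 8L, `2` = 6L, `3` = 0L,
                              `4` = 1L))
  expect_equal(s$exam_accuracy, 1 / 24)
})

test_that("stratified report partitions counts and reduces to global", {
  set.seed(14)
  tl <- random_labels(120); pl <- random_labels(120)
  strata <- sample(c("Philips", "Siemens Health", NA), 120, replace = TRUE)
  rep_all <- stratified_report(tl, pl, strata = strata)
  expect_named(rep_all$strata,
               c(unique(strata[!is.na(strata)]), "unknown"),
               ignore.order = TRUE)
  ns <- vapply(rep_all$strata, `[[`, numeric(1), "n")
  expect_equal(sum(ns), 120)
  tot <- Reduce(`+`, lapply(rep_all$strata, function(r) r$confusion$matrix))
  expect_equal(tot, rep_all$global$confusion$matrix)
  single <- stratified_report(tl, pl, strata = rep("x", 120))
  expect_equal(single$strata$x$per_class, single$global$per_class)
})
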