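test_that("kinetics table respects the contrast timing invariants", {
  k <- kinetics_table()
  expect_setequal(k$structure, names(ctphase:::STRUCT_CODES))
  expect_true(all(k$unenhanced == 0))
  expect_gt(k["aorta", "arterial"], k["aorta", "portal"])
  expect_gt(k["portal_vein", "portal"], k["portal_vein", "arterial"])
  expect_equal(which.max(as.numeric(k["collecting_system", phase_levels()])),
               match("delayed", phase_levels()))
})

test_that("generate_exam produces the configured shapes and labels", {
  cfg <- phantom_config(n_exams = 2L, slices_per_volume = 8L,
                        image_side = 64L, seed = 7L)
  exams <- generate_exams(cfg)
  expect_length(exams, 2L)
  for (ex in exams) {
    expect_length(ex$volumes, 4L)
    expect_setequal(vapply(ex$volumes, `[[`, character(1), "true_phase"),
                    phase_levels())
    for (v in ex$volumes) expect_equal(dim(v$pixels), c(64L, 64L, 8L))
    uids <- vapply(ex$volumes, `[[`, character(1), "series_uid")
    expect_length(unique(uids), 4L)
  }
  expect_error(generate_exam(cfg, 2L), class = "ctphase_config_error")
  expect_error(phantom_config(0), class = "ctphase_config_error")
  expect_error(phantom_config(1, image_side = 16), class = "ctphase_config_error")
})

test_that("same (seed, exam_index) reproduces bit-identical pixels", {
  cfg <- phantom_config(n_exams = 2L, slices_per_volume = 6L,
                        image_side = 64L, noise_sigma = 8, seed = 13L)
  a <- generate_exam(cfg, 1L)
  b <- generate_exam(cfg, 1L)
  expect_identical(a, b)
  expect_false(identical(a$volumes[[1]]$pixels,
                         generate_exam(cfg, 0L)$volumes[[1]]$pixels))
})

test_that("noise-free enhancement follows the kinetics deltas exactly", {
  ex <- noiseless_exam()
  k <- kinetics_table()
  for (st in c("aorta", "portal_vein", "liver", "collecting_system")) {
    for (ph in phase_levels()) {
      expected <- k[st, "baseline"] + k[st, ph]
      expect_equal(struct_mean(ex, vol_of_phase(ex, ph), st), expected,
                   tolerance = 1e-12, info = paste(st, ph))
    }
  }
  # arterial aorta strictly brighter than unenhanced aorta
  expect_gt(struct_mean(ex, vol_of_phase(ex, "arterial"), "aorta"),
            struct_mean(ex, vol_of_phase(ex, "unenhanced"), "aorta"))
})

test_that("anatomical placement invariants hold across seeds", {
  for (seed in 1:5) {
    ex <- generate_exam(phantom_config(1L, 8L, 64L, 0, seed = seed), 0L)
    map <- ex$structure_map
    cs <- ctphase:::STRUCT_CODES
    S <- dim(map)[3]
    caudal_from <- floor(S / 2) + 1
    # collecting system only in the caudal half of the slices
    for (z in seq_len(S)) {
      has_cs <- any(map[, , z] == cs[["collecting_system"]])
      expect_equal(has_cs, z >= caudal_from)
    }
    # aorta anterior to (lower row index than) the spine
    rows_of <- function(code) which(map[, , 1] == code, arr.ind = TRUE)[, 1]
    expect_lt(mean(rows_of(cs[["aorta"]])), mean(rows_of(cs[["bone"]])))
    # liver on the image left (patient right)
    cols_liver <- which(map[, , 1] == cs[["liver"]], arr.ind = TRUE)[, 2]
    expect_lt(mean(cols_liver), 32)
  }
})

test_that("separability: nearest-centroid rule is perfect at <= 10 HU noise", {
  cfg <- phantom_config(n_exams = 6L, slices_per_volume = 8L,
                        image_side = 64L, noise_sigma = 10, seed = 21L)
  for (ex in generate_exams(cfg)) {
    nc <- nearest_centroid_phase(ex)
    expect_equal(as.character(nc$predicted), as.character(nc$true))
  }
})

test_that("slow_excretion zeroes delayed collecting-system enhancement", {
  ex <- noiseless_exam()
  con <- apply_confounder(ex, "slow_excretion")
  k <- kinetics_table()
  j <- vol_of_phase(con, "delayed")
  expect_equal(struct_mean(con, j, "collecting_system"),
               k["collecting_system", "baseline"], tolerance = 1e-12)
  # labels unchanged
  expect_identical(vapply(con$volumes, `[[`, character(1), "true_phase"),
                   vapply(ex$volumes, `[[`, character(1), "true_phase"))
  # other volumes untouched
  u <- vol_of_phase(ex, "unenhanced")
  expect_identical(con$volumes[[u]]$pixels, ex$volumes[[u]]$pixels)
})

test_that("portal_thrombosis caps portal liver enhancement at 25% nominal", {
  ex <- noiseless_exam()
  con <- apply_confounder(ex, "portal_thrombosis")
  k <- kinetics_table()
  j <- vol_of_phase(con, "portal")
  expect_lte(struct_mean(con, j, "liver"),
             k["liver", "baseline"] + 0.25 * k["liver", "portal"] + 1e-9)
  expect_lte(struct_mean(con, j, "portal_vein"),
             k["portal_vein", "baseline"] +
               0.25 * k["portal_vein", "portal"] + 1e-9)
})

test_that("confounder mode none is the identity; unknown modes error", {
  ex <- noiseless_exam()
  expect_identical(apply_confounder(ex, "none"), ex)
  expect_error(apply_confounder(ex, "bogus"), class = "ctphase_config_error")
})

test_that("slow_excretion shrinks the centroid delayed-vs-portal margin", {
  ex <- noiseless_exam()
  margin <- function(e) {
    d <- nearest_centroid_phase(e)$dist
    j <- vol_of_phase(e, "delayed")
    d[j, "portal"] - d[j, "delayed"]
  }
  expect_lt(margin(apply_confounder(ex, "slow_excretion")), margin(ex))
})

test_that("confounder_fraction selects a reproducible subset of exams", {
  cfg <- phantom_config(n_exams = 12L, slices_per_volume = 6L,
                        image_side = 64L, noise_sigma = 8, seed = 5L,
                        confounder_mode = "slow_excretion",
                        confounder_fraction = 0.5)
  exams <- generate_exams(cfg)
  modes <- vapply(exams, `[[`, character(1), "confounder")
  expect_true(any(modes == "slow_excretion") && any(modes == "none"))
  # base pixels identical to the unconfounded world except confounded volumes
  cfg0 <- phantom_config(n_exams = 12L, slices_per_volume = 6L,
                         image_side = 64L, noise_sigma = 8, seed = 5L)
  base <- generate_exams(cfg0)
  for (i in seq_along(exams)) {
    u <- vol_of_phase(exams[[i]], "unenhanced")
    expect_identical(exams[[i]]$volumes[[u]]$pixels,
                     base[[i]]$volumes[[u]]$pixels)
  }
})

test_that("write_phantom_dataset emits the forced file counts and manifest", {
  cfg <- phantom_config(n_exams = 1L, slices_per_volume = 8L,
                        image_side = 64L, seed = 3L)
  td <- withr::local_tempdir()
  manifest <- write_phantom_dataset(cfg, td)
  files <- list.files(td, pattern = "\\.dcm$", recursive = TRUE)
  expect_length(files, 32L)
  series_dirs <- list.dirs(file.path(td, "EXAM_0000"), recursive = FALSE)
  expect_length(series_dirs, 4L)
  expect_equal(nrow(manifest), 4L)
  expect_setequal(manifest$true_phase, phase_levels())
  expect_true(file.exists(file.path(td, "manifest.json")))
  # series descriptions deliberately uninformative
  expect_true(all(grepl("^SERIES_\\d$", basename(manifest$series_dir))))
})
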