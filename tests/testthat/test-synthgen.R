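test_that("cohort spec validates its fields with named configuration errors", {
  expect_error(cohort_spec(abscopal_fraction = 1.3), "abscopal_fraction")
  expect_error(cohort_spec(abscopal_fraction = 0.01, n_treated = 10),
               "abscopal_fraction")
  expect_error(cohort_spec(voxel_spacing_ct = c(0.4, 0, 0.6)), "voxel_spacing")
  expect_error(cohort_spec(nlr_ratio = -1), "nlr_ratio")
  expect_error(cohort_spec(doubling_time_days = 0), "doubling_time_days")
})

test_that("arm sizes and the planted abscopal count follow the spec", {
  coh <- generate_cohort(cohort_spec(seed = 1), images = FALSE)
  arms <- vapply(coh, function(a) a$arm, "")
  expect_equal(sum(arms == "control"), 4L)
  expect_equal(sum(arms == "treated"), 15L)
  ab <- vapply(coh, function(a) isTRUE(a$abscopal), TRUE)
  expect_equal(sum(ab), 4L)  # round(0.27 * 15)
  expect_true(all(is.na(vapply(coh[arms == "control"], function(a) a$abscopal, TRUE))))

  coh0 <- generate_cohort(cohort_spec(n_treated = 0L, n_control = 4L,
                                      abscopal_fraction = 0), images = FALSE)
  expect_length(coh0, 4L)
  expect_true(all(vapply(coh0, function(a) a$arm, "") == "control"))
})

test_that("control growth doubles on schedule and labeling round-trips planted status", {
  spec <- cohort_spec(measurement_days = c(0, 7), growth_noise_sd = 0)
  g <- generate_growth("control", NA, spec, baseline_mm3 = c(200, 250))
  expect_equal(g$left$volume_mm3[2] / g$left$volume_mm3[1], 2, tolerance = 1e-9)
  expect_equal(g$right$volume_mm3[2] / g$right$volume_mm3[1], 2, tolerance = 1e-9)

  spec0 <- cohort_spec(growth_noise_sd = 0)
  for (q in 1:20) {
    ga <- generate_growth("treated", TRUE, spec0)
    gn <- generate_growth("treated", FALSE, spec0)
    expect_true(label_abscopal(ga$left, ga$right, tol = 0))
    expect_false(label_abscopal(gn$left, gn$right, tol = 0))
  }
})

test_that("label recovery under default measurement noise stays above 95%", {
  spec <- cohort_spec(seed = 2)
  set.seed(97)
  hits <- 0L
  n <- 200L
  for (q in seq_len(n)) {
    absc <- q %% 4 == 0  # 25% abscopal mix
    g <- generate_growth("treated", absc, spec)
    hits <- hits + (label_abscopal(g$left, g$right) == absc)
  }
  expect_gte(hits / n, 0.95)
})

test_that("generation is deterministic for a fixed seed", {
  spec <- cohort_spec(seed = 7)
  c1 <- generate_cohort(spec, images = FALSE)
  c2 <- generate_cohort(spec, images = FALSE)
  expect_identical(c1, c2)
  t1 <- simulate_feature_table(spec)
  t2 <- simulate_feature_table(spec)
  expect_identical(t1, t2)
})

test_that("mask volumes agree with the analytic ellipsoid volume within 15%", {
  coh <- get_image_cohort()
  for (a in coh[c(1, 6, 12)]) {
    for (key in c("ct_left", "mri_right")) {
      tu <- a$tumors[[key]]
      v_mask <- sum(tu$roi$mask) * prod(tu$volume$spacing)
      v_true <- a$growth[[sub("^(ct|mri)_", "", key)]]$volume_mm3[1]
      expect_lt(abs(v_mask - v_true) / v_true, 0.15)
    }
  }
})

test_that("written cohorts round-trip through the manifest", {
  dir_ <- withr::local_tempdir()
  spec <- cohort_spec(n_control = 0L, n_treated = 2L, abscopal_fraction = 0.5,
                      seed = 5)
  coh <- generate_cohort(spec)
  man <- write_cohort(coh, dir_)
  expect_true(file.exists(man))
  # 2 modalities x 2 flanks x 2 animals volumes + as many masks + 2 tables
  expect_length(list.files(dir_, pattern = "\\.nii\\.gz$"), 16L)
  mj <- jsonlite::read_json(man)
  for (e in mj$animals) for (f in e$files) {
    expect_true(file.exists(file.path(dir_, f$volume)))
    expect_true(file.exists(file.path(dir_, f$mask)))
  }
  back <- read_cohort(man)
  expect_length(back, 2L)
  for (q in 1:2) {
    expect_identical(back[[q]]$animal_id, coh[[q]]$animal_id)
    expect_identical(back[[q]]$abscopal, coh[[q]]$abscopal)
    for (key in names(coh[[q]]$tumors)) {
      expect_identical(back[[q]]$tumors[[key]]$roi$mask,
                       coh[[q]]$tumors[[key]]$roi$mask)
      expect_equal(back[[q]]$tumors[[key]]$volume$values,
                   coh[[q]]$tumors[[key]]$volume$values, tolerance = 1e-5)
    }
    expect_equal(back[[q]]$growth$left$volume_mm3,
                 coh[[q]]$growth$left$volume_mm3, tolerance = 1e-6)
  }
  # fixed seed => byte-identical manifests
  dir2 <- withr::local_tempdir()
  write_cohort(generate_cohort(spec), dir2)
  expect_identical(readLines(file.path(dir2, "manifest.json")), readLines(man))
})

test_that("null generator yields uniform screen p-values for the planted features", {
  # all effects zeroed; ANOVA on one tumor per animal so rows are independent
  es0 <- setNames(rep(0, 5), names(default_effect_sizes()))
  spec0 <- cohort_spec(effect_sizes = es0, nlr_ratio = 1, n_treated = 12L,
                       abscopal_fraction = 0.33)
  pv <- c()
  for (q in 1:200) {
    recs <- simulate_feature_table(spec0, seed = 4000 + q)
    lab <- vapply(recs, function(a) a$label, TRUE)
    for (nm in names(es0)) {
      pref <- sub("_.*", "", nm); feat <- sub("^(ct|mri)_", "", nm)
      x <- vapply(recs, function(a) a$features[[paste0(pref, "_left")]][[feat]], 0)
      pv <- c(pv, stats::oneway.test(x ~ lab, var.equal = TRUE)$p.value)
    }
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
  expect_equal(mean(pv), 0.5, tolerance = 0.05)
})

test_that("planted effect directions are recovered from the group feature model", {
  # >= 50 cohorts; sign test on abscopal-minus-non-abscopal group mean
  # differences for the five planted features and NLR
  spec <- cohort_spec()
  diffs <- matrix(NA_real_, 50, 6)
  for (q in 1:50) {
    recs <- simulate_feature_table(spec, seed = 600 + q)
    lab <- vapply(recs, function(a) a$label, TRUE)
    feat_mean <- function(nm) {
      pref <- sub("_.*", "", nm); feat <- sub("^(ct|mri)_", "", nm)
      vapply(recs, function(a)
        mean(c(a$features[[paste0(pref, "_left")]][[feat]],
               a$features[[paste0(pref, "_right")]][[feat]])), 0)
    }
    for (j in seq_along(names(default_effect_sizes()))) {
      v <- feat_mean(names(default_effect_sizes())[j])
      diffs[q, j] <- mean(v[lab]) - mean(v[!lab])
    }
    nl <- vapply(recs, function(a) nlr(a$cbc), 0)
    diffs[q, 6] <- mean(nl[lab]) - mean(nl[!lab])
  }
  expected_sign <- c(sign(default_effect_sizes()), -1)
  for (j in 1:6) {
    n_ok <- sum(sign(diffs[, j]) == expected_sign[j])
    # one-sided sign test at p < 0.01
    expect_lt(stats::binom.test(n_ok, 50, 0.5, alternative = "greater")$p.value,
              0.01)
  }
})

test_that("image synthesis carries the planted directions into extracted features", {
  coh <- get_image_cohort()
  recs <- get_image_features()
  treated <- which(vapply(coh, function(a) a$arm == "treated", TRUE))
  ab <- vapply(coh[treated], function(a) isTRUE(a$abscopal), TRUE)
  gm <- function(key, f) vapply(treated, function(i)
    mean(c(recs[[i]]$features[[paste0(key, "_left")]][[f]],
           recs[[i]]$features[[paste0(key, "_right")]][[f]])), 0)
  expect_gt(mean(gm("ct", "surface_to_mass_ratio")[ab]),
            mean(gm("ct", "surface_to_mass_ratio")[!ab]))
  expect_lt(mean(gm("ct", "kurtosis_2d")[ab]), mean(gm("ct", "kurtosis_2d")[!ab]))
  expect_lt(mean(gm("ct", "average_gray")[ab]), mean(gm("ct", "average_gray")[!ab]))
  expect_gt(mean(gm("mri", "kurtosis_2d")[ab]), mean(gm("mri", "kurtosis_2d")[!ab]))
  expect_lt(mean(gm("mri", "imc1_3d")[ab]), mean(gm("mri", "imc1_3d")[!ab]))
})

test_that("the end-to-end pipeline is reproducible and writes its artifacts", {
  dir_ <- withr::local_tempdir()
  spec <- cohort_spec(n_control = 0L, n_treated = 8L, abscopal_fraction = 0.27,
                      seed = 9)
  r1 <- suppressWarnings(run_pipeline("synthetic", spec = spec, n_train = 4L,
                                      out_dir = dir_))
  r2 <- suppressWarnings(run_pipeline("synthetic", spec = spec, n_train = 4L))
  expect_equal(summary(r1$fit), summary(r2$fit))
  expect_true(file.exists(file.path(dir_, "analysis_table.csv")))
  expect_true(file.exists(file.path(dir_, "model_report.csv")))
  expect_true(file.exists(file.path(dir_, "screen_ct.csv")))
  expect_true(file.exists(file.path(dir_, "provenance.json")))
  expect_error(run_pipeline("from-files", path = file.path(dir_, "nope.json")),
               "not found")
})

test_that("a pre-assembled feature table file round-trips through the S1 reader", {
  dir_ <- withr::local_tempdir()
  recs <- simulate_feature_table(cohort_spec(seed = 13))
  tab <- build_analysis_table(recs, n_train = 6, seed = 13)
  f <- file.path(dir_, "model_data.csv")
  utils::write.csv(tab[, c("animal_id", "abscopal", "split", "nlr",
                           paste0("ct_", c("surface_to_mass_ratio",
                                           "kurtosis_2d", "average_gray")),
                           paste0("mri_", c("kurtosis_2d", "imc1_3d")))],
                   f, row.names = FALSE)
  got <- read_s1_table(f)
  expect_s3_class(got, "analysis_table")
  expect_equal(nrow(got), 30L)
  fit <- suppressWarnings(abscopal_model(got))
  sm <- summary(fit)
  expect_true(all(sm$auc >= 0 & sm$auc <= 1))
  expect_error(read_s1_table(f, mapping = list(abscopal = "missing_col")),
               "not found")
})
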