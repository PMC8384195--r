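test_that("AUC equals exhaustive pair counting and handles the degenerate cases", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(20)
  for (q in 1:20) {
    n <- sample(6:25, 1)
    sc <- sample(stats::rnorm(8), n, replace = TRUE)  # force ties sometimes
    la <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(la)) < 2) next
    expect_identical(roc_auc(sc, la)$auc, oracle_auc(sc, la))
  }
})

test_that("AUC is invariant to monotone score transforms and flips with labels", {
  set.seed(21)
  sc <- stats::rnorm(30)
  la <- stats::rbinom(30, 1, stats::plogis(sc)) == 1
  r <- roc_auc(sc, la)
  expect_equal(roc_auc(exp(3 * sc) + 5, la)$auc, r$auc)
  expect_equal(roc_auc(sc, !la)$auc, 1 - r$auc)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
})

test_that("Hanley-McNeil interval is untruncated and shrinks with sample size", {
  set.seed(22)
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    sc <- c(stats::rnorm(n, 1), stats::rnorm(n))
    la <- rep(c(TRUE, FALSE), each = n)
    r <- roc_auc(sc, la)
    r$ci_high - r$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
  # perfect separation at small n: the upper bound exceeds 1 by construction
  r <- roc_auc(c(5, 6, 7, -1, -2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$ci_low, 1); expect_equal(r$ci_high, 1)
  r2 <- roc_auc(c(5, 6, 0.5, 1, -2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_lt(r2$auc, 1)
  expect_gt(r2$ci_high, 1)  # not clipped to [0, 1]
})

test_that("AUC and curve agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- stats::rnorm(40)
  la <- stats::rbinom(40, 1, stats::plogis(1.5 * sc)) == 1
  ours <- roc_auc(sc, la)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(la, sc, direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("separable training data is flagged and scores stay well ordered", {
  rows <- data.frame(x = c(1, 2, 3, 10, 11, 12),
                     abscopal = rep(c(FALSE, TRUE), each = 3))
  m <- fit_logistic(rows, "x")
  expect_true(m$separation)
  expect_equal(roc_auc(predict(m, rows), rows$abscopal)$auc, 1)
})

test_that("a pure-noise predictor yields chance-level AUC on a large sample", {
  set.seed(24)
  rows <- data.frame(x = stats::rnorm(2000),
                     abscopal = rep(c(TRUE, FALSE), 1000))
  m <- fit_logistic(rows, "x")
  expect_equal(roc_auc(predict(m, rows), rows$abscopal)$auc, 0.5, tolerance = 0.05)
})

test_that("coefficients of a generative logistic model are recovered", {
  set.seed(25)
  n <- 5000
  X <- matrix(stats::rnorm(2 * n), n, 2)
  beta <- c(-0.4, 0.9, -1.3)
  y <- stats::rbinom(n, 1, stats::plogis(beta[1] + X %*% beta[-1])) == 1
  rows <- data.frame(x1 = X[, 1], x2 = X[, 2], abscopal = y)
  m <- fit_logistic(rows, c("x1", "x2"))
  # back-transform standardized coefficients to the raw scale
  raw <- m$coefficients[-1] / m$scale
  expect_equal(unname(raw), beta[-1], tolerance = 0.1)
})

test_that("with vanishing ridge the fit matches the unpenalized MLE from glm", {
  set.seed(26)
  n <- 400
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * x)) == 1
  rows <- data.frame(x = x, abscopal = y)
  m <- fit_logistic(rows, "x", lambda = 1e-10)
  ref <- stats::glm(y ~ scale(x), family = stats::binomial())
  expect_equal(unname(m$coefficients),
               unname(stats::coef(ref)), tolerance = 1e-4)
  expect_error(fit_logistic(rows[y, ], "x"), "both classes")
})

test_that("evaluate_models fits the three models and reports both splits", {
  recs <- simulate_feature_table(cohort_spec(seed = 30))
  tab <- build_analysis_table(recs, n_train = 6, seed = 30)
  pan <- c("ct_surface_to_mass_ratio", "ct_average_gray")
  rep_ <- evaluate_models(tab, pan)
  expect_named(rep_$models, c("nlr_only", "radiomics", "combined"))
  expect_named(rep_$roc$combined, c("train", "validation"))
  expect_true(all(vapply(rep_$roc, function(r) r$train$auc, 0) >= 0))
  expect_warning(rep0 <- evaluate_models(tab, character(0)), "empty radiomics panel")
  expect_false("radiomics" %in% names(rep0$models))
})

test_that("the fitted abscopal model exposes the standard S3 surface", {
  recs <- simulate_feature_table(cohort_spec(seed = 31))
  tab <- build_analysis_table(recs, n_train = 6, seed = 31)
  fit <- suppressWarnings(abscopal_model(tab))
  expect_s3_class(fit, "abscopal_model")
  sm <- summary(fit)
  expect_true(all(c("modality", "model", "split", "auc", "ci_low", "ci_high")
                  %in% names(sm)))
  pr <- predict(fit, modality = "ct")
  expect_length(pr, sum(tab$split == "validation"))
  expect_true(all(pr > 0 & pr < 1))
  expect_type(coef(fit, modality = "ct"), "double")
  expect_output(print(fit), "Abscopal-effect model")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf)); unlink(tf)
})
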