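test_that("extraction returns exactly the 92 named features in stable order", {
  st <- small_textured_roi()
  fv <- extract_features(st$volume, st$roi)
  expect_length(fv, 92L)
  expect_identical(names(fv), radiomics_feature_names())
  expect_true(all(is.finite(fv)))
  # deterministic: repeated extraction identical
  expect_identical(as.numeric(fv), as.numeric(extract_features(st$volume, st$roi)))
})

test_that("constant-intensity ROI yields the analytic first-order limits", {
  m <- make_sphere_mask(13, 5)
  vol <- image_volume(array(42, c(13, 13, 13)), c(1, 1, 1), "CT")
  roi <- tumor_roi(m, "a", "left", "CT")
  fv <- extract_features(vol, roi)
  expect_equal(unname(fv["average_gray"]), 42)
  expect_equal(unname(fv["fo_hist_entropy"]), 0)
  expect_equal(unname(fv["fo_hist_uniformity"]), 1)
  expect_true("kurtosis_2d" %in% attr(fv, "flags"))
  expect_error(histogram_kurtosis(vol, roi), "variance")
})

test_that("histogram kurtosis matches closed forms and large-sample limits", {
  d <- c(50, 50, 40)
  rr <- tumor_roi(array(TRUE, d), "a", "left", "CT")
  mk <- function(v) image_volume(array(v, d), c(1, 1, 1), "CT")
  set.seed(2)
  expect_equal(histogram_kurtosis(mk(stats::rnorm(prod(d))), rr), 3, tolerance = 0.2)
  expect_equal(histogram_kurtosis(mk(stats::runif(prod(d))), rr), 9 / 5, tolerance = 0.05)
  expect_equal(histogram_kurtosis(mk(rep(c(0, 1), prod(d) / 2)), rr), 1)
})

test_that("average gray equals the brute-force mean", {
  expect_equal(unname(average_gray(
    image_volume(array(c(0, 10, rep(5, 66)), c(4, 17, 1)), c(1, 1, 1), "CT"),
    structure(list(mask = array(c(TRUE, TRUE, rep(FALSE, 66)), c(4, 17, 1))),
              class = "tumor_roi"))), 5)
  st <- small_textured_roi(7)
  expect_equal(unname(average_gray(st$volume, st$roi)),
               mean(st$volume$values[st$roi$mask]))
})

test_that("surface-to-mass ratio: cube closed form, scaling law, isoperimetry", {
  # 8 mm uniform 0-HU cube at 1 mm voxels: 384 mm^2 / 512 mg
  m <- make_cube_mask(12, 3, 10)
  vol <- image_volume(array(0, c(12, 12, 12)), c(1, 1, 1), "CT")
  roi <- tumor_roi(m, "a", "left", "CT")
  expect_equal(surface_to_mass_ratio(vol, roi, method = "voxel_face"), 0.75)

  # doubling linear size halves the ratio (ellipsoid phantoms, 5%)
  mk_ell <- function(s) {
    dd <- as.integer(round(3 * s) * 2 + 9); cc <- (dd + 1) / 2
    co <- expand.grid(x = 1:dd, y = 1:dd, z = 1:dd)
    m <- array(((co$x - cc) / s)^2 + ((co$y - cc) / (1.3 * s))^2 +
                 ((co$z - cc) / (0.8 * s))^2 <= 1, c(dd, dd, dd))
    list(roi = tumor_roi(m, "a", "left", "CT"),
         vol = image_volume(array(0, c(dd, dd, dd)), c(1, 1, 1), "CT"))
  }
  e1 <- mk_ell(10); e2 <- mk_ell(20)
  r1 <- surface_to_mass_ratio(e1$vol, e1$roi)
  r2 <- surface_to_mass_ratio(e2$vol, e2$roi)
  expect_equal(r2 / r1, 0.5, tolerance = 0.05)

  # sphere beats an equal-mass spiculated shape
  sm <- make_sphere_mask(25, 9)
  sp_roi <- tumor_roi(sm, "a", "left", "CT")
  set.seed(3)
  co <- expand.grid(x = 1:25, y = 1:25, z = 1:25)
  ang <- atan2(co$y - 13, co$x - 13)
  spik <- array(sqrt((co$x - 13)^2 + (co$y - 13)^2 + (co$z - 13)^2) <=
                  9 * (1 + 0.35 * sin(5 * ang) * cos(3 * (co$z - 13))), c(25, 25, 25))
  vol25 <- image_volume(array(0, c(25, 25, 25)), c(1, 1, 1), "CT")
  a_s <- surface_area(sp_roi, c(1, 1, 1)) / sum(sm)
  a_k <- surface_area(tumor_roi(spik, "a", "left", "CT"), c(1, 1, 1)) / sum(spik)
  expect_lt(a_s, a_k)  # per unit mass (uniform density), sphere is smaller
})

test_that("second-order statistics match the literal-summation oracle", {
  # closed forms
  G <- 5
  st <- second_order_features(cooc_matrix(diag(G) / G))
  expect_equal(unname(st["contrast"]), 0)
  expect_equal(unname(st["energy"]), 1 / G)
  expect_equal(unname(second_order_features(cooc_matrix(matrix(0.25, 2, 2)))["imc1"]), 0)

  # random matrices vs naive double loop
  set.seed(9)
  for (q in 1:5) {
    p <- matrix(stats::rexp(64), 8, 8); p <- (p + t(p)); p <- p / sum(p)
    got <- second_order_features(cooc_matrix(p))
    want <- oracle_glcm_stats(p)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("checkerboard contrast equals the brute-force pair-count value", {
  d <- 8L
  co <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  vals <- array(((co$x + co$y + co$z) %% 2) * 100, c(d, d, d))
  mask <- array(TRUE, c(d, d, d))
  vol <- image_volume(vals, c(1, 1, 1), "CT")
  roi <- tumor_roi(mask, "a", "left", "CT")
  cooc <- compute_cooc(vol, roi, levels = 4L, distance = 1L, directions = "3d")
  p_oracle <- oracle_glcm(vals, mask, 4L, oracle_dirs_3d, 1L)
  contrast_oracle <- sum(p_oracle * outer(1:4, 1:4, function(i, j) (i - j)^2))
  expect_equal(unname(second_order_features(cooc)["contrast"]), contrast_oracle,
               tolerance = 1e-10)
})

test_that("triplet IMC1 analytic limits and literal-summation equivalence hold", {
  G <- 6
  px <- stats::rexp(G); px <- px / sum(px)
  indep <- array(outer(outer(px, px), px), c(G, G, G))
  expect_equal(unname(imc1_3d(triplet_tensor(indep))), 0, tolerance = 1e-12)

  dep <- array(0, c(G, G, G))
  for (i in 1:G) dep[i, i, i] <- 1 / G
  expect_equal(unname(imc1_3d(triplet_tensor(dep))), -2, tolerance = 1e-12)

  set.seed(13)
  for (q in 1:5) {
    parr <- random_prob_tensor(5)
    got <- imc1_3d(triplet_tensor(parr))
    expect_equal(unname(got), oracle_triplet_imc1(parr), tolerance = 1e-10)
    expect_lte(unname(got), 1e-12)
  }
})

test_that("pair and triplet accumulation matches naive enumeration on a small textured ROI", {
  st <- small_textured_roi(21, d = 9L)
  vals <- st$volume$values; mask <- st$roi$mask
  cooc <- compute_cooc(st$volume, st$roi, levels = 6L)
  expect_equal(cooc$p, oracle_glcm(vals, mask, 6L, oracle_dirs_3d), tolerance = 1e-12)

  tt <- compute_triplet_tensor(st$volume, st$roi, levels = 4L, distance = 1L)
  want <- oracle_triplet(vals, mask, 4L, 1L)
  got <- array(0, c(4, 4, 4))
  idx <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    idx <- idx + 1
    got[i, j, k] <- tt$p[(i - 1) * 16 + (j - 1) * 4 + k]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("texture features are invariant to intensity shifts and 90-degree rotations", {
  st <- small_textured_roi(31, d = 11L)
  fv <- extract_features(st$volume, st$roi)
  tex_names <- grep("^(glcm|tjp|imc1_3d)", names(fv), value = TRUE)

  shifted <- image_volume(st$volume$values + 111, c(1, 1, 1), "CT")
  fv_s <- extract_features(shifted, st$roi)
  expect_equal(fv_s[tex_names], fv[tex_names], tolerance = 1e-10)

  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  vol_r <- image_volume(rot(st$volume$values), c(1, 1, 1), "CT")
  roi_r <- tumor_roi(rot(st$roi$mask), "t1", "left", "CT")
  fv_r <- extract_features(vol_r, roi_r)
  expect_equal(fv_r[tex_names], fv[tex_names], tolerance = 1e-8)
})

test_that("undersized ROIs are rejected", {
  vol <- image_volume(array(0, c(5, 5, 5)), c(1, 1, 1), "CT")
  expect_error(tumor_roi(array(c(rep(TRUE, 10), rep(FALSE, 115)), c(5, 5, 5))),
               "27")
})
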