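#' Radiomics extraction configuration
#'
#' @param n_bins first-order histogram bins (128 equally spaced bins covering
#'   the ROI gray-value range).
#' @param levels_2nd gray levels for co-occurrence matrices.
#' @param levels_3rd gray levels for the triplet tensor (kept at 16 so the
#'   G^3 tensor stays tractable).
#' @param distances_3rd voxel distances for the third-order family.
#' @param surface_method see [surface_area()].
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(n_bins = 128L, levels_2nd = 32L, levels_3rd = 16L,
                             distances_3rd = c(1L, 2L),
                             surface_method = c("marching", "voxel_face")) {
  surface_method <- match.arg(surface_method)
  stopifnot_scalar_pos(n_bins, "n_bins")
  structure(list(n_bins = as.integer(n_bins), levels_2nd = as.integer(levels_2nd),
                 levels_3rd = as.integer(levels_3rd),
                 distances_3rd = as.integer(distances_3rd),
                 surface_method = surface_method),
            class = "radiomics_config")
}

#' First-order intensity histogram (128 equally spaced bins)
#'
#' Bins span the ROI intensity range; a constant ROI collapses all mass into
#' the first bin and is flagged degenerate.
#'
#' @param vals numeric vector of ROI intensities.
#' @param n_bins number of bins.
#' @return A list with `bin_edges` (n_bins + 1), `counts`, `probabilities`,
#'   `mids`, and a `degenerate` flag.
#' @export
histogram128 <- function(vals, n_bins = 128L) {
  rng <- range(vals)
  if (diff(rng) == 0) {
    counts <- c(length(vals), rep(0L, n_bins - 1L))
    edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = n_bins + 1L)
    return(list(bin_edges = edges, counts = counts,
                probabilities = counts / sum(counts),
                mids = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                degenerate = TRUE))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(n_bins, 1L + floor((vals - rng[1]) / diff(rng) * n_bins))
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_edges = edges, counts = counts, probabilities = counts / sum(counts),
       mids = (edges[-1] + edges[-(n_bins + 1L)]) / 2, degenerate = FALSE)
}

#' Histogram kurtosis (Pearson, non-excess)
#'
#' The fourth central moment over the squared second central moment of the
#' binned intensity distribution (bin centers weighted by probabilities); a
#' normal distribution gives ~3, a symmetric two-point distribution gives 1.
#'
#' @param volume an [image_volume()].
#' @param roi a [tumor_roi()].
#' @param n_bins number of histogram bins.
#' @return Scalar kurtosis.
#' @export
histogram_kurtosis <- function(volume, roi, n_bins = 128L) {
  vals <- volume$values[roi$mask]
  h <- histogram128(vals, n_bins)
  if (h$degenerate) stop("zero intensity variance in ROI; kurtosis undefined",
                         call. = FALSE)
  binned_kurtosis(h)
}

binned_kurtosis <- function(h) {
  mu <- sum(h$probabilities * h$mids)
  mu2 <- sum(h$probabilities * (h$mids - mu)^2)
  if (mu2 == 0) return(NA_real_)
  sum(h$probabilities * (h$mids - mu)^4) / mu2^2
}

#' Mean ROI intensity
#'
#' @inheritParams histogram_kurtosis
#' @return Arithmetic mean of the voxel intensities inside the ROI.
#' @export
average_gray <- function(volume, roi) mean(volume$values[roi$mask])

first_order_features <- function(vals, n_bins = 128L) {
  h <- histogram128(vals, n_bins)
  n <- length(vals)
  mu <- mean(vals)
  va <- stats::var(vals) * (n - 1) / n  # population moments, no bias correction
  sdv <- sqrt(va)
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  skew <- if (sdv > 0) mean((vals - mu)^3) / sdv^3 else NA_real_
  kurt <- if (h$degenerate) NA_real_ else binned_kurtosis(h)
  c(average_gray = mu,
    fo_median = qs[3],
    fo_minimum = min(vals),
    fo_maximum = max(vals),
    fo_range = diff(range(vals)),
    fo_p10 = qs[1],
    fo_p90 = qs[5],
    fo_iqr = qs[4] - qs[2],
    fo_variance = va,
    fo_sd = sdv,
    fo_cv = if (mu != 0) sdv / abs(mu) else NA_real_,
    fo_mad_median = stats::median(abs(vals - qs[3])),
    fo_mean_abs_dev = mean(abs(vals - mu)),
    fo_rms = sqrt(mean(vals^2)),
    fo_energy = sum(vals^2),
    fo_skewness = skew,
    kurtosis_2d = kurt,
    fo_hist_entropy = shannon_entropy(h$probabilities),
    fo_hist_uniformity = sum(h$probabilities^2),
    fo_hist_mode = h$mids[which.max(h$counts)])
}

.second_order_stat_names <- c("energy", "contrast", "correlation", "variance",
  "homogeneity", "sum_average", "sum_variance", "sum_entropy", "entropy",
  "diff_variance", "diff_entropy", "imc1", "imc2", "max_prob", "cluster_shade",
  "cluster_prominence", "autocorrelation", "dissimilarity")

.third_order_stat_names <- c("energy", "entropy", "max_prob", "contrast",
  "dissimilarity", "homogeneity", "imc1", "imc2", "sum_average", "sum_entropy",
  "sum_variance", "autocorrelation")

third_order_name <- function(dist, stat) {
  if (dist == 1L && stat == "imc1") "imc1_3d" else sprintf("tjp_d%d_%s", dist, stat)
}

#' Names of the 92-feature radiomics catalogue
#'
#' 12 geometric, 20 first-order histogram, 36 second-order co-occurrence
#' (18 statistics for slice-wise 2D and for 3D direction sets), and 24
#' third-order triplet features (12 statistics at distances 1 and 2). The
#' order is stable across runs and releases.
#'
#' @param config a [radiomics_config()].
#' @return Character vector of length 92.
#' @export
radiomics_feature_names <- function(config = radiomics_config()) {
  geo <- c("geo_volume_mm3", "geo_surface_area_mm2", "geo_surface_to_volume",
           "surface_to_mass_ratio", "geo_sphericity", "geo_compactness",
           "geo_equiv_diameter_mm", "geo_extent_x_mm", "geo_extent_y_mm",
           "geo_extent_z_mm", "geo_elongation", "geo_flatness")
  fo <- c("average_gray", "fo_median", "fo_minimum", "fo_maximum", "fo_range",
          "fo_p10", "fo_p90", "fo_iqr", "fo_variance", "fo_sd", "fo_cv",
          "fo_mad_median", "fo_mean_abs_dev", "fo_rms", "fo_energy",
          "fo_skewness", "kurtosis_2d", "fo_hist_entropy", "fo_hist_uniformity",
          "fo_hist_mode")
  so <- c(paste0("glcm2d_", .second_order_stat_names),
          paste0("glcm3d_", .second_order_stat_names))
  to <- unlist(lapply(config$distances_3rd, function(d)
    vapply(.third_order_stat_names, function(s) third_order_name(d, s), "")))
  unname(c(geo, fo, so, to))
}

# Direction-pooled co-occurrence statistics: pair counts are accumulated over
# the whole symmetric direction set before normalization, then the statistics
# are computed once. Pooling keeps the estimates dense (per-direction joint
# histograms are badly undersampled at murine-tumor ROI sizes) and is
# invariant to axis-aligned 90-degree rotations.
cooc_stats_pooled <- function(level_arr, mask, G, dirs, dist) {
  cnt <- matrix(0, G, G)
  for (r in seq_len(nrow(dirs)))
    cnt <- cnt + cooc_counts_dir(level_arr, mask, G, dirs[r, ], dist)
  if (sum(cnt) == 0)
    return(stats::setNames(rep(NA_real_, 18L), .second_order_stat_names))
  second_order_features(cooc_matrix(cnt / sum(cnt)))
}

triplet_stats_pooled <- function(level_arr, mask, G, dist) {
  dirs <- directions_3d()
  cnt <- numeric(G^3)
  for (r in seq_len(nrow(dirs)))
    cnt <- cnt + triplet_counts_dir(level_arr, mask, G, dirs[r, ], dist)
  if (sum(cnt) == 0)
    return(stats::setNames(rep(NA_real_, 12L), .third_order_stat_names))
  triplet_stats(triplet_tensor(cnt / sum(cnt), levels = G, distance = dist))
}

#' Extract the 92-feature radiomics vector for one tumor
#'
#' Computes the full catalogue over the ROI: geometric features from the mask
#' (and CT density for mass), first-order statistics from the 128-bin
#' intensity histogram, 18 co-occurrence statistics for slice-wise 2D and 3D
#' direction sets (gray levels min-max quantized within the ROI), and 12
#' collinear-triplet statistics at distances 1 and 2. Features whose value is
#' undefined for a degenerate (e.g. constant-intensity) ROI are returned as
#' their analytic limit where one exists and otherwise flagged by name in the
#' `flags` attribute. MRI volumes are expected to be normalized (see
#' [normalize_mri()]) before extraction.
#'
#' @param volume an [image_volume()].
#' @param roi a [tumor_roi()] on the same grid (>= 27 voxels).
#' @param config a [radiomics_config()].
#' @return A named numeric vector of class `feature_vector` with exactly 92
#'   entries, plus attributes `modality`, `animal_id`, `flank`, `flags`.
#' @export
extract_features <- function(volume, roi, config = radiomics_config()) {
  if (!identical(dim(volume$values), dim(roi$mask)))
    stop("volume and ROI grids differ", call. = FALSE)
  n <- sum(roi$mask)
  if (n < 27L) stop("ROI below 27 voxels", call. = FALSE)
  vals <- volume$values[roi$mask]

  geo <- geometric_features(volume, roi, config$surface_method)
  fo <- first_order_features(vals, config$n_bins)

  lv2 <- quantize_levels(vals, config$levels_2nd)
  la2 <- array(NA_integer_, dim = dim(roi$mask)); la2[roi$mask] <- lv2
  so2d <- cooc_stats_pooled(la2, roi$mask, config$levels_2nd, directions_2d(), 1L)
  so3d <- cooc_stats_pooled(la2, roi$mask, config$levels_2nd, directions_3d(), 1L)
  names(so2d) <- paste0("glcm2d_", .second_order_stat_names)
  names(so3d) <- paste0("glcm3d_", .second_order_stat_names)

  lv3 <- quantize_levels(vals, config$levels_3rd)
  la3 <- array(NA_integer_, dim = dim(roi$mask)); la3[roi$mask] <- lv3
  to <- numeric(0)
  for (d in config$distances_3rd) {
    st <- triplet_stats_pooled(la3, roi$mask, config$levels_3rd, d)
    names(st) <- vapply(.third_order_stat_names, function(s) third_order_name(d, s), "")
    to <- c(to, st)
  }

  out <- c(geo, fo, so2d, so3d, to)
  want <- radiomics_feature_names(config)
  out <- out[want]
  names(out) <- want
  flags <- names(out)[!is.finite(out)]
  structure(out, class = "feature_vector", modality = volume$modality,
            animal_id = roi$animal_id, flank = roi$flank, flags = flags)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s  %d features  (%s, %s flank)\n",
              attr(x, "modality"), length(x),
              attr(x, "animal_id") %||% "?", attr(x, "flank") %||% "?"))
  if (length(attr(x, "flags")))
    cat("  flagged degenerate:", paste(attr(x, "flags"), collapse = ", "), "\n")
  invisible(x)
}
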