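#' Construct an image volume
#'
#' A 3D scalar grid with anisotropic voxel spacing and a modality tag, the
#' in-memory container for a CT (Hounsfield units) or T1 MRI (arbitrary
#' intensity) acquisition.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @param modality `"CT"` or `"MRI"`.
#' @param origin world coordinate of voxel (1,1,1), mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, modality = c("CT", "MRI"),
                         origin = c(0, 0, 0)) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_config("spacing", "must be three positive values (mm)")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 modality = modality, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Construct a tumor region of interest
#'
#' A binary segmentation mask congruent with an [image_volume()] grid, tied to
#' an animal and flank. A valid ROI has at least 27 voxels (the minimum for
#' 3x3x3 texture neighborhoods).
#'
#' @param mask logical 3D array, `TRUE` inside the tumor.
#' @param animal_id,flank identity of the tumor (`flank` is `"left"` or
#'   `"right"`; the right flank is the irradiated one).
#' @param modality `"CT"` or `"MRI"`.
#' @param min_voxels minimum voxel count accepted.
#' @return An object of class `tumor_roi`.
#' @export
tumor_roi <- function(mask, animal_id = NA_character_,
                      flank = c("left", "right"), modality = c("CT", "MRI"),
                      min_voxels = 27L) {
  flank <- match.arg(flank)
  modality <- match.arg(modality)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  n <- sum(mask)
  if (n == 0L) stop("empty ROI: mask has no voxels set", call. = FALSE)
  if (n < min_voxels)
    stop(sprintf("ROI has %d voxels; at least %d required for texture analysis",
                 n, min_voxels), call. = FALSE)
  structure(list(mask = mask, animal_id = animal_id, flank = flank,
                 modality = modality),
            class = "tumor_roi")
}

#' Read a NIfTI volume
#'
#' Voxel spacing is taken from the NIfTI header; modality is supplied by the
#' caller (NIfTI carries no modality tag).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality `"CT"` or `"MRI"`.
#' @return An [image_volume()].
#' @export
load_volume <- function(path, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(arr, spacing = spacing, modality = modality,
               origin = as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)))
}

#' Write a volume or mask as NIfTI
#'
#' @param volume an [image_volume()] or a `tumor_roi` (masks are written as
#'   uint8 0/1 on the same grid).
#' @param path output path (`.nii.gz`).
#' @param spacing spacing used when writing a bare mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "tumor_roi")) {
    arr <- array(as.integer(volume$mask), dim = dim(volume$mask))
    sp <- spacing %||% c(1, 1, 1)
    dtype <- "uint8"
  } else {
    arr <- volume$values
    sp <- volume$spacing
    dtype <- "auto"
  }
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a segmentation mask tied to a volume
#'
#' The mask grid must match the volume grid exactly; values are binarized at
#' 0.5. An all-zero mask is rejected.
#'
#' @param path NIfTI mask path.
#' @param volume the [image_volume()] the mask segments.
#' @inheritParams tumor_roi
#' @return A [tumor_roi()].
#' @export
load_mask <- function(path, volume, animal_id = NA_character_,
                      flank = c("left", "right")) {
  flank <- match.arg(flank)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)[1:3]
  dv <- dim(volume$values)
  if (!identical(as.integer(dm), as.integer(dv)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dm, collapse = "x"), paste(dv, collapse = "x")),
         call. = FALSE)
  mask <- array(as.numeric(img) > 0.5, dim = dv)
  tumor_roi(mask, animal_id = animal_id, flank = flank,
            modality = volume$modality)
}

# Trilinear interpolation of a 3D array at fractional voxel indices (1-based).
# Out-of-grid queries clamp to the boundary.
interp_trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  xi <- cl(xi, d[1]); yi <- cl(yi, d[2]); zi <- cl(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(xi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  idx <- function(x, y, z) (z - 1) * d[1] * d[2] + (y - 1) * d[1] + x
  v000 <- arr[idx(x0, y0, z0)];         v100 <- arr[idx(x0 + 1, y0, z0)]
  v010 <- arr[idx(x0, y0 + 1, z0)];     v110 <- arr[idx(x0 + 1, y0 + 1, z0)]
  v001 <- arr[idx(x0, y0, z0 + 1)];     v101 <- arr[idx(x0 + 1, y0, z0 + 1)]
  v011 <- arr[idx(x0, y0 + 1, z0 + 1)]; v111 <- arr[idx(x0 + 1, y0 + 1, z0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Resample a volume and its ROI to an isotropic grid
#'
#' Intensities are interpolated trilinearly; the mask by nearest neighbor.
#' Texture directions assume (near) isotropic voxels, so anisotropic CT grids
#' are resampled before feature extraction.
#'
#' @param volume an [image_volume()].
#' @param roi optional [tumor_roi()] on the same grid.
#' @param target_mm isotropic target spacing in mm.
#' @return `list(volume =, roi =)` on the new grid.
#' @export
resample_isotropic <- function(volume, roi = NULL, target_mm = 0.5) {
  stopifnot_scalar_pos(target_mm, "target_mm")
  d <- dim(volume$values)
  sp <- volume$spacing
  if (all(abs(sp - target_mm) < 1e-12))
    return(list(volume = volume, roi = roi))
  extent <- (d - 1) * sp
  nd <- pmax(2L, as.integer(floor(extent / target_mm)) + 1L)
  # output voxel centers in input fractional index coordinates
  ax <- lapply(1:3, function(k) ( (seq_len(nd[k]) - 1) * target_mm ) / sp[k] + 1)
  xi <- rep(ax[[1]], times = nd[2] * nd[3])
  yi <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
  zi <- rep(ax[[3]], each = nd[1] * nd[2])
  vals <- interp_trilinear(volume$values, xi, yi, zi)
  out_vol <- image_volume(array(vals, dim = nd), spacing = rep(target_mm, 3),
                          modality = volume$modality, origin = volume$origin)
  out_roi <- NULL
  if (!is.null(roi)) {
    xn <- pmin(pmax(round(xi), 1), d[1]); yn <- pmin(pmax(round(yi), 1), d[2])
    zn <- pmin(pmax(round(zi), 1), d[3])
    m <- roi$mask[cbind(xn, yn, zn)]
    out_roi <- tumor_roi(array(m, dim = nd), animal_id = roi$animal_id,
                         flank = roi$flank, modality = roi$modality)
  }
  list(volume = out_vol, roi = out_roi)
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a 128-bin histogram; used as the
#' default body-mask rule for MRI normalization.
#'
#' @param values numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold value (intensities above it are "body").
#' @export
otsu_threshold <- function(values, n_bins = 128L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(values, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Normalize MRI intensities
#'
#' Inter-subject MRI intensity variance is scanner-driven; before histogram and
#' texture features are computed, intensities are z-scored within a body mask
#' and then affinely mapped so body intensities span `[0, 1]`. The transform is
#' monotone increasing and invariant to positive affine transforms of the
#' input, so binned-histogram and quantized-texture features are stable across
#' acquisitions.
#'
#' @param volume an MRI [image_volume()].
#' @param body_mask optional logical array; default is voxels above the Otsu
#'   threshold of the whole volume.
#' @return The normalized [image_volume()].
#' @export
normalize_mri <- function(volume, body_mask = NULL) {
  if (volume$modality != "MRI")
    stop("normalize_mri() applies to MRI volumes only (CT stays in calibrated HU)",
         call. = FALSE)
  v <- volume$values
  if (is.null(body_mask)) body_mask <- v > otsu_threshold(as.numeric(v))
  if (sum(body_mask) == 0L) stop("body mask is empty", call. = FALSE)
  mu <- mean(v[body_mask])
  sd_ <- stats::sd(v[body_mask])
  if (!is.finite(sd_) || sd_ == 0)
    stop("zero intensity variance inside body mask; cannot normalize", call. = FALSE)
  z <- (v - mu) / sd_
  zb <- range(z[body_mask])
  z <- (z - zb[1]) / (zb[2] - zb[1])
  image_volume(z, spacing = volume$spacing, modality = "MRI",
               origin = volume$origin)
}
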