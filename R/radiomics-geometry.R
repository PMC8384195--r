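# Geometric features: mask volume, triangulated surface area, shape ratios.

# 6-tetrahedra decomposition of the unit cube along the v0-v6 diagonal.
# Cube corner offsets, row = corner index 0..7.
.cube_offsets <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                       c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
.cube_tets <- rbind(c(0,1,2,6), c(0,2,3,6), c(0,3,7,6),
                    c(0,7,4,6), c(0,4,5,6), c(0,5,1,6)) + 1L

# Total area of triangles defined by three n x 3 coordinate matrices.
tri_area <- function(a, b, c) {
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Separable box-smoothing of a 0/1 array (two passes approximate a small
# Gaussian); keeps the 0.5 isosurface close to the voxel boundary while
# letting edge interpolation place vertices sub-voxel, which removes most of
# the faceting bias of a binary isosurface.
smooth_mask_field <- function(mask, passes = 2L) {
  f <- array(as.numeric(mask), dim(mask))
  d <- dim(f)
  for (q in seq_len(passes)) {
    for (ax in 1:3) {
      idx <- seq_len(d[ax])
      lo <- pmax(idx - 1L, 1L); hi <- pmin(idx + 1L, d[ax])
      f <- switch(ax,
                  (f[lo, , , drop = FALSE] + f + f[hi, , , drop = FALSE]) / 3,
                  (f[, lo, , drop = FALSE] + f + f[, hi, , drop = FALSE]) / 3,
                  (f[, , lo, drop = FALSE] + f + f[, , hi, drop = FALSE]) / 3)
    }
  }
  f
}

# Marching-tetrahedra surface area of a binary mask, in mm^2: the mask is
# lightly smoothed and the 0.5 isosurface triangulated with linear edge
# interpolation.
surface_area_marching <- function(mask, spacing) {
  d <- dim(mask)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(mask)
  pad <- smooth_mask_field(pad)
  dp <- dim(pad)
  # cube base corners
  nb <- dp - 1L
  bx <- rep(seq_len(nb[1]), times = nb[2] * nb[3])
  by <- rep(rep(seq_len(nb[2]), each = nb[1]), times = nb[3])
  bz <- rep(seq_len(nb[3]), each = nb[1] * nb[2])
  lin <- function(x, y, z) (z - 1L) * dp[1] * dp[2] + (y - 1L) * dp[1] + x
  iso <- 0.5
  corner_f <- matrix(0, length(bx), 8)
  for (cidx in 1:8) {
    o <- .cube_offsets[cidx, ]
    corner_f[, cidx] <- pad[lin(bx + o[1], by + o[2], bz + o[3])]
  }
  inside <- corner_f > iso
  ns <- rowSums(inside)
  active <- which(ns > 0 & ns < 8)
  if (length(active) == 0L) return(0)
  corner_f <- corner_f[active, , drop = FALSE]
  inside <- inside[active, , drop = FALSE]
  base <- cbind(bx[active], by[active], bz[active])
  area <- 0
  corner_xyz <- function(cidx) {
    sweep(base + matrix(.cube_offsets[cidx, ], nrow(base), 3, byrow = TRUE) - 1,
          2, spacing, `*`)
  }
  # isosurface vertex on the edge between corners a and b (rows subset)
  edge_vertex <- function(P, Fv, rows, ia, ib) {
    A <- t(vapply(seq_along(rows), function(q) P[[ia[q]]][rows[q], ], numeric(3)))
    B <- t(vapply(seq_along(rows), function(q) P[[ib[q]]][rows[q], ], numeric(3)))
    fa <- Fv[cbind(seq_along(rows), ia)]
    fb <- Fv[cbind(seq_along(rows), ib)]
    t_ <- (iso - fa) / (fb - fa)
    A + (B - A) * t_
  }
  for (tet in seq_len(nrow(.cube_tets))) {
    tc <- .cube_tets[tet, ]
    b4 <- inside[, tc, drop = FALSE]
    f4 <- corner_f[, tc, drop = FALSE]
    nin <- rowSums(b4)
    cut <- which(nin > 0 & nin < 4)
    if (length(cut) == 0L) next
    P <- lapply(tc, corner_xyz)
    for (m in 1:3) { # number of corners inside the surface
      rows <- cut[nin[cut] == m]
      if (length(rows) == 0L) next
      bm <- b4[rows, , drop = FALSE]
      fm <- f4[rows, , drop = FALSE]
      if (m == 2L) {
        # two in (a1,a2), two out (b1,b2): quad cut, two triangles
        ord <- t(apply(bm, 1, function(z) c(which(z), which(!z))))
        v13 <- edge_vertex(P, fm, rows, ord[, 1], ord[, 3])
        v14 <- edge_vertex(P, fm, rows, ord[, 1], ord[, 4])
        v24 <- edge_vertex(P, fm, rows, ord[, 2], ord[, 4])
        v23 <- edge_vertex(P, fm, rows, ord[, 2], ord[, 3])
        area <- area + tri_area(v13, v14, v24) + tri_area(v13, v24, v23)
      } else {
        # one odd corner: triangle on its three edges
        odd <- if (m == 1L) bm else !bm
        oi <- apply(odd, 1, which)
        others <- t(vapply(seq_along(rows), function(q) setdiff(1:4, oi[q]),
                           integer(3)))
        area <- area + tri_area(edge_vertex(P, fm, rows, oi, others[, 1]),
                                edge_vertex(P, fm, rows, oi, others[, 2]),
                                edge_vertex(P, fm, rows, oi, others[, 3]))
      }
    }
  }
  area
}

# Exposed-face surface area: number of mask faces adjacent to background
# times the face area, per axis. Exact for axis-aligned boxes.
surface_area_voxel_face <- function(mask, spacing) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len); dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  total <- 0
  for (ax in 1:3) {
    face <- prod(spacing[-ax])
    total <- total + face * (sum(mask & !shift(mask, ax, 1)) +
                             sum(mask & !shift(mask, ax, -1)))
  }
  total
}

#' Mask surface area
#'
#' @param roi a [tumor_roi()].
#' @param spacing voxel spacing in mm.
#' @param method `"marching"` (marching-tetrahedra triangulated isosurface,
#'   the default) or `"voxel_face"` (exposed voxel faces; exact for
#'   axis-aligned boxes).
#' @return Surface area in mm^2.
#' @export
surface_area <- function(roi, spacing, method = c("marching", "voxel_face")) {
  method <- match.arg(method)
  switch(method,
         marching = surface_area_marching(roi$mask, spacing),
         voxel_face = surface_area_voxel_face(roi$mask, spacing))
}

# CT mass in mg: water-referenced density 1 + HU/1000 mg/mm^3, clamped at
# 0.1 (air pockets cannot carry negative mass). MRI intensities are not
# calibrated to density, so unit density is used.
roi_mass_mg <- function(volume, roi) {
  voxvol <- prod(volume$spacing)
  if (volume$modality == "CT") {
    dens <- pmax(1 + volume$values[roi$mask] / 1000, 0.1)
    sum(dens) * voxvol
  } else {
    sum(roi$mask) * voxvol
  }
}

#' Surface-to-mass ratio
#'
#' Triangulated surface area divided by the mask mass. Unlike sphericity this
#' ratio is not dimensionless (mm^2/mg): a lower value indicates a more
#' compact (and denser, for CT) tumor. For CT, voxel density is
#' `1 + HU/1000` mg/mm^3 clamped at 0.1; MRI uses unit density.
#'
#' @param volume an [image_volume()].
#' @param roi a [tumor_roi()].
#' @param method surface-area method, see [surface_area()].
#' @return Ratio in mm^2/mg.
#' @export
surface_to_mass_ratio <- function(volume, roi,
                                  method = c("marching", "voxel_face")) {
  method <- match.arg(method)
  mass <- roi_mass_mg(volume, roi)
  if (!is.finite(mass) || mass <= 0)
    stop("non-positive tumor mass", call. = FALSE)
  surface_area(roi, volume$spacing, method) / mass
}

geometric_features <- function(volume, roi, surface_method = "marching") {
  sp <- volume$spacing
  n <- sum(roi$mask)
  V <- n * prod(sp)
  A <- surface_area(roi, sp, surface_method)
  mass <- roi_mass_mg(volume, roi)
  co <- arrayInd(which(roi$mask), dim(roi$mask))
  xyz <- sweep(co - 1, 2, sp, `*`)
  ext <- apply(co, 2, function(ix) diff(range(ix)) + 1L) * sp
  elong <- flat <- NA_real_
  if (n >= 3) {
    ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    if (ev[1] > 0) { elong <- sqrt(ev[2] / ev[1]); flat <- sqrt(ev[3] / ev[1]) }
  }
  c(geo_volume_mm3 = V,
    geo_surface_area_mm2 = A,
    geo_surface_to_volume = A / V,
    surface_to_mass_ratio = A / mass,
    geo_sphericity = (pi^(1 / 3) * (6 * V)^(2 / 3)) / A,
    geo_compactness = 36 * pi * V^2 / A^3,
    geo_equiv_diameter_mm = (6 * V / pi)^(1 / 3),
    geo_extent_x_mm = ext[1], geo_extent_y_mm = ext[2], geo_extent_z_mm = ext[3],
    geo_elongation = elong,
    geo_flatness = flat)
}
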