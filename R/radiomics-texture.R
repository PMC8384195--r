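# Gray-level quantization and joint-probability texture machinery.
#
# Intensities are min-max quantized within the ROI (range-based, so all
# texture features are invariant to intensity shifts); pair and triplet
# co-occurrences are accumulated symmetrically over the 13 unique 3D
# directions (or the 4 unique in-plane directions slice-wise).

quantize_levels <- function(vals, G) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rep(1L, length(vals)))
  pmin(G, 1L + as.integer(floor((vals - rng[1]) / diff(rng) * G)))
}

directions_3d <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1),
        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
        c(1,1,1), c(1,1,-1), c(1,-1,1), c(-1,1,1))
}

directions_2d <- function() {
  rbind(c(1,0,0), c(0,1,0), c(1,1,0), c(1,-1,0))
}

# Pair counts for one direction/distance; returns a symmetric G x G count
# matrix (each ordered pair counted in both orders).
cooc_counts_dir <- function(level_arr, mask, G, dir, dist) {
  d <- dim(mask)
  co <- arrayInd(which(mask), d)
  nb <- co + matrix(as.integer(dir) * dist, nrow(co), 3, byrow = TRUE)
  ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
  if (!any(ok)) return(matrix(0, G, G))
  co <- co[ok, , drop = FALSE]; nb <- nb[ok, , drop = FALSE]
  lin <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  nb_lin <- lin(nb)
  inroi <- mask[nb_lin]
  if (!any(inroi)) return(matrix(0, G, G))
  i <- level_arr[lin(co)[inroi]]
  j <- level_arr[nb_lin[inroi]]
  cnt <- tabulate((i - 1L) * G + j, nbins = G * G)
  m <- matrix(cnt, G, G, byrow = TRUE)
  m + t(m)
}

# Collinear triplet counts (v, v+d, v+2d) for one direction/distance, with
# reversal symmetry: (i,j,k) and (k,j,i) both accumulated. Returns a length
# G^3 count vector indexed (i-1)*G^2 + (j-1)*G + k.
triplet_counts_dir <- function(level_arr, mask, G, dir, dist) {
  d <- dim(mask)
  co <- arrayInd(which(mask), d)
  step <- matrix(as.integer(dir) * dist, nrow(co), 3, byrow = TRUE)
  nb1 <- co + step
  nb2 <- co + 2L * step
  ok <- nb2[, 1] >= 1L & nb2[, 1] <= d[1] & nb2[, 2] >= 1L & nb2[, 2] <= d[2] &
        nb2[, 3] >= 1L & nb2[, 3] <= d[3] &
        nb1[, 1] >= 1L & nb1[, 1] <= d[1] & nb1[, 2] >= 1L & nb1[, 2] <= d[2] &
        nb1[, 3] >= 1L & nb1[, 3] <= d[3]
  if (!any(ok)) return(numeric(G^3))
  co <- co[ok, , drop = FALSE]; nb1 <- nb1[ok, , drop = FALSE]
  nb2 <- nb2[ok, , drop = FALSE]
  lin <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  l1 <- lin(nb1); l2 <- lin(nb2)
  inroi <- mask[l1] & mask[l2]
  if (!any(inroi)) return(numeric(G^3))
  i <- level_arr[lin(co)[inroi]]
  j <- level_arr[l1[inroi]]
  k <- level_arr[l2[inroi]]
  cnt <- tabulate((i - 1L) * G * G + (j - 1L) * G + k, nbins = G^3) +
         tabulate((k - 1L) * G * G + (j - 1L) * G + i, nbins = G^3)
  as.numeric(cnt)
}

#' Build a gray-level co-occurrence matrix
#'
#' Intensities inside the ROI are min-max quantized to `levels` gray levels and
#' voxel pairs at the given distance are accumulated symmetrically over the
#' full direction set (13 unique 3D directions, or 4 in-plane directions
#' pooled over axial slices for `directions = "2d"`).
#'
#' @param volume an [image_volume()].
#' @param roi a [tumor_roi()] on the same grid.
#' @param levels number of gray levels G.
#' @param distance voxel offset distance.
#' @param directions `"3d"` or `"2d"` (slice-wise in-plane).
#' @return A `cooc_matrix`: joint probabilities `p` (G x G, summing to 1),
#'   marginals, and the configuration used.
#' @export
compute_cooc <- function(volume, roi, levels = 32L, distance = 1L,
                         directions = c("3d", "2d")) {
  directions <- match.arg(directions)
  vals <- volume$values[roi$mask]
  lv <- quantize_levels(vals, levels)
  level_arr <- array(NA_integer_, dim = dim(roi$mask))
  level_arr[roi$mask] <- lv
  dirs <- if (directions == "3d") directions_3d() else directions_2d()
  cnt <- matrix(0, levels, levels)
  for (r in seq_len(nrow(dirs)))
    cnt <- cnt + cooc_counts_dir(level_arr, roi$mask, levels, dirs[r, ], distance)
  if (sum(cnt) == 0) stop("ROI admits no voxel pairs at this distance", call. = FALSE)
  cooc_matrix(cnt / sum(cnt), distance = distance, directions = directions)
}

#' Construct a co-occurrence matrix object from joint probabilities
#'
#' @param p square matrix of joint probabilities (will be checked to sum to 1).
#' @param distance,directions metadata describing how `p` was accumulated.
#' @return A `cooc_matrix` object.
#' @export
cooc_matrix <- function(p, distance = NA_integer_, directions = NA_character_) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("co-occurrence matrix must be square", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("joint probabilities must sum to 1", call. = FALSE)
  structure(list(p = p, levels = nrow(p), p_x = rowSums(p), p_y = colSums(p),
                 distance = distance, directions = directions),
            class = "cooc_matrix")
}

#' Second-order (co-occurrence) texture statistics
#'
#' The 18 classical co-occurrence statistics: energy (angular second moment),
#' contrast, correlation, variance, homogeneity (inverse difference moment),
#' sum average/variance/entropy, entropy, difference variance/entropy, the two
#' information measures of correlation, maximum probability, cluster shade,
#' cluster prominence, autocorrelation and dissimilarity. Natural logarithms
#' are used for all entropies; IMC ratios are base-invariant.
#'
#' @param cooc a [cooc_matrix()].
#' @return Named numeric vector of 18 statistics.
#' @export
second_order_features <- function(cooc) {
  p <- cooc$p
  G <- cooc$levels
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  # p_{x+y}(s), s = i+j in 2..2G ; p_{x-y}(k), k = |i-j| in 0..G-1
  s_idx <- as.vector(i + j)
  pxy_sum <- as.numeric(tapply(as.vector(p), factor(s_idx, levels = 2:(2 * G)), sum))
  pxy_sum[is.na(pxy_sum)] <- 0
  d_idx <- as.vector(abs(i - j))
  pxy_dif <- as.numeric(tapply(as.vector(p), factor(d_idx, levels = 0:(G - 1)), sum))
  pxy_dif[is.na(pxy_dif)] <- 0
  s_vals <- 2:(2 * G)
  k_vals <- 0:(G - 1)
  sum_avg <- sum(s_vals * pxy_sum)
  dif_avg <- sum(k_vals * pxy_dif)
  HX <- shannon_entropy(px); HY <- shannon_entropy(py)
  HXY <- shannon_entropy(as.vector(p))
  pxpy <- as.vector(outer(px, py))
  pv <- as.vector(p)
  HXY1 <- -sum(ifelse(pv > 0 & pxpy > 0, pv * log(pxpy), 0))
  HXY2 <- shannon_entropy(pxpy)
  denom <- max(HX, HY)
  imc1 <- if (denom > 0) (HXY - HXY1) / denom else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else NA_real_
  c(energy = sum(p^2),
    contrast = sum(p * (i - j)^2),
    correlation = corr,
    variance = sum(p * (i - mux)^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    sum_average = sum_avg,
    sum_variance = sum((s_vals - sum_avg)^2 * pxy_sum),
    sum_entropy = shannon_entropy(pxy_sum),
    entropy = HXY,
    diff_variance = sum((k_vals - dif_avg)^2 * pxy_dif),
    diff_entropy = shannon_entropy(pxy_dif),
    imc1 = imc1,
    imc2 = imc2,
    max_prob = max(p),
    cluster_shade = sum(p * (i + j - mux - muy)^3),
    cluster_prominence = sum(p * (i + j - mux - muy)^4),
    autocorrelation = sum(p * i * j),
    dissimilarity = sum(p * abs(i - j)))
}

#' Build a third-order (collinear triplet) joint-probability tensor
#'
#' The joint distribution of quantized gray levels at three collinear voxels
#' `(v, v + d, v + 2d)`, accumulated with reversal symmetry over the 13 unique
#' 3D directions; it generalizes the co-occurrence matrix to triplets.
#'
#' @inheritParams compute_cooc
#' @param levels number of gray levels G (tensor is G^3).
#' @return A `triplet_tensor`: probabilities `p` (length G^3, indexed
#'   `(i-1)G^2 + (j-1)G + k`), marginals, and joint/product entropies.
#' @export
compute_triplet_tensor <- function(volume, roi, levels = 16L, distance = 1L) {
  vals <- volume$values[roi$mask]
  lv <- quantize_levels(vals, levels)
  level_arr <- array(NA_integer_, dim = dim(roi$mask))
  level_arr[roi$mask] <- lv
  dirs <- directions_3d()
  cnt <- numeric(levels^3)
  for (r in seq_len(nrow(dirs)))
    cnt <- cnt + triplet_counts_dir(level_arr, roi$mask, levels, dirs[r, ], distance)
  if (sum(cnt) == 0) stop("ROI admits no collinear triplets at this distance", call. = FALSE)
  triplet_tensor(cnt / sum(cnt), levels = levels, distance = distance)
}

#' Construct a triplet joint-probability tensor from probabilities
#'
#' @param p numeric vector of length `levels^3` (or a G x G x G array) of
#'   joint probabilities.
#' @param levels number of gray levels G.
#' @param distance metadata: voxel step used.
#' @return A `triplet_tensor` object.
#' @export
triplet_tensor <- function(p, levels = NULL, distance = NA_integer_) {
  if (is.array(p) && length(dim(p)) == 3L) {
    levels <- dim(p)[1]
    # array layout p[i,j,k] -> vector layout (i-1)G^2+(j-1)G+k
    p <- as.vector(aperm(p, c(3, 2, 1)))
  }
  if (is.null(levels)) levels <- round(length(p)^(1 / 3))
  G <- as.integer(levels)
  if (length(p) != G^3) stop("tensor length must be levels^3", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("joint probabilities must sum to 1", call. = FALSE)
  idx <- triplet_index(G)
  p_x <- as.numeric(rowsum(p, idx$i)[, 1])
  p_y <- as.numeric(rowsum(p, idx$j)[, 1])
  p_z <- as.numeric(rowsum(p, idx$k)[, 1])
  H_XYZ <- shannon_entropy(p)
  prod_marg <- p_x[idx$i] * p_y[idx$j] * p_z[idx$k]
  H_XYZ1 <- -sum(ifelse(p > 0 & prod_marg > 0, p * log(prod_marg), 0))
  H_XYZ2 <- shannon_entropy(prod_marg)
  structure(list(p = p, levels = G, p_x = p_x, p_y = p_y, p_z = p_z,
                 H_X = shannon_entropy(p_x), H_Y = shannon_entropy(p_y),
                 H_Z = shannon_entropy(p_z),
                 H_XYZ = H_XYZ, H_XYZ1 = H_XYZ1, H_XYZ2 = H_XYZ2,
                 distance = distance),
            class = "triplet_tensor")
}

triplet_index <- function(G) {
  n <- G^3
  k <- rep(seq_len(G), times = G * G)
  j <- rep(rep(seq_len(G), each = G), times = G)
  i <- rep(seq_len(G), each = G * G)
  list(i = i, j = j, k = k)
}

#' Third-order information measure of correlation (3D IMC1)
#'
#' Measures, via mutual information, the dependence between the gray levels of
#' three collinear tumor voxels: `(H_XYZ - H_XYZ1) / max(H_X, H_Y, H_Z)` with
#' natural-log entropies. It is 0 when the triplet distribution factorizes
#' into its marginals (no mutual information) and strictly negative under
#' dependence; a uniform perfectly dependent tensor gives -2.
#'
#' @param tensor a [triplet_tensor()].
#' @return A scalar in `(-2, 0]` (0, flagged by attribute `degenerate`, for a
#'   constant ROI whose marginal entropies vanish).
#' @export
imc1_3d <- function(tensor) {
  stopifnot(inherits(tensor, "triplet_tensor"))
  denom <- max(tensor$H_X, tensor$H_Y, tensor$H_Z)
  if (denom <= 0) return(structure(0, degenerate = TRUE))
  (tensor$H_XYZ - tensor$H_XYZ1) / denom
}

# The 12 triplet statistics used by the third-order feature family.
triplet_stats <- function(tensor) {
  p <- tensor$p
  G <- tensor$levels
  idx <- triplet_index(G)
  i <- idx$i; j <- idx$j; k <- idx$k
  sq <- ((i - j)^2 + (j - k)^2 + (i - k)^2) / 3
  ab <- (abs(i - j) + abs(j - k) + abs(i - k)) / 3
  s <- i + j + k
  ps <- as.numeric(rowsum(p, s)[, 1])
  s_vals <- sort(unique(s))
  sum_avg <- sum(s_vals * ps)
  denom <- max(tensor$H_X, tensor$H_Y, tensor$H_Z)
  imc1 <- if (denom > 0) (tensor$H_XYZ - tensor$H_XYZ1) / denom else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (tensor$H_XYZ2 - tensor$H_XYZ))))
  c(energy = sum(p^2),
    entropy = tensor$H_XYZ,
    max_prob = max(p),
    contrast = sum(p * sq),
    dissimilarity = sum(p * ab),
    homogeneity = sum(p / (1 + sq)),
    imc1 = imc1,
    imc2 = imc2,
    sum_average = sum_avg,
    sum_entropy = shannon_entropy(ps),
    sum_variance = sum((s_vals - sum_avg)^2 * ps),
    autocorrelation = sum(p * i * j * k))
}
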