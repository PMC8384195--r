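# Independent naive-loop oracles and small phantom builders used across the
# suite. These deliberately share no code with the package internals.

make_sphere_mask <- function(d = 15L, r = 5.5, ctr = (d + 1) / 2) {
  co <- expand.grid(x = seq_len(d), y = seq_len(d), z = seq_len(d))
  array((co$x - ctr)^2 + (co$y - ctr)^2 + (co$z - ctr)^2 <= r^2, c(d, d, d))
}

make_cube_mask <- function(d = 12L, lo = 3L, hi = 10L) {
  m <- array(FALSE, c(d, d, d))
  m[lo:hi, lo:hi, lo:hi] <- TRUE
  m
}

oracle_dirs_3d <- rbind(
  c(1,0,0), c(0,1,0), c(0,0,1),
  c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
  c(1,1,1), c(1,1,-1), c(1,-1,1), c(-1,1,1))

# min-max quantization, duplicated on purpose from first principles
oracle_quantize <- function(vals, G) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rep(1L, length(vals)))
  pmin(G, 1L + as.integer(floor((vals - rng[1]) / diff(rng) * G)))
}

# Pooled symmetric GLCM probabilities by literal voxel-pair enumeration.
oracle_glcm <- function(values, mask, G, dirs, dist = 1L) {
  lv <- array(NA_integer_, dim(mask))
  lv[mask] <- oracle_quantize(values[mask], G)
  d <- dim(mask)
  cnt <- matrix(0, G, G)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (r in seq_len(nrow(dirs))) {
      nx <- x + dirs[r, 1] * dist; ny <- y + dirs[r, 2] * dist
      nz <- z + dirs[r, 3] * dist
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      if (!mask[nx, ny, nz]) next
      i <- lv[x, y, z]; j <- lv[nx, ny, nz]
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
  }
  cnt / sum(cnt)
}

# Literal double-loop versions of the 18 co-occurrence statistics.
oracle_glcm_stats <- function(p) {
  G <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum((1:G - mux)^2 * px)); sy <- sqrt(sum((1:G - muy)^2 * py))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  psum <- rep(0, 2 * G); pdif <- rep(0, G)
  s <- numeric(18); names(s) <- c("energy","contrast","correlation","variance",
    "homogeneity","sum_average","sum_variance","sum_entropy","entropy",
    "diff_variance","diff_entropy","imc1","imc2","max_prob","cluster_shade",
    "cluster_prominence","autocorrelation","dissimilarity")
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
    s["energy"] <- s["energy"] + v^2
    s["contrast"] <- s["contrast"] + v * (i - j)^2
    s["variance"] <- s["variance"] + v * (i - mux)^2
    s["homogeneity"] <- s["homogeneity"] + v / (1 + (i - j)^2)
    s["cluster_shade"] <- s["cluster_shade"] + v * (i + j - mux - muy)^3
    s["cluster_prominence"] <- s["cluster_prominence"] + v * (i + j - mux - muy)^4
    s["autocorrelation"] <- s["autocorrelation"] + v * i * j
    s["dissimilarity"] <- s["dissimilarity"] + v * abs(i - j)
    if (v > 0) HXY <- HXY - v * log(v)
    if (v > 0 && px[i] * py[j] > 0) HXY1 <- HXY1 - v * log(px[i] * py[j])
    if (px[i] * py[j] > 0) HXY2 <- HXY2 - px[i] * py[j] * log(px[i] * py[j])
  }
  sa <- sum((2:(2 * G)) * psum[2:(2 * G)])
  s["sum_average"] <- sa
  s["sum_variance"] <- sum(((2:(2 * G)) - sa)^2 * psum[2:(2 * G)])
  s["sum_entropy"] <- ent(psum)
  s["entropy"] <- HXY
  da <- sum((0:(G - 1)) * pdif)
  s["diff_variance"] <- sum(((0:(G - 1)) - da)^2 * pdif)
  s["diff_entropy"] <- ent(pdif)
  s["correlation"] <- if (sx > 0 && sy > 0)
    (sum(outer(1:G, 1:G) * p) - mux * muy) / (sx * sy) else NA_real_
  denom <- max(ent(px), ent(py))
  s["imc1"] <- if (denom > 0) (HXY - HXY1) / denom else 0
  s["imc2"] <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  s["max_prob"] <- max(p)
  s
}

# Pooled symmetric triplet tensor (array G x G x G) by literal enumeration of
# collinear triplets, accumulating (i,j,k) and (k,j,i).
oracle_triplet <- function(values, mask, G, dist = 1L) {
  lv <- array(NA_integer_, dim(mask))
  lv[mask] <- oracle_quantize(values[mask], G)
  d <- dim(mask)
  cnt <- array(0, c(G, G, G))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (r in seq_len(nrow(oracle_dirs_3d))) {
      x1 <- x + oracle_dirs_3d[r, 1] * dist; y1 <- y + oracle_dirs_3d[r, 2] * dist
      z1 <- z + oracle_dirs_3d[r, 3] * dist
      x2 <- x + 2 * oracle_dirs_3d[r, 1] * dist; y2 <- y + 2 * oracle_dirs_3d[r, 2] * dist
      z2 <- z + 2 * oracle_dirs_3d[r, 3] * dist
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      if (x1 < 1 || x1 > d[1] || y1 < 1 || y1 > d[2] || z1 < 1 || z1 > d[3]) next
      if (!mask[x1, y1, z1] || !mask[x2, y2, z2]) next
      i <- lv[x, y, z]; j <- lv[x1, y1, z1]; k <- lv[x2, y2, z2]
      cnt[i, j, k] <- cnt[i, j, k] + 1
      cnt[k, j, i] <- cnt[k, j, i] + 1
    }
  }
  cnt / sum(cnt)
}

# IMC1 of a triplet probability array by literal summation.
oracle_triplet_imc1 <- function(parr) {
  G <- dim(parr)[1]
  px <- apply(parr, 1, sum); py <- apply(parr, 2, sum); pz <- apply(parr, 3, sum)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  H <- 0; H1 <- 0
  for (i in 1:G) for (j in 1:G) for (k in 1:G) {
    v <- parr[i, j, k]
    if (v > 0) {
      H <- H - v * log(v)
      pr <- px[i] * py[j] * pz[k]
      if (pr > 0) H1 <- H1 - v * log(pr)
    }
  }
  denom <- max(ent(px), ent(py), ent(pz))
  if (denom > 0) (H - H1) / denom else 0
}

# AUC by exhaustive positive x negative pair counting (ties get 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_prob_tensor <- function(G) {
  a <- array(stats::rexp(G^3), c(G, G, G))
  a / sum(a)
}

# Deterministic small test volume/ROI pair with texture.
small_textured_roi <- function(seed = 42, d = 10L, modality = "CT") {
  set.seed(seed)
  vals <- array(stats::rnorm(d^3, 50, 12), c(d, d, d))
  mask <- make_sphere_mask(d, r = d / 2 - 1)
  list(volume = image_volume(vals, c(1, 1, 1), modality),
       roi = tumor_roi(mask, "t1", "left", modality))
}
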