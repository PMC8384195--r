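#' Specification of a synthetic bilateral-tumor cohort
#'
#' Defines the study conditions the generator emulates: a 4-animal untreated
#' control arm with unchecked exponential growth, a treated arm (default 15
#' animals) of which ~27% experience the abscopal effect, bilateral ellipsoid
#' tumors around 200 mm^3 at imaging with a doubling time of about a week,
#' and planted group differences in the five analysis features plus the
#' neutrophil-to-lymphocyte ratio (abscopal mean ~66% of non-abscopal).
#'
#' @param n_control,n_treated arm sizes.
#' @param abscopal_fraction fraction of treated animals labeled abscopal; the
#'   planted count is `round(abscopal_fraction * n_treated)`.
#' @param effect_sizes named standardized group mean shifts (abscopal minus
#'   non-abscopal, in units of the within-group sd on the model scale) for
#'   planted features; names use analysis-table columns (`ct_*` / `mri_*`).
#' @param nlr_ratio abscopal-group mean NLR over non-abscopal mean.
#' @param doubling_time_days control-tumor volume doubling time.
#' @param baseline_volume_range_mm3 per-tumor baseline volume is log-uniform
#'   over this range (mirrors the observed ~100-440 mm^3 spread around a
#'   ~214 mm^3 mean).
#' @param voxel_spacing_ct,voxel_spacing_mri acquisition grids in mm.
#' @param growth_noise_sd log-sd of multiplicative caliper measurement noise.
#' @param measurement_days caliper day grid (day 0 = imaging day; two to
#'   three measurements per week out to two days past the treatment window).
#' @param icc within-animal correlation of tumor-level feature draws.
#' @param seed master seed; all stages derive deterministic substreams.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 4L, n_treated = 15L,
                        abscopal_fraction = 0.27,
                        effect_sizes = default_effect_sizes(),
                        nlr_ratio = 0.66,
                        doubling_time_days = 7,
                        baseline_volume_range_mm3 = c(100, 440),
                        voxel_spacing_ct = c(0.4, 0.4, 0.6),
                        voxel_spacing_mri = c(0.5, 0.5, 0.5),
                        growth_noise_sd = 0.1,
                        measurement_days = c(0, 2, 5, 7, 9, 12),
                        icc = 0.15,
                        seed = 1L) {
  if (n_control < 0 || n_treated < 0) abort_config("n_control/n_treated", "must be >= 0")
  if (abscopal_fraction < 0 || abscopal_fraction > 1)
    abort_config("abscopal_fraction", "must be in [0, 1]")
  if (n_treated >= 4L && round(abscopal_fraction * n_treated) < 1)
    abort_config("abscopal_fraction", "rounds to no abscopal animal for this arm size")
  if (any(voxel_spacing_ct <= 0) || any(voxel_spacing_mri <= 0))
    abort_config("voxel_spacing", "all spacings must be > 0")
  if (!is.numeric(nlr_ratio) || nlr_ratio <= 0) abort_config("nlr_ratio", "must be > 0")
  stopifnot_scalar_pos(doubling_time_days, "doubling_time_days")
  if (growth_noise_sd < 0) abort_config("growth_noise_sd", "must be >= 0")
  structure(list(n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 abscopal_fraction = abscopal_fraction,
                 effect_sizes = effect_sizes, nlr_ratio = nlr_ratio,
                 doubling_time_days = doubling_time_days,
                 baseline_volume_range_mm3 = baseline_volume_range_mm3,
                 voxel_spacing_ct = voxel_spacing_ct,
                 voxel_spacing_mri = voxel_spacing_mri,
                 growth_noise_sd = growth_noise_sd,
                 measurement_days = measurement_days,
                 icc = icc, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default planted effect sizes
#'
#' Standardized abscopal-vs-non-abscopal mean shifts for the five analysis
#' features, with the directions reported for the real cohorts: abscopal
#' tumors have larger surface-to-mass ratio, lower CT histogram kurtosis and
#' average gray, markedly higher (~4x) MRI histogram kurtosis, and more
#' negative MRI third-order IMC1. Magnitudes are fixed at 2.8 sd, except
#' the MRI kurtosis whose shift (2.0 sd on the log scale, within-group log-sd
#' 0.693) is anchored to its ~4-fold change.
#'
#' @return Named numeric vector.
#' @export
default_effect_sizes <- function() {
  c(ct_surface_to_mass_ratio = 2.8,
    ct_kurtosis_2d = -2.8,
    ct_average_gray = -2.8,
    mri_kurtosis_2d = 2.0,
    mri_imc1_3d = -2.8)
}

# Group model for planted features: per-feature sampling scale, baseline
# (non-abscopal) mean and within-group sd on that scale. The abscopal group
# mean is base + shift * sd. Shared by the feature-table sampler and the
# image synthesizer so both emulate the same population.
planted_feature_model <- function(spec) {
  base <- list(
    ct_surface_to_mass_ratio = list(scale = "log", mean = log(0.80), sd = 0.08),
    ct_kurtosis_2d           = list(scale = "log", mean = log(3.2), sd = 0.15),
    ct_average_gray          = list(scale = "identity", mean = 45, sd = 10),
    mri_kurtosis_2d          = list(scale = "log", mean = log(2.5), sd = 0.693),
    mri_imc1_3d              = list(scale = "identity", mean = -0.10, sd = 0.025))
  for (nm in names(base)) {
    sh <- spec$effect_sizes[nm]
    base[[nm]]$shift <- if (is.na(sh)) 0 else unname(sh)
  }
  # planted features named in effect_sizes but absent above get a generic
  # standard-normal baseline
  extra <- setdiff(names(spec$effect_sizes), names(base))
  for (nm in extra)
    base[[nm]] <- list(scale = "identity", mean = 0, sd = 1,
                       shift = unname(spec$effect_sizes[nm]))
  base
}

# Draw one animal's planted feature values (both tumors, within-animal
# correlation icc) given its group.
draw_planted <- function(model, abscopal, icc) {
  out <- list(left = numeric(0), right = numeric(0))
  for (nm in names(model)) {
    m <- model[[nm]]
    mu <- m$mean + if (isTRUE(abscopal)) m$shift * m$sd else 0
    a <- stats::rnorm(1)
    e <- stats::rnorm(2)
    v <- mu + m$sd * (sqrt(icc) * a + sqrt(1 - icc) * e)
    if (m$scale == "log") v <- exp(v)
    out$left[nm] <- v[1]
    out$right[nm] <- v[2]
  }
  out
}

draw_cbc <- function(animal_id, abscopal, spec) {
  lymph <- stats::rlnorm(1, log(6000), 0.2)
  nlr_mu <- log(0.45) + if (isTRUE(abscopal)) log(spec$nlr_ratio) else 0
  nlr_val <- stats::rlnorm(1, nlr_mu, 0.18)
  neut <- nlr_val * lymph
  mono <- stats::rlnorm(1, log(300), 0.3)
  eos <- stats::rlnorm(1, log(100), 0.4)
  baso <- stats::rlnorm(1, log(30), 0.5)
  cbc_panel(animal_id, wbc = neut + lymph + mono + eos + baso,
            neutrophils = neut, lymphocytes = lymph, monocytes = mono,
            eosinophils = eos, basophils = baso,
            rbc = stats::rlnorm(1, log(9e6), 0.1))
}

#' Generate bilateral caliper growth curves for one animal
#'
#' Deterministic exponential kinetics with multiplicative log-normal
#' measurement noise. Controls grow unchecked at the specified doubling time
#' on both flanks; treated non-abscopal animals show growth delay on the
#' irradiated right flank while the left flank grows faster; abscopal animals
#' shrink on both flanks with the left trajectory at or below the right one.
#'
#' @param arm `"control"` or `"treated"`.
#' @param abscopal logical (treated arm only).
#' @param spec a [cohort_spec()].
#' @param animal_id identifier stamped on the records.
#' @param baseline_mm3 length-2 baseline volumes (left, right); defaults to
#'   log-uniform draws over the spec range.
#' @param noise_sd override of the measurement noise log-sd.
#' @return `list(left =, right =)` of [growth_record()]s.
#' @export
generate_growth <- function(arm, abscopal, spec, animal_id = "a1",
                            baseline_mm3 = NULL, noise_sd = NULL) {
  days <- spec$measurement_days
  horizon <- max(days)
  g <- log(2) / spec$doubling_time_days
  if (is.null(baseline_mm3)) {
    r <- log(spec$baseline_volume_range_mm3)
    baseline_mm3 <- exp(stats::runif(2, r[1], r[2]))
  }
  noise_sd <- noise_sd %||% spec$growth_noise_sd
  rates <- if (arm == "control") c(left = g, right = g)
  else if (isTRUE(abscopal)) {
    right <- -0.5 * g
    c(left = right + log(0.75) / horizon, right = right)
  } else c(left = 0.7 * g, right = 0.1 * g)
  rec <- function(flank) {
    v <- baseline_mm3[[if (flank == "left") 1 else 2]] *
      exp(rates[[flank]] * days) *
      exp(stats::rnorm(length(days), 0, noise_sd))
    # invert the caliper formula assuming aspect ratio length/width = 1.2
    w <- (2 * v / 1.2)^(1 / 3)
    growth_record(animal_id, flank, days, width_mm = w, length_mm = 1.2 * w)
  }
  list(left = rec("left"), right = rec("right"))
}

# ---- image synthesis ------------------------------------------------------

# Spatially correlated Gaussian random field via FFT smoothing of white
# noise; marginal approximately N(0,1), correlation length `ell` voxels.
gaussian_random_field <- function(dim3, ell) {
  wn <- array(stats::rnorm(prod(dim3)), dim3)
  if (ell <= 0) return(wn)
  ax <- lapply(dim3, function(n) {
    f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
    exp(-2 * (pi * f * ell)^2)
  })
  ker <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  sm <- Re(fft(fft(wn) * array(ker, dim3), inverse = TRUE)) / prod(dim3)
  sm / stats::sd(sm)
}

# Map a ~N(0,1) field to a zero-mean unit-variance marginal with the target
# Pearson kurtosis: Student-t tails for kurtosis > 3, symmetric beta for
# kurtosis < 3, identity at 3.
kurtosis_transform <- function(z, kurt) {
  kurt <- min(max(kurt, 1.3), 30)
  u <- stats::pnorm(z)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  if (abs(kurt - 3) < 1e-6) return(z)
  if (kurt > 3) {
    nu <- 4 + 6 / (kurt - 3)
    x <- stats::qt(u, nu)
    x / sqrt(nu / (nu - 2))
  } else {
    al <- 3 * (kurt - 1) / (2 * (3 - kurt))
    x <- stats::qbeta(u, al, al) - 0.5
    x / sqrt(1 / (4 * (2 * al + 1)))
  }
}

# Synthesize one tumor: ellipsoid mask with smooth boundary perturbation on
# an image grid, plus intensities with the requested histogram shape and
# spatial correlation.
synth_tumor_image <- function(modality, spacing, volume_mm3, mean_gray,
                              sd_gray, kurt, ell = 1.2, roughness = 0.08,
                              background = NULL) {
  # oblate-ish ellipsoid: a = b, c = 0.8 a
  a <- (3 * volume_mm3 / (4 * pi * 0.8))^(1 / 3)
  semi <- c(a, a, 0.8 * a)
  dimv <- as.integer(2 * ceiling(semi / spacing) + 9L)
  ctr <- (dimv + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(dimv[k]) - ctr[k]) * spacing[k]) / semi[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  bump <- gaussian_random_field(dimv, 1.5)
  # roughness deforms the normalized radius; the threshold is then set at the
  # quantile matching the requested analytic volume, so the mask volume equals
  # volume_mm3 up to voxel rounding whatever the boundary perturbation
  g <- sqrt(r2) - roughness * bump
  n_target <- max(27L, min(round(volume_mm3 / prod(spacing)),
                           length(g) - 1L))
  thr <- sort(as.vector(g), partial = n_target)[n_target]
  mask <- g <= thr
  tex <- gaussian_random_field(dimv, ell)
  vals <- mean_gray + sd_gray * kurtosis_transform(tex, kurt)
  bg <- background %||% (if (modality == "CT") -60 else 60)
  out <- array(bg + 0.05 * abs(sd_gray) * stats::rnorm(prod(dimv)), dimv)
  out[mask] <- vals[mask]
  list(volume = image_volume(out, spacing, modality),
       mask = mask, semi_axes = semi)
}

# Monotone map from a target third-order IMC1 to a texture correlation
# length in voxels: stronger spatial dependence (longer ell) makes IMC1 more
# negative. Anchored on measured phantom values; clamped to the usable range.
imc1_to_ell <- function(imc1) {
  imc1 <- min(max(imc1, -0.6), -0.02)
  0.45 + 2.2 * (-imc1)
}

#' Generate a complete synthetic cohort
#'
#' Draws every animal of the specified cohort: arm and abscopal status, a CBC
#' panel, bilateral growth curves, and per-flank CT and MRI phantom volumes
#' with segmentation masks whose extracted features carry the planted group
#' effects. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param images if `FALSE`, skip image synthesis (CBC, growth, and planted
#'   feature values are still drawn); used where only the downstream
#'   statistics are under study.
#' @return A list of `synthetic_animal` records: `animal_id`, `arm`,
#'   `abscopal` (NA for controls), `cbc`, `growth` (left/right), `tumors`
#'   (per modality and flank: `volume`, `roi`), and `planted` (the latent
#'   per-tumor feature targets).
#' @export
generate_cohort <- function(spec, images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- planted_feature_model(spec)
  with_seed(derive_seed(spec$seed, "cohort"), {
    n_abs <- round(spec$abscopal_fraction * spec$n_treated)
    abs_flags <- rep(FALSE, spec$n_treated)
    if (n_abs > 0) abs_flags[sample(spec$n_treated, n_abs)] <- TRUE
    animals <- list()
    idx <- 0L
    for (arm in c("control", "treated")) {
      n_arm <- if (arm == "control") spec$n_control else spec$n_treated
      for (q in seq_len(n_arm)) {
        idx <- idx + 1L
        aid <- sprintf("m%02d", idx)
        absc <- if (arm == "treated") abs_flags[q] else NA
        planted <- draw_planted(model, isTRUE(absc), spec$icc)
        cbc <- draw_cbc(aid, isTRUE(absc), spec)
        growth <- generate_growth(arm, isTRUE(absc), spec, animal_id = aid)
        tumors <- NULL
        if (images) {
          tumors <- list()
          for (fl in c("left", "right")) {
            v0 <- growth[[fl]]$volume_mm3[1]
            pl <- planted[[fl]]
            rough <- min(max((pl[["ct_surface_to_mass_ratio"]] - 0.745) / 0.40,
                             0.02), 0.45)
            ct <- synth_tumor_image("CT", spec$voxel_spacing_ct, v0,
                                    mean_gray = pl[["ct_average_gray"]],
                                    sd_gray = 15,
                                    kurt = pl[["ct_kurtosis_2d"]],
                                    ell = 0.8, roughness = rough)
            mri <- synth_tumor_image("MRI", spec$voxel_spacing_mri, v0,
                                     mean_gray = 500, sd_gray = 90,
                                     kurt = pl[["mri_kurtosis_2d"]],
                                     ell = imc1_to_ell(pl[["mri_imc1_3d"]]),
                                     roughness = 0.06)
            tumors[[paste0("ct_", fl)]] <-
              list(volume = ct$volume,
                   roi = tumor_roi(ct$mask, aid, fl, "CT"))
            tumors[[paste0("mri_", fl)]] <-
              list(volume = mri$volume,
                   roi = tumor_roi(mri$mask, aid, fl, "MRI"))
          }
        }
        animals[[idx]] <- structure(
          list(animal_id = aid, arm = arm, abscopal = absc, cbc = cbc,
               growth = growth, tumors = tumors, planted = planted),
          class = "synthetic_animal")
      }
    }
    animals
  })
}

#' Simulate the tumor-level feature table directly
#'
#' Draws the analysis-table feature values straight from the generator's group
#' model (planted features from their group distributions, the remaining
#' catalogue as uninformative standard-normal columns, within-animal
#' correlation `spec$icc`), bypassing image synthesis. This is the sampler
#' used for repeated-cohort studies of the selection and modeling stages,
#' where hundreds of cohorts are needed; [generate_cohort()] +
#' [extract_features()] realizes the same population through actual phantom
#' images.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return A list of animal records suitable for [build_analysis_table()]
#'   (treated arm only, since only treated animals carry a label).
#' @export
simulate_feature_table <- function(spec, seed = NULL) {
  model <- planted_feature_model(spec)
  with_seed(derive_seed(seed %||% spec$seed, "feature-table"), {
    n_abs <- round(spec$abscopal_fraction * spec$n_treated)
    abs_flags <- rep(FALSE, spec$n_treated)
    if (n_abs > 0) abs_flags[sample(spec$n_treated, n_abs)] <- TRUE
    lapply(seq_len(spec$n_treated), function(q) {
      aid <- sprintf("m%02d", q)
      absc <- abs_flags[q]
      planted <- draw_planted(model, absc, spec$icc)
      fe <- list()
      # Label-uninformative features: animal latent + tumor noise (ICC), with
      # a 12-block latent-factor structure (loading 0.8) mimicking the heavy
      # redundancy of a real radiomics catalogue — the decorrelation filter
      # sees correlated blocks, not 87 independent screens.
      nm_ct <- radiomics_feature_names()
      nblk <- 12L
      blk <- (seq_along(nm_ct) - 1L) %% nblk + 1L
      lam <- 0.8
      for (pref in c("ct", "mri")) {
        fa <- stats::rnorm(nblk)
        lat <- lam * fa[blk] + sqrt(1 - lam^2) * stats::rnorm(length(nm_ct))
        for (fl in c("left", "right")) {
          fe_t <- stats::rnorm(nblk)
          e <- lam * fe_t[blk] + sqrt(1 - lam^2) * stats::rnorm(length(nm_ct))
          vals <- sqrt(spec$icc) * lat + sqrt(1 - spec$icc) * e
          names(vals) <- nm_ct
          fe[[paste0(pref, "_", fl)]] <- vals
        }
      }
      # overwrite planted columns with group-model draws
      for (nm in names(planted$left)) {
        pref <- sub("_.*$", "", nm)
        feat <- sub("^(ct|mri)_", "", nm)
        fe[[paste0(pref, "_left")]][feat] <- planted$left[[nm]]
        fe[[paste0(pref, "_right")]][feat] <- planted$right[[nm]]
      }
      cbc <- draw_cbc(aid, absc, spec)
      list(animal_id = aid, label = absc, cbc = cbc, features = fe,
           planted = planted)
    })
  })
}
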