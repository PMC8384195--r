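#' Ellipsoid tumor volume from caliper measurements
#'
#' `width^2 * length / 2` with the convention `width <= length` enforced by
#' swapping, so the result does not depend on which caliper axis was recorded
#' first.
#'
#' @param width_mm,length_mm caliper measurements in mm (vectorized).
#' @return Volume in mm^3.
#' @export
caliper_volume <- function(width_mm, length_mm) {
  if (any(!is.finite(width_mm)) || any(!is.finite(length_mm)) ||
      any(width_mm <= 0) || any(length_mm <= 0))
    stop("caliper measurements must be positive", call. = FALSE)
  w <- pmin(width_mm, length_mm)
  l <- pmax(width_mm, length_mm)
  w^2 * l / 2
}

#' Complete blood count panel
#'
#' Per-animal leukocyte/erythrocyte concentrations (cells/uL) with derived
#' ratios; blood is animal-level and shared by both flank tumors.
#'
#' @param animal_id animal identifier.
#' @param wbc,neutrophils,lymphocytes,monocytes,eosinophils,basophils,rbc
#'   counts in cells/uL (rbc in cells/uL as reported by the counter).
#' @return A list of class `cbc_panel` with a `ratios` element (currently the
#'   neutrophil-to-lymphocyte ratio when lymphocytes > 0).
#' @export
cbc_panel <- function(animal_id, wbc, neutrophils, lymphocytes, monocytes = 0,
                      eosinophils = 0, basophils = 0, rbc = 0) {
  counts <- c(wbc = wbc, neutrophils = neutrophils, lymphocytes = lymphocytes,
              monocytes = monocytes, eosinophils = eosinophils,
              basophils = basophils, rbc = rbc)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("CBC counts must be non-negative", call. = FALSE)
  ratios <- list()
  if (lymphocytes > 0) ratios$nlr <- neutrophils / lymphocytes
  structure(c(list(animal_id = animal_id), as.list(counts), list(ratios = ratios)),
            class = "cbc_panel")
}

#' Neutrophil-to-lymphocyte ratio
#'
#' Lower pre-treatment NLR is associated with better immunotherapy response.
#'
#' @param panel a [cbc_panel()].
#' @return `neutrophils / lymphocytes`.
#' @export
nlr <- function(panel) {
  if (panel$lymphocytes <= 0)
    stop("NLR undefined: lymphocyte count must be positive", call. = FALSE)
  panel$neutrophils / panel$lymphocytes
}

#' Caliper growth record for one tumor
#'
#' @param animal_id,flank tumor identity.
#' @param day measurement days (strictly increasing; day 0 = imaging day).
#' @param width_mm,length_mm caliper series.
#' @return A data.frame of class `growth_record` with derived `volume_mm3`.
#' @export
growth_record <- function(animal_id, flank, day, width_mm, length_mm) {
  if (length(day) < 2L) stop("growth record needs at least two time points", call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  vol <- caliper_volume(width_mm, length_mm)
  structure(data.frame(animal_id = animal_id, flank = flank, day = day,
                       width_mm = pmin(width_mm, length_mm),
                       length_mm = pmax(width_mm, length_mm),
                       volume_mm3 = vol),
            class = c("growth_record", "data.frame"))
}

#' Label the abscopal response from bilateral growth curves
#'
#' The right flank is the irradiated one. Both series are normalized to their
#' first shared day, `r_f(t) = V_f(t) / V_f(t0)`; the animal is labeled
#' abscopal when the non-irradiated (left) flank shows identical or augmented
#' growth delay at the final shared day `T`:
#' `r_left(T) <= r_right(T) * (1 + tol)`. The relative tolerance (default
#' 0.10) operationalizes "identical" growth delay. Series on different day
#' grids are interpolated on log-volume.
#'
#' @param left,right [growth_record()]s for the two flanks.
#' @param tol relative tolerance for "identical" trajectories.
#' @return Logical; `TRUE` = abscopal.
#' @export
label_abscopal <- function(left, right, tol = 0.10) {
  t0 <- max(min(left$day), min(right$day))
  T_ <- min(max(left$day), max(right$day))
  if (!is.finite(t0) || !is.finite(T_) || T_ <= t0)
    stop("growth records lack a shared [first, final] measurement window",
         call. = FALSE)
  traj <- function(g, tt) exp(stats::approx(g$day, log(g$volume_mm3), xout = tt)$y)
  r_left <- traj(left, T_) / traj(left, t0)
  r_right <- traj(right, T_) / traj(right, t0)
  unname(r_left <= r_right * (1 + tol))
}

#' Assemble the tumor-level analysis table
#'
#' Builds two rows per complete animal (one per flank), carrying the CT and
#' MRI feature vectors (prefixed `ct_` / `mri_`), the animal-level NLR and
#' abscopal label (copied to both tumors — imaging features are predictive
#' regardless of which flank was irradiated), and a train/validation split
#' assigned animal-wise so the two tumors of one animal never straddle the
#' split. Incomplete animals are excluded and listed in the `rejected`
#' attribute with a reason.
#'
#' @param animals list of animal records; each needs `animal_id`, `label`
#'   (logical), `cbc` (a [cbc_panel()]), and `features`, a list with entries
#'   `ct_left`, `ct_right`, `mri_left`, `mri_right` (named numeric vectors).
#' @param n_train number of animals assigned to the training split.
#' @param seed seed for the random animal-level split.
#' @param split optional pre-recorded assignment, a data.frame with columns
#'   `animal_id` and `split` (`"train"`/`"validation"`); overrides the random
#'   split.
#' @param stratify keep at least one animal of each label class in each
#'   split (a single-class training arm makes screening and logistic fitting
#'   undefined).
#' @return A data.frame of class `analysis_table`, 2 rows per animal.
#' @export
build_analysis_table <- function(animals, n_train = 6L, seed = 1L,
                                 split = NULL, stratify = TRUE) {
  rejected <- data.frame(animal_id = character(0), reason = character(0))
  keep <- list()
  for (a in animals) {
    reason <- NULL
    if (is.null(a$cbc)) reason <- "missing CBC"
    else if (a$cbc$lymphocytes <= 0) reason <- "NLR undefined (no lymphocytes)"
    else if (is.null(a$label) || is.na(a$label)) reason <- "missing abscopal label"
    else {
      fe <- a$features
      need <- c("ct_left", "ct_right", "mri_left", "mri_right")
      miss <- need[!vapply(need, function(k) !is.null(fe[[k]]), TRUE)]
      if (length(miss)) reason <- paste("missing features:", paste(miss, collapse = ", "))
    }
    if (is.null(reason)) keep[[length(keep) + 1L]] <- a
    else rejected <- rbind(rejected, data.frame(animal_id = a$animal_id, reason = reason))
  }
  if (length(keep) == 0L) stop("no complete animals", call. = FALSE)
  ids <- vapply(keep, function(a) as.character(a$animal_id), "")
  labels <- vapply(keep, function(a) isTRUE(a$label), TRUE)

  if (is.null(split)) {
    assign_split <- with_seed(derive_seed(seed, "split"), {
      tr <- if (stratify && n_train < length(ids) && n_train >= 2 &&
                length(unique(labels)) == 2) {
        pos <- which(labels); neg <- which(!labels)
        n_pos_tr <- max(1L, min(length(pos) - 1L, round(n_train * length(pos) / length(ids))))
        c(sample(pos, n_pos_tr), sample(neg, n_train - n_pos_tr))
      } else sample(seq_along(ids), min(n_train, length(ids)))
      ifelse(seq_along(ids) %in% tr, "train", "validation")
    })
  } else {
    assign_split <- split$split[match(ids, split$animal_id)]
    if (any(is.na(assign_split)))
      stop("split table does not cover all animals", call. = FALSE)
  }

  rows <- list()
  for (q in seq_along(keep)) {
    a <- keep[[q]]
    for (fl in c("left", "right")) {
      ct <- a$features[[paste0("ct_", fl)]]
      mri <- a$features[[paste0("mri_", fl)]]
      row <- data.frame(tumor_id = paste(ids[q], fl, sep = "_"),
                        animal_id = ids[q], flank = fl,
                        nlr = nlr(a$cbc), abscopal = labels[q],
                        split = assign_split[q])
      row <- cbind(row,
                   stats::setNames(as.data.frame(as.list(as.numeric(ct))),
                                   paste0("ct_", names(ct))),
                   stats::setNames(as.data.frame(as.list(as.numeric(mri))),
                                   paste0("mri_", names(mri))))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("analysis_table", "data.frame"), rejected = rejected)
}
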