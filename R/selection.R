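#' Screen features by one-way ANOVA against the abscopal label
#'
#' For each feature a two-group one-way ANOVA F statistic (between over within
#' mean squares, p from the F(1, n-2) distribution — equivalently the squared
#' pooled-variance t statistic) is computed against the dichotomized abscopal
#' label; features are ranked by ascending p. Zero-variance features are
#' dropped with a reason rather than propagating NaN.
#'
#' @param table a data.frame holding the feature columns and the label.
#' @param feature_names columns to screen.
#' @param label logical/0-1 vector, or the name of a column of `table`.
#' @return A data.frame of class `screen_result`, one row per feature, ranked
#'   by ascending p: `feature`, `F`, `p`, `mean_pos`, `mean_neg`, `usable`,
#'   `reason`.
#' @export
anova_screen <- function(table, feature_names, label = "abscopal") {
  if (is.character(label) && length(label) == 1L) label <- table[[label]]
  g <- as.logical(label)
  if (length(unique(g)) < 2L)
    stop("label must contain both classes", call. = FALSE)
  X <- as.matrix(table[, feature_names, drop = FALSE])
  n <- nrow(X); n1 <- sum(g); n0 <- n - n1
  m1 <- colMeans(X[g, , drop = FALSE])
  m0 <- colMeans(X[!g, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((t(t(X[g, , drop = FALSE]) - m1))^2) +
         colSums((t(t(X[!g, , drop = FALSE]) - m0))^2)
  msw <- ssw / (n - 2)
  # no between-group variance => F = 0, p = 1, whatever the within-variance
  Fv <- ifelse(ssb <= .Machine$double.eps * pmax(1, ssw), 0,
               ifelse(msw > 0, ssb / msw, Inf))
  p <- stats::pf(Fv, 1, n - 2, lower.tail = FALSE)
  usable <- apply(X, 2, function(col) stats::sd(col) > 0) & is.finite(Fv)
  reason <- ifelse(usable, "", "zero-variance or undefined")
  out <- data.frame(feature = feature_names, F = Fv, p = p,
                    mean_pos = m1, mean_neg = m0,
                    usable = usable, reason = reason, row.names = NULL)
  out <- out[order(!out$usable, out$p, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"),
            n_pos = n1, n_neg = n0)
}

#' Remove inter-correlated features at a Pearson cutoff
#'
#' Greedy forward pass in ascending-p order: a feature is kept iff its
#' absolute Pearson correlation with every already-kept feature is below the
#' cutoff. This yields the maximal p-ordered admissible prefix set.
#'
#' @param table the data.frame the screen ran on.
#' @param ranked_features feature names in ascending-p order.
#' @param r_cut absolute Pearson correlation cutoff (default 0.5).
#' @return Character vector of kept features, plus a `dropped` attribute
#'   naming, for each dropped feature, the kept feature it correlated with.
#' @export
decorrelate <- function(table, ranked_features, r_cut = 0.5) {
  kept <- character(0)
  dropped <- character(0)
  for (f in ranked_features) {
    conflict <- NULL
    for (k in kept) {
      r <- suppressWarnings(stats::cor(table[[f]], table[[k]]))
      if (is.finite(r) && abs(r) >= r_cut) { conflict <- k; break }
    }
    if (is.null(conflict)) kept <- c(kept, f)
    else dropped[f] <- conflict
  }
  structure(kept, dropped = dropped)
}

#' Select the final feature panel
#'
#' Takes the decorrelated significant features in ascending-p order, capped at
#' `k_max` (3 for CT, 2 for MRI by default, matching the final panel sizes the
#' screening procedure is designed to produce). Ties on p break
#' lexicographically so selection is deterministic. If nothing is significant
#' the panel is empty with a warning and downstream modeling falls back to the
#' blood-count-only model.
#'
#' @param screen a `screen_result` from [anova_screen()].
#' @param table the data.frame the screen ran on (for correlations).
#' @param k_max panel size cap.
#' @param alpha significance gate on the ANOVA p-value.
#' @param r_cut see [decorrelate()].
#' @return Character vector of selected feature names (possibly empty).
#' @export
select_panel <- function(screen, table, k_max = 3L, alpha = 0.05, r_cut = 0.5) {
  sig <- screen$feature[screen$usable & screen$p < alpha]
  if (length(sig) == 0L) {
    warning("no feature passed the significance gate; returning empty panel")
    return(character(0))
  }
  kept <- decorrelate(table, sig, r_cut = r_cut)
  utils::head(as.character(kept), k_max)
}
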