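#' Fit the abscopal-effect prediction model
#'
#' The central estimator of the package: starting from a tumor-level analysis
#' table (see [build_analysis_table()]), it screens each modality's radiomics
#' features by one-way ANOVA against the abscopal label on the training rows,
#' removes inter-correlated features at the |Pearson r| >= 0.5 cutoff, and
#' fits ridge-stabilized binary logistic models — radiomics-only, NLR-only,
#' and combined radiomics + NLR — evaluated by ROC/AUC with untruncated
#' Hanley-McNeil 95% intervals on the training and validation splits.
#'
#' @param table an `analysis_table` (or any data.frame with `ct_*` / `mri_*`
#'   feature columns, `nlr`, logical `abscopal`, and a `split` column).
#' @param modalities which imaging modalities to model.
#' @param alpha ANOVA significance gate.
#' @param r_cut Pearson decorrelation cutoff.
#' @param k_max named panel-size caps per modality.
#' @param lambda ridge penalty for the logistic fits.
#' @return An object of class `abscopal_model`: per-modality `screen`,
#'   `panel`, and `report` (see [evaluate_models()]), plus the table used.
#' @export
abscopal_model <- function(table, modalities = c("ct", "mri"), alpha = 0.05,
                           r_cut = 0.5, k_max = c(ct = 3L, mri = 2L),
                           lambda = 1e-6) {
  stopifnot(all(c("nlr", "abscopal", "split") %in% names(table)))
  train <- table[table$split == "train", , drop = FALSE]
  fits <- list()
  for (mod in modalities) {
    feats <- grep(paste0("^", mod, "_"), names(table), value = TRUE)
    screen <- anova_screen(train, feats)
    panel <- select_panel(screen, train, k_max = k_max[[mod]] %||% 3L,
                          alpha = alpha, r_cut = r_cut)
    report <- evaluate_models(table, panel)
    fits[[mod]] <- list(screen = screen, panel = panel, report = report)
  }
  structure(list(modalities = fits, table = table, alpha = alpha,
                 r_cut = r_cut, k_max = k_max, lambda = lambda,
                 n_train = sum(table$split == "train"),
                 n_validation = sum(table$split == "validation")),
            class = "abscopal_model")
}

#' @export
print.abscopal_model <- function(x, ...) {
  cat(sprintf("Abscopal-effect model: %d training / %d validation tumors\n",
              x$n_train, x$n_validation))
  for (mod in names(x$modalities)) {
    f <- x$modalities[[mod]]
    cat(sprintf("\n[%s] panel: %s\n", toupper(mod),
                if (length(f$panel)) paste(f$panel, collapse = ", ") else "(empty)"))
    print(f$report)
  }
  invisible(x)
}

#' @export
summary.abscopal_model <- function(object, ...) {
  rows <- list()
  for (mod in names(object$modalities)) {
    rep_ <- object$modalities[[mod]]$report
    for (m in names(rep_$roc)) for (s in names(rep_$roc[[m]])) {
      r <- rep_$roc[[m]][[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        modality = toupper(mod), model = m, split = s, auc = r$auc,
        ci_low = r$ci_low, ci_high = r$ci_high,
        n_pos = r$n_pos, n_neg = r$n_neg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("summary.abscopal_model", "data.frame"))
}

#' @export
coef.abscopal_model <- function(object, modality = NULL, model = "combined", ...) {
  modality <- modality %||% names(object$modalities)[1]
  stats::coef(object$modalities[[modality]]$report$models[[model]])
}

#' Predict abscopal probabilities from a fitted abscopal model
#'
#' @param object an `abscopal_model`.
#' @param newdata data.frame with the predictor columns (defaults to the
#'   fitted table's validation rows).
#' @param modality which modality's model to apply.
#' @param model `"combined"`, `"radiomics"`, or `"nlr_only"`.
#' @param ... passed to [predict.logistic_model()].
#' @return Numeric probability scores.
#' @export
predict.abscopal_model <- function(object, newdata = NULL, modality = NULL,
                                   model = "combined", ...) {
  modality <- modality %||% names(object$modalities)[1]
  newdata <- newdata %||%
    object$table[object$table$split == "validation", , drop = FALSE]
  predict(object$modalities[[modality]]$report$models[[model]], newdata, ...)
}

#' Plot ROC curves of a fitted abscopal model
#'
#' Training curves for the three models plus the validation curve of the
#' combined model, one panel per modality.
#'
#' @param x an `abscopal_model`.
#' @param ... unused.
#' @export
plot.abscopal_model <- function(x, ...) {
  mods <- names(x$modalities)
  oldpar <- graphics::par(mfrow = c(1, length(mods)))
  on.exit(graphics::par(oldpar))
  cols <- c(radiomics = "steelblue", nlr_only = "darkorange",
            combined = "firebrick")
  for (mod in mods) {
    rep_ <- x$modalities[[mod]]$report
    first <- TRUE
    leg <- character(0); legcol <- character(0)
    for (m in names(rep_$roc)) {
      r <- rep_$roc[[m]]$train
      plot(r, add = !first, col = cols[[m]], lty = 2,
           main = if (first) toupper(mod) else NULL)
      first <- FALSE
      leg <- c(leg, sprintf("%s train (%.2f)", m, r$auc))
      legcol <- c(legcol, cols[[m]])
      if (m == "combined" && !is.null(rep_$roc[[m]]$validation)) {
        rv <- rep_$roc[[m]]$validation
        plot(rv, add = TRUE, col = "forestgreen")
        leg <- c(leg, sprintf("combined validation (%.2f)", rv$auc))
        legcol <- c(legcol, "forestgreen")
      }
    }
    graphics::legend("bottomright", legend = leg, col = legcol, lwd = 2,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
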