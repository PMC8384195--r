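#' Fit a binary logistic model by ridge-stabilized IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares with a small ridge penalty (default `lambda = 1e-6` on the
#' standardized predictors, intercept unpenalized) and an iteration cap.
#' Predictors are standardized internally using training means/sds. With 12
#' training tumors quasi-separation is common; the ridge keeps coefficients
#' finite while preserving the ordering of the scores (AUC depends only on
#' that ordering), and separation is detected and flagged rather than treated
#' as an error.
#'
#' @param rows data.frame of training rows.
#' @param predictors predictor column names.
#' @param label logical/0-1 response, or the name of a column of `rows`.
#' @param lambda ridge penalty on standardized predictors.
#' @param max_iter IRLS iteration cap.
#' @return An object of class `logistic_model`.
#' @export
fit_logistic <- function(rows, predictors, label = "abscopal",
                         lambda = 1e-6, max_iter = 100L) {
  if (is.character(label) && length(label) == 1L) label <- rows[[label]]
  y <- as.numeric(as.logical(label))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 rows per class", call. = FALSE)
  X <- as.matrix(rows[, predictors, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1 # constant predictor carries no information; leave centered
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  Zi <- cbind(`(Intercept)` = 1, Z)
  p_ <- ncol(Zi)
  pen <- diag(c(0, rep(lambda, p_ - 1L)), p_)
  beta <- rep(0, p_)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Zi %*% beta)
    prob <- stats::plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-12)
    z <- eta + (y - prob) / w
    WZ <- Zi * w
    beta_new <- tryCatch(
      solve(crossprod(Zi, WZ) + pen, crossprod(WZ, z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    dev <- -2 * sum(y * log(pmax(prob, 1e-300)) +
                    (1 - y) * log(pmax(1 - prob, 1e-300)))
    if (max(abs(beta_new - beta)) < 1e-10 || abs(dev_old - dev) < 1e-12) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
    dev_old <- dev
  }
  eta <- drop(Zi %*% beta)
  prob <- stats::plogis(eta)
  dev <- -2 * sum(y * log(pmax(prob, 1e-300)) + (1 - y) * log(pmax(1 - prob, 1e-300)))
  separation <- sqrt(sum(beta[-1]^2)) > 15 || dev < 1e-6
  structure(list(predictors = predictors, coefficients = beta,
                 center = mu, scale = sdv, lambda = lambda,
                 iterations = it, converged = converged || separation,
                 separation = separation, deviance = dev,
                 n = length(y), n_pos = sum(y)),
            class = "logistic_model")
}

#' @export
coef.logistic_model <- function(object, ...) object$coefficients

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d predictors, n = %d (%d positive)%s\n",
              length(x$predictors), x$n, x$n_pos,
              if (x$separation) "  [separated]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict abscopal probability scores
#'
#' @param object a `logistic_model`.
#' @param newdata data.frame containing the predictor columns.
#' @param type `"response"` (probabilities) or `"link"` (linear predictor).
#' @param ... unused.
#' @return Numeric scores; higher score = more likely abscopal.
#' @export
predict.logistic_model <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  eta <- drop(cbind(1, Z) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' ROC curve and AUC with an untruncated Hanley-McNeil interval
#'
#' AUC is the Mann-Whitney probability estimate (ties credited 1/2); the curve
#' is a threshold sweep from (0,0) to (1,1). The 95% confidence interval is
#' `AUC +/- 1.96 * SE` with the Hanley-McNeil closed-form standard error and
#' is deliberately not truncated to [0,1].
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical/0-1 class labels.
#' @param conf_z normal quantile for the CI (1.96 for 95%).
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `fpr`, `tpr`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_z = 1.96) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep on descending unique scores
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t) / n_neg, 0)
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
             (n_pos * n_neg))
  structure(list(auc = auc, se = se, ci_low = A - conf_z * se,
                 ci_high = A + conf_z * se, fpr = fpr, tpr = tpr,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI: %.2f to %.2f; %d pos / %d neg)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ..., add = FALSE, col = "steelblue") {
  if (!add) {
    plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1), col = col,
         xlab = "False positive rate", ylab = "True positive rate", ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else graphics::lines(x$fpr, x$tpr, type = "s", col = col, ...)
  invisible(x)
}

#' Fit and evaluate the three models for one modality
#'
#' Fits radiomics-only, NLR-only, and combined (radiomics + NLR) logistic
#' models on the training rows and evaluates ROC/AUC on both splits. The
#' combined model on the validation split is the headline result; the other
#' validation curves are retained for comparisons. With an empty radiomics
#' panel the radiomics-only model is skipped with a warning and the combined
#' model reduces to NLR-only.
#'
#' @param table an analysis table (see [build_analysis_table()]) with a
#'   `split` column.
#' @param panel character vector of radiomics feature columns for this
#'   modality.
#' @param nlr_col name of the blood-count ratio column.
#' @return A list of class `model_report`: `models` (logistic fits) and `roc`
#'   (nested list `roc[[model]][[split]]` of [roc_auc()] results).
#' @export
evaluate_models <- function(table, panel, nlr_col = "nlr") {
  train <- table[table$split == "train", , drop = FALSE]
  valid <- table[table$split == "validation", , drop = FALSE]
  specs <- list(nlr_only = nlr_col)
  if (length(panel) > 0L) {
    specs$radiomics <- panel
    specs$combined <- c(panel, nlr_col)
  } else {
    warning("empty radiomics panel: radiomics-only model skipped; combined model reduces to NLR-only")
    specs$combined <- nlr_col
  }
  models <- lapply(specs, function(pr) fit_logistic(train, pr))
  roc <- lapply(models, function(m) {
    out <- list(train = roc_auc(predict(m, train), train$abscopal))
    if (nrow(valid) > 0L && length(unique(valid$abscopal)) == 2L)
      out$validation <- roc_auc(predict(m, valid), valid$abscopal)
    out
  })
  structure(list(models = models, roc = roc,
                 n_train = nrow(train), n_validation = nrow(valid)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %d training / %d validation tumors\n",
              x$n_train, x$n_validation))
  for (m in names(x$roc)) for (s in names(x$roc[[m]])) {
    r <- x$roc[[m]][[s]]
    cat(sprintf("  %-10s %-11s AUC %.3f (95%% CI %.2f to %.2f)\n",
                m, s, r$auc, r$ci_low, r$ci_high))
  }
  invisible(x)
}
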