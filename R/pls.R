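#' Fit a PLS1 regression model
#'
#' NIPALS PLS1 with deflation on mean-centered data: the spectrum matrix is
#' decomposed as `X = T P' + E` and the response as `y = T q' + f`; the
#' latent scores `T` are built from covariance-maximising weight vectors.
#' The regression coefficient vector `b` (centered space) reproduces the
#' score-space predictions exactly.
#'
#' @param Xc centered calibration matrix (n x p).
#' @param yc centered calibration response (length n).
#' @param n_lv number of latent variables requested
#'   (`1 <= n_lv <= min(n - 1, p)`). If the residual rank is exhausted
#'   earlier, the achieved number is reported in `n_lv` of the result.
#' @param centering optional `centering_transform` recorded on the model so
#'   [predict.pls_model()] can take raw spectra; defaults to a no-op
#'   (all-zero means), i.e. the model lives in centered space.
#' @return Object of class `pls_model`: `scores_T`, `loadings_P`,
#'   `y_loadings_q`, `weights_W`, `coef_b` (coefficients at `n_lv`),
#'   `coef_path` (p x n_lv cumulative coefficients), `n_lv`, `centering`.
#' @export
fit_pls <- function(Xc, yc, n_lv, centering = NULL) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc); p <- ncol(Xc)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1) stop_ss("n_lv must be >= 1")
  if (n_lv > min(n - 1, p))
    stop_ss("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1, p))
  if (length(yc) != n) stop_ss("X and y dimensions disagree")
  fit <- .cpp_pls1(Xc, as.numeric(yc), n_lv)
  if (fit$ncomp == 0)
    stop_ss("first weight vector has zero norm (X'y = 0): no signal to fit")
  if (is.null(centering))
    centering <- structure(list(x_means = numeric(p), y_mean = 0),
                           class = "centering_transform")
  structure(
    list(scores_T = fit$T, loadings_P = fit$P,
         y_loadings_q = as.numeric(fit$q), weights_W = fit$W,
         coef_b = as.numeric(fit$B[, fit$ncomp]), coef_path = fit$B,
         n_lv = fit$ncomp, centering = centering),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", length(x$coef_b), "channels,", x$n_lv,
      "latent variable(s)\n")
  invisible(x)
}

#' Predict from a PLS model
#'
#' Applies the model's centering to raw spectra, multiplies by the
#' regression vector and adds the calibration response mean back.
#'
#' @param object a `pls_model`.
#' @param X raw spectra (matrix with the model's channel count).
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$coef_b))
    stop_ss("X has ", ncol(X), " channels but the model expects ",
            length(object$coef_b))
  Xc <- sweep(X, 2, object$centering$x_means)
  as.numeric(Xc %*% object$coef_b) + object$centering$y_mean
}

#' k-fold cross-validation for latent-variable selection
#'
#' Folds are a seeded random permutation cut into near-equal contiguous
#' blocks. Centering is re-estimated inside each training fold. RMSECV per
#' candidate number of latent variables is computed from the pooled
#' out-of-fold residuals; the chosen count minimises RMSECV, smallest
#' count on ties (parsimony).
#'
#' @param X raw (uncentered) calibration spectra.
#' @param y calibration response.
#' @param k number of folds (default 5).
#' @param max_nlv largest candidate count (default 10); silently capped at
#'   the smallest training-fold capacity `min(n_train - 1, p)`.
#' @param seed RNG seed for the fold permutation.
#' @param foldid optional explicit 1-based fold labels overriding the
#'   seeded construction (used to pair comparisons across subsets).
#' @return Object of class `cv_result`: `rmsecv_by_nlv`, `chosen_nlv`,
#'   `cv_predictions` (out-of-fold, at the chosen count), `q2_cv`,
#'   `fold_assignment`.
#' @export
kfold_cv <- function(X, y, k = 5, max_nlv = 10, seed = NULL, foldid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(foldid)) foldid <- make_folds(n, k, seed)
  stopifnot(length(foldid) == n)
  k <- max(foldid)
  ntr_min <- n - max(tabulate(foldid, k))
  Amax <- min(max_nlv, ntr_min - 1, ncol(X))
  if (Amax < 1) stop_ss("folds too small for even one latent variable")
  oof <- .cpp_cv_oof(X, as.numeric(y), as.integer(foldid), Amax)
  rmsecv <- sqrt(colMeans((y - oof)^2))
  chosen <- which.min(rmsecv)  # first minimum: lowest count wins ties
  structure(
    list(rmsecv_by_nlv = as.numeric(rmsecv), chosen_nlv = as.integer(chosen),
         cv_predictions = as.numeric(oof[, chosen]),
         q2_cv = q2(y, oof[, chosen]),
         fold_assignment = as.integer(foldid)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$chosen_nlv, "latent variable(s), RMSECV =",
      format(x$rmsecv_by_nlv[x$chosen_nlv], digits = 5), "\n")
  invisible(x)
}

#' Root-mean-square error
#'
#' `sqrt(sum((y - yhat)^2) / n)` — the RMSEC/RMSEP formula (note the
#' plain `n` denominator, not `n - 1`).
#'
#' @param y reference values.
#' @param yhat predictions.
#' @return Non-negative scalar in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1)
    stop_ss("y and yhat must have equal positive length")
  sqrt(mean((y - yhat)^2))
}

#' Q-squared (predictive coefficient of determination)
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Equals 1 for perfect
#' prediction, 0 for the mean predictor, and may be negative.
#'
#' @param y reference values (length >= 2, non-constant).
#' @param yhat predictions.
#' @return Scalar `<= 1`.
#' @export
q2 <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop_ss("y and yhat must have equal length >= 2")
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop_ss("q2 is undefined for a constant reference vector")
  1 - sum((y - yhat)^2) / ss
}

#' Sample standard deviation over repeated runs
#'
#' The `n - 1` denominator form used to summarise robustness across
#' stochastic repeats.
#'
#' @param values numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
sd_over_runs <- function(values) {
  if (length(values) < 2)
    stop_ss("need at least 2 values for a standard deviation")
  stats::sd(values)
}
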