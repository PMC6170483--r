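#' Evaluate a channel subset by the full calibration protocol
#'
#' Restricts the spectra to `indices`, chooses the latent-variable count
#' by k-fold cross-validation on the calibration block, fits the final
#' PLS model on all calibration samples, and reports calibration,
#' cross-validation and independent-test metrics. `Q2_cv` uses the
#' pooled out-of-fold predictions; `RMSEC` uses the refitted calibration
#' predictions; `RMSEP` and `Q2_test` come from the untouched test set.
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result`.
#' @param indices channel indices to use (default: all).
#' @param cv_folds folds (default 5).
#' @param max_nlv cap on latent variables (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return List with `metrics` (`rmsec`, `rmsep`, `q2_cv`, `q2_test`),
#'   `n_lv`, `n_var`, the fitted `model` and the `cv` result.
#' @export
evaluate_model <- function(ds, split, indices = NULL, cv_folds = 5,
                           max_nlv = 10, seed = 1) {
  validate_dataset(ds)
  validate_split(split, nrow(ds$X))
  if (is.null(indices)) indices <- seq_len(ncol(ds$X))
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1) stop_ss("indices must be non-empty")
  if (any(indices < 1) || any(indices > ncol(ds$X)))
    stop_ss("channel indices out of range")
  X <- ds$X[, indices, drop = FALSE]
  cal <- split$cal_indices; tst <- split$test_indices
  Xcal <- X[cal, , drop = FALSE]; ycal <- ds$y[cal]
  cv <- kfold_cv(Xcal, ycal, k = cv_folds, max_nlv = max_nlv, seed = seed)
  xm <- colMeans(Xcal); ym <- mean(ycal)
  ct <- structure(list(x_means = xm, y_mean = ym),
                  class = "centering_transform")
  model <- fit_pls(sweep(Xcal, 2, xm), ycal - ym, cv$chosen_nlv,
                   centering = ct)
  yhat_cal <- predict(model, Xcal)
  yhat_tst <- predict(model, X[tst, , drop = FALSE])
  list(metrics = list(rmsec = rmse(ycal, yhat_cal),
                      rmsep = rmse(ds$y[tst], yhat_tst),
                      q2_cv = cv$q2_cv,
                      q2_test = q2(ds$y[tst], yhat_tst)),
       n_lv = model$n_lv, n_var = length(indices),
       model = model, cv = cv)
}

selector_fun <- function(method) {
  switch(method,
         mcuve = select_mcuve, cars = select_cars,
         boss = select_boss, vcpa = select_vcpa,
         stop_ss("unknown method '", method, "'"))
}

#' Repeated-evaluation benchmark of wavelength-selection methods
#'
#' The study protocol: a single deterministic Kennard-Stone split, then
#' each stochastic selector is re-run `repeats` times with seed
#' `base_seed + repeat`, re-choosing the latent-variable count each
#' time, and the per-method mean and sample SD (n - 1 denominator) of
#' nVAR, nLV, Q2_cv, Q2_test, RMSEC and RMSEP are reported. The
#' full-spectrum PLS row (`"pls"`) is deterministic: its metric SDs are
#' zero and its nVAR has no SD.
#'
#' @param ds a [spectral_dataset()].
#' @param methods subset of `c("pls", "mcuve", "cars", "boss", "vcpa")`.
#' @param repeats stochastic repeats (>= 2; 50 in the reference
#'   protocol).
#' @param base_seed seed; repeat `r` uses `base_seed + r`.
#' @param n_cal calibration-set size for the Kennard-Stone split.
#' @param cv_folds folds (default 5).
#' @param max_nlv cap on latent variables (default 10).
#' @param method_args named list of per-method argument lists passed to
#'   the selectors (e.g. `list(mcuve = list(n_runs = 200))`).
#' @return Object of class `benchmark_report`: a data frame with one row
#'   per method and `<metric>_mean` / `<metric>_sd` columns, plus
#'   attributes `repeats`, `base_seed`, `split` and `per_repeat` (the
#'   raw per-repeat values). Failed repeats are excluded from the
#'   summaries and counted in `n_failed`.
#' @export
run_benchmark <- function(ds, methods = c("pls", "mcuve", "cars", "boss",
                                          "vcpa"),
                          repeats = 50, base_seed = 1,
                          n_cal = round(0.61 * nrow(ds$X)), cv_folds = 5,
                          max_nlv = 10, method_args = list()) {
  if (repeats < 2) stop_ss("repeats must be >= 2 for SDs")
  methods <- match.arg(methods, several.ok = TRUE)
  split <- kennard_stone_split(ds, n_cal)
  metrics <- c("nvar", "nlv", "q2_cv", "q2_test", "rmsec", "rmsep")
  per_repeat <- list()
  rows <- list()
  for (m in methods) {
    if (m == "pls") {
      ev <- evaluate_model(ds, split, cv_folds = cv_folds,
                           max_nlv = max_nlv, seed = base_seed)
      vals <- c(nvar = ev$n_var, nlv = ev$n_lv,
                q2_cv = ev$metrics$q2_cv, q2_test = ev$metrics$q2_test,
                rmsec = ev$metrics$rmsec, rmsep = ev$metrics$rmsep)
      row <- c(rbind(vals, 0))
      names(row) <- paste0(rep(metrics, each = 2), c("_mean", "_sd"))
      row["nvar_sd"] <- NA_real_  # nVAR is the constant p
      rows[[m]] <- c(row, n_failed = 0)
      per_repeat[[m]] <- as.data.frame(t(vals))
    } else {
      recs <- vector("list", repeats)
      for (r in seq_len(repeats)) {
        seed_r <- base_seed + r
        recs[[r]] <- tryCatch({
          sel <- do.call(selector_fun(m),
                         c(list(ds = ds, split = split,
                                cv_folds = cv_folds, max_nlv = max_nlv,
                                seed = seed_r),
                           method_args[[m]]))
          ev <- evaluate_model(ds, split, sel$selected_indices,
                               cv_folds = cv_folds, max_nlv = max_nlv,
                               seed = seed_r)
          data.frame(nvar = ev$n_var, nlv = ev$n_lv,
                     q2_cv = ev$metrics$q2_cv,
                     q2_test = ev$metrics$q2_test,
                     rmsec = ev$metrics$rmsec, rmsep = ev$metrics$rmsep)
        }, error = function(e) NULL)
      }
      ok <- !vapply(recs, is.null, logical(1))
      if (sum(ok) < 2)
        stop_ss("method '", m, "' failed in all but ", sum(ok), " repeats")
      df <- do.call(rbind, recs[ok])
      row <- numeric(0)
      for (met in metrics)
        row <- c(row, stats::setNames(
          c(mean(df[[met]]), sd_over_runs(df[[met]])),
          paste0(met, c("_mean", "_sd"))))
      rows[[m]] <- c(row, n_failed = sum(!ok))
      per_repeat[[m]] <- df
    }
  }
  report <- cbind(data.frame(method = methods),
                  as.data.frame(do.call(rbind, rows[methods])))
  rownames(report) <- NULL
  structure(report, class = c("benchmark_report", "data.frame"),
            repeats = repeats, base_seed = base_seed, split = split,
            per_repeat = per_repeat)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", attr(x, "repeats"), "repeats, base seed",
      attr(x, "base_seed"), "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 5))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write / read a benchmark report as CSV
#'
#' @param report a `benchmark_report`.
#' @param path file path.
#' @return `write_report` returns `path` invisibly; `read_report`
#'   returns the report data frame (summary columns only — the
#'   per-repeat attribute is not serialised).
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
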