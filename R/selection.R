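# Shared constructor for the result object returned by all four
# wavelength-selection methods.

new_selection_result <- function(method, selected, n_lv, rmsecv,
                                 diagnostics = NULL) {
  selected <- sort(as.integer(selected))
  if (length(selected) < 1 || anyDuplicated(selected))
    stop_ss("selection must be a non-empty set of unique channel indices")
  structure(
    list(method = method, selected_indices = selected,
         n_lv = as.integer(n_lv), rmsecv = as.numeric(rmsecv),
         diagnostics = diagnostics),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]: ", length(x$selected_indices),
      " channels, ", x$n_lv, " latent variable(s), RMSECV = ",
      format(x$rmsecv, digits = 5), "\n", sep = "")
  invisible(x)
}

# Calibration block + one shared seeded fold assignment, drawn from the
# current RNG stream (callers wrap in with_seed).
cal_block <- function(ds, split, cv_folds) {
  validate_dataset(ds)
  validate_split(split, nrow(ds$X))
  X <- ds$X[split$cal_indices, , drop = FALSE]
  y <- ds$y[split$cal_indices]
  list(X = X, y = y, foldid = make_folds(nrow(X), cv_folds))
}
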