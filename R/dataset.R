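#' Construct a spectral dataset
#'
#' Bundles a sample-by-channel intensity matrix, its channel axis
#' (wavelength in nm or Raman shift in cm^-1), and the reference response
#' (iodine value, g I2 / 100 g oil) into a validated container.
#'
#' @param X numeric matrix, `n` samples by `p` channels; no missing values.
#' @param axis numeric vector of length `p`, strictly monotone channel
#'   positions.
#' @param y numeric response vector of length `n`.
#' @param instrument_label free-text instrument tag.
#' @param sample_ids unique sample labels; defaults to `"S1" ... "Sn"`.
#' @return An object of class `spectral_dataset` with elements `X`, `axis`,
#'   `y`, `instrument_label`, `sample_ids`.
#' @examples
#' ds <- spectral_dataset(matrix(rnorm(12), 3, 4), axis = c(900, 950, 1000, 1050),
#'                        y = c(90, 100, 110))
#' ds
#' @export
spectral_dataset <- function(X, axis, y, instrument_label = "unknown",
                             sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  ds <- structure(
    list(X = X, axis = as.numeric(axis), y = as.numeric(y),
         instrument_label = as.character(instrument_label)[1],
         sample_ids = as.character(sample_ids)),
    class = "spectral_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  X <- ds$X
  if (nrow(X) < 2 || ncol(X) < 2)
    stop_ss("dataset needs at least 2 samples and 2 channels")
  if (anyNA(X) || any(!is.finite(X)))
    stop_ss("X contains missing or non-finite values")
  if (anyNA(ds$y) || any(!is.finite(ds$y)))
    stop_ss("y contains missing or non-finite values")
  if (length(ds$y) != nrow(X))
    stop_ss("length of y (", length(ds$y), ") does not match rows of X (",
            nrow(X), ")")
  if (length(ds$axis) != ncol(X))
    stop_ss("length of axis (", length(ds$axis), ") does not match columns",
            " of X (", ncol(X), ")")
  d <- diff(ds$axis)
  if (!(all(d > 0) || all(d < 0)))
    stop_ss("channel axis must be strictly increasing or strictly decreasing")
  if (anyDuplicated(ds$sample_ids))
    stop_ss("duplicate sample ids: ",
            paste(unique(ds$sample_ids[duplicated(ds$sample_ids)]),
                  collapse = ", "))
  if (length(ds$sample_ids) != nrow(X))
    stop_ss("sample_ids length does not match rows of X")
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("spectral_dataset:", nrow(x$X), "samples x", ncol(x$X), "channels\n")
  cat("  instrument:", x$instrument_label, "\n")
  cat(sprintf("  axis: %g .. %g\n", x$axis[1], x$axis[length(x$axis)]))
  cat(sprintf("  response (IV): %.2f .. %.2f\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

#' Read a spectral dataset from delimited text
#'
#' Expects the package's CSV dialect: a leading sample-id column, one
#' numeric column per channel whose header is the channel position, and a
#' trailing response column (default name `"IV"`). Decimal point `"."`,
#' UTF-8, comma separated.
#'
#' @param path file path.
#' @param response_column name of the response column (default `"IV"`).
#' @param instrument_label instrument tag to attach.
#' @return A [spectral_dataset()].
#' @seealso [write_dataset()] which emits the same dialect.
#' @export
read_dataset <- function(path, response_column = "IV",
                         instrument_label = "unknown") {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 4)
    stop_ss("file must have a sample-id column, >= 2 channel columns and a ",
            "response column")
  cn <- colnames(raw)
  if (!response_column %in% cn)
    stop_ss("response column '", response_column, "' not found")
  rc <- which(cn == response_column)
  chan_cols <- setdiff(seq_along(cn)[-1], rc)
  axis <- suppressWarnings(as.numeric(cn[chan_cols]))
  if (anyNA(axis))
    stop_ss("channel headers are not numeric positions: ",
            paste(cn[chan_cols][is.na(axis)], collapse = ", "))
  parse_num <- function(txt, colname) {
    bad <- !nzchar(trimws(txt))
    if (any(bad))
      stop_ss("empty cell at row ", which(bad)[1], ", column '", colname, "'")
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v))
      stop_ss("non-numeric cell at row ", which(is.na(v))[1], ", column '",
              colname, "': '", txt[which(is.na(v))[1]], "'")
    v
  }
  X <- vapply(chan_cols, function(j) parse_num(raw[[j]], cn[j]),
              numeric(nrow(raw)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(raw))
  y <- parse_num(raw[[rc]], response_column)
  spectral_dataset(X, axis = axis, y = y,
                   instrument_label = instrument_label,
                   sample_ids = raw[[1]])
}

#' Write a spectral dataset as delimited text
#'
#' Emits the dialect read by [read_dataset()]; reading the file back
#' reproduces `X`, `axis` and `y` exactly for finite decimal inputs.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file path.
#' @param response_column header for the response column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, response_column = "IV") {
  validate_dataset(ds)
  df <- data.frame(sample_id = ds$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(ds$axis))
    df[[as.character(ds$axis[j])]] <- as.character(ds$X[, j])
  df[[response_column]] <- as.character(ds$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a dataset to a subset of channels
#'
#' @param ds a [spectral_dataset()].
#' @param channels integer channel indices (kept in the given order must be
#'   monotone in the axis; duplicates are not allowed).
#' @return A [spectral_dataset()] on the selected channels.
#' @export
subset_channels <- function(ds, channels) {
  channels <- as.integer(channels)
  if (length(channels) < 2)
    stop_ss("need at least 2 channels")
  if (anyDuplicated(channels) || any(channels < 1) ||
      any(channels > ncol(ds$X)))
    stop_ss("invalid channel indices")
  channels <- sort(channels)
  spectral_dataset(ds$X[, channels, drop = FALSE], ds$axis[channels], ds$y,
                   ds$instrument_label, ds$sample_ids)
}

#' Kennard-Stone calibration/test split
#'
#' Deterministic max-min-distance sample selection: the pair of samples at
#' maximal Euclidean distance in spectral space seeds the calibration set;
#' each further calibration sample maximises its minimum distance to the
#' samples already selected. Ties are broken by the lowest sample index,
#' so the split is fully deterministic.
#'
#' Distances are computed on the raw (uncentered) spectra.
#'
#' @param ds a [spectral_dataset()].
#' @param n_cal number of calibration samples (`2 <= n_cal <= n`). The
#'   default keeps ~61% of samples for calibration (a 36/23 style split).
#' @return An object of class `split_result` with ordered integer vectors
#'   `cal_indices` (selection order) and `test_indices` (ascending).
#' @examples
#' ds <- spectral_dataset(matrix(c(0, 1, 10, 0, 1, 10), 3, 2),
#'                        axis = c(1, 2), y = c(0, 1, 10))
#' kennard_stone_split(ds, 2)$cal_indices  # the extreme pair: 1 and 3
#' @export
kennard_stone_split <- function(ds, n_cal = round(0.61 * nrow(ds$X))) {
  validate_dataset(ds)
  n <- nrow(ds$X)
  n_cal <- as.integer(n_cal)
  if (n_cal < 2 || n_cal > n)
    stop_ss("n_cal must be between 2 and n = ", n)
  D <- as.matrix(stats::dist(ds$X))
  # Seed: max-distance pair, lowest indices on ties (row-major scan order).
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  mind <- pmin(D[, best[1]], D[, best[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)  # first maximum -> lowest index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(cal_indices = as.integer(sel),
                 test_indices = setdiff(seq_len(n), sel)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("split_result:", length(x$cal_indices), "calibration /",
      length(x$test_indices), "test samples\n")
  invisible(x)
}

validate_split <- function(split, n) {
  idx <- c(split$cal_indices, split$test_indices)
  if (length(split$cal_indices) < 2)
    stop_ss("calibration set needs >= 2 samples")
  if (anyDuplicated(idx) || !setequal(idx, seq_len(n)))
    stop_ss("split indices must partition the samples exactly once")
  invisible(split)
}

#' Mean-center calibration and test blocks
#'
#' Column means and the response mean are estimated on the calibration
#' rows only and applied to both blocks, as done before every model fit.
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result` for `ds`.
#' @return A list with centered blocks `X_cal`, `X_test`, `y_cal`,
#'   `y_test` and the `centering` transform (`x_means`, `y_mean`).
#' @export
mean_center <- function(ds, split) {
  validate_dataset(ds)
  validate_split(split, nrow(ds$X))
  cal <- split$cal_indices
  tst <- split$test_indices
  xm <- colMeans(ds$X[cal, , drop = FALSE])
  ym <- mean(ds$y[cal])
  ct <- structure(list(x_means = xm, y_mean = ym),
                  class = "centering_transform")
  list(
    X_cal = sweep(ds$X[cal, , drop = FALSE], 2, xm),
    X_test = sweep(ds$X[tst, , drop = FALSE], 2, xm),
    y_cal = ds$y[cal] - ym,
    y_test = ds$y[tst] - ym,
    centering = ct)
}
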