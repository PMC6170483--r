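# Independent oracles and small fixtures shared across the suite.

# Brute-force Kennard-Stone: literal greedy max-min selection written
# independently of the package implementation (plain loops, no distance
# matrix caching tricks beyond dist()).
ks_reference <- function(X, n_cal) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  sel <- integer(0)
  # seed pair: max distance, scanning i < j so the lowest pair wins ties
  best <- c(1L, 2L); bd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# Least-squares coefficients on centered data.
ols_coef <- function(Xc, yc) qr.solve(Xc, yc)

# A small well-conditioned regression dataset wrapped as a
# spectral_dataset, with y an exact linear function of 2 channels plus
# optional noise.
toy_dataset <- function(n = 24, p = 10, noise = 0.05, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- 100 + 3 * X[, 2] - 2 * X[, min(5, p)] + rnorm(n, 0, noise)
  spectral_dataset(X, axis = seq_len(p), y = y)
}

# A fast planted fixture for module-level selector tests (smaller than
# the acceptance fixture).
small_planted <- function(seed = 1, p = 50) {
  planted_dataset(n = 40, p = p, n_informative = 5, seed = seed)
}

expect_selection_valid <- function(sel, p, method = NULL) {
  expect_s3_class(sel, "selection_result")
  expect_true(length(sel$selected_indices) >= 1)
  expect_false(anyDuplicated(sel$selected_indices) > 0)
  expect_true(all(sel$selected_indices >= 1 & sel$selected_indices <= p))
  if (!is.null(method)) expect_identical(sel$method, method)
}
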