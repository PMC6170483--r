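#' Append artificial noise channels
#'
#' Adds columns of uniform noise to a spectrum matrix. The artificial
#' channels calibrate the elimination cutoff in MCUVE: any real channel
#' whose stability does not exceed the best artificial one is treated as
#' uninformative.
#'
#' @param X spectrum matrix (calibration block).
#' @param p_artif number of artificial channels (>= 1); the classic
#'   convention is one per real channel.
#' @param amplitude noise half-range as a fraction of the median column
#'   standard deviation of `X` (> 0).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with `X_aug` (the augmented matrix) and `artificial_idx`
#'   (column indices of the appended block).
#' @export
append_noise_variables <- function(X, p_artif = ncol(X), amplitude = 1e-3,
                                   seed = NULL) {
  X <- as.matrix(X)
  if (p_artif < 1) stop_ss("p_artif must be >= 1")
  if (amplitude <= 0) stop_ss("amplitude must be > 0")
  s <- stats::median(apply(X, 2, stats::sd))
  noise <- with_seed(seed,
    matrix(stats::runif(nrow(X) * p_artif, -1, 1), nrow(X)) * amplitude * s)
  list(X_aug = cbind(X, noise),
       artificial_idx = ncol(X) + seq_len(p_artif))
}

#' Monte Carlo coefficient-stability profile
#'
#' Repeatedly fits PLS on random subsamples of the calibration rows and
#' summarises each channel's regression coefficient stream as
#' `c_j = mean(b_j) / sd(b_j)` (sample SD, `N - 1` denominator). Large
#' `|c_j|` marks channels whose contribution is consistent across
#' resamples.
#'
#' @param X_aug matrix of real plus (optionally) artificial channels.
#' @param y calibration response.
#' @param n_runs number of Monte Carlo fits `N` (>= 2; 500 in the
#'   reference protocol).
#' @param frac fraction of rows drawn (without replacement) per run.
#' @param n_lv latent variables used in every run (fixed so all
#'   coefficient vectors live in one model space).
#' @param artificial_idx column indices of artificial channels (may be
#'   empty).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return Object of class `stability_profile`: `c_real`, `c_artif`,
#'   `n_runs`, `samples_per_run`.
#' @export
compute_stability <- function(X_aug, y, n_runs = 500, frac = 0.8, n_lv,
                              artificial_idx = integer(0), seed = NULL) {
  X_aug <- as.matrix(X_aug)
  n <- nrow(X_aug)
  if (n_runs < 2) stop_ss("n_runs must be >= 2 (the SD needs N - 1 >= 1)")
  M <- as.integer(round_half_up(frac * n))
  if (M < n_lv + 1)
    stop_ss("sampling fraction too small: M = ", M, " rows cannot support ",
            n_lv, " latent variable(s)")
  rows <- with_seed(seed, t(replicate(n_runs, sample.int(n, M))))
  coefs <- .cpp_mc_coefs(X_aug, as.numeric(y), rows, as.integer(n_lv))
  mu <- colMeans(coefs)
  sdv <- apply(coefs, 2, stats::sd)
  if (any(sdv == 0))
    stop_ss("zero coefficient variance across runs for channel(s) ",
            paste(utils::head(which(sdv == 0), 5), collapse = ", "))
  cstab <- mu / sdv
  real_idx <- setdiff(seq_len(ncol(X_aug)), artificial_idx)
  structure(list(c_real = cstab[real_idx], c_artif = cstab[artificial_idx],
                 n_runs = n_runs, samples_per_run = M),
            class = "stability_profile")
}

#' Monte Carlo uninformative variable elimination (MCUVE)
#'
#' Ranks channels by the stability of their PLS regression coefficients
#' over Monte Carlo subsamples, eliminates those no more stable than the
#' best appended artificial noise channel, and picks the best-performing
#' prefix of the stability ranking by cross-validation:
#'
#' 1. choose the full-spectrum latent-variable count by k-fold CV;
#' 2. append `n_artificial` noise channels and compute the stability
#'    profile over `n_runs` subsample fits;
#' 3. discard real channels with `|c| < max |c_artif|`;
#' 4. rank survivors by `|c|` (descending) and evaluate every prefix of
#'    the ranking by k-fold RMSECV, re-choosing the latent-variable count
#'    per prefix;
#' 5. return the prefix with the lowest RMSECV.
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result`; only calibration rows are used.
#' @param n_runs Monte Carlo runs (default 500).
#' @param sample_fraction rows drawn per run (default 0.8).
#' @param n_artificial artificial channels (default: one per real channel).
#' @param noise_amplitude artificial noise amplitude relative to the
#'   median channel SD (default 1e-3).
#' @param cv_folds folds for every cross-validation (default 5).
#' @param max_nlv cap on candidate latent variables (default 10).
#' @param seed RNG seed driving all randomness in the call.
#' @return A `selection_result`; `diagnostics` carries the
#'   `stability_profile`, the cutoff, the ranked survivor list and the
#'   per-prefix RMSECV trajectory.
#' @export
select_mcuve <- function(ds, split, n_runs = 500, sample_fraction = 0.8,
                         n_artificial = NULL, noise_amplitude = 1e-3,
                         cv_folds = 5, max_nlv = 10, seed = 1) {
  with_seed(seed, {
    cb <- cal_block(ds, split, cv_folds)
    p <- ncol(cb$X)
    if (is.null(n_artificial)) n_artificial <- p
    # Latent-variable count for the stability runs: the full-spectrum
    # CV choice, so every Monte Carlo coefficient vector shares a model
    # space.
    full_cv <- kfold_cv(cb$X, cb$y, foldid = cb$foldid, max_nlv = max_nlv)
    aug <- append_noise_variables(cb$X, n_artificial, noise_amplitude)
    prof <- compute_stability(aug$X_aug, cb$y, n_runs = n_runs,
                              frac = sample_fraction,
                              n_lv = full_cv$chosen_nlv,
                              artificial_idx = aug$artificial_idx)
    cutoff <- max(abs(prof$c_artif))
    survivors <- which(abs(prof$c_real) >= cutoff)
    if (length(survivors) == 0)
      stop_ss("all channels eliminated by the artificial-noise cutoff; ",
              "lower noise_amplitude")
    ranked <- survivors[order(-abs(prof$c_real[survivors]), survivors)]
    prefixes <- lapply(seq_along(ranked), function(k) ranked[seq_len(k)])
    res <- .cpp_cv_subsets(cb$X, cb$y, cb$foldid, prefixes, max_nlv)
    best <- which.min(res[, 1])
    new_selection_result(
      "MCUVE", ranked[seq_len(best)], res[best, 2], res[best, 1],
      diagnostics = list(
        stability = prof, cutoff = cutoff, ranked_survivors = ranked,
        prefix_rmsecv = res[, 1], full_spectrum_nlv = full_cv$chosen_nlv,
        foldid = cb$foldid))
  })
}
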