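#' Exponentially decreasing retention schedule (EDF)
#'
#' The fraction of channels retained at sampling run `i` is
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2) / (N-1)`. Algebraically `r_1 = 1` (all channels kept on
#' the first run) and `r_N = 2/p` (two channels at the last).
#'
#' @param p initial channel count (>= 3).
#' @param N number of sampling runs (>= 2).
#' @return Object of class `edf_schedule`: constants `a`, `k`, the
#'   ratio vector `ratios` (length `N`), `p` and `N`.
#' @examples
#' s <- edf_schedule(p = 200, N = 3)
#' s$ratios  # 1, 0.1, 0.01
#' @export
edf_schedule <- function(p, N) {
  if (p < 3) stop_ss("p must be >= 3 (the final ratio 2/p needs p > 2)")
  if (N < 2) stop_ss("N must be >= 2")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  structure(list(a = a, k = k, ratios = a * exp(-k * seq_len(N)),
                 p = as.integer(p), N = as.integer(N)),
            class = "edf_schedule")
}

#' Adaptive reweighted sampling (ARS)
#'
#' Draws channel indices with replacement, with probability proportional
#' to the given weights, and returns the unique set. Channels with large
#' weights almost surely survive while low-weight channels may vanish —
#' the "survival of the fittest" step of CARS.
#'
#' @param weights non-negative weights (not all zero).
#' @param draws number of with-replacement draws.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return Sorted unique integer indices into `weights`.
#' @export
ars_sample <- function(weights, draws, seed = NULL) {
  if (any(weights < 0)) stop_ss("weights must be non-negative")
  if (all(weights == 0)) stop_ss("weights must not be all zero")
  picked <- with_seed(seed,
    sample.int(length(weights), draws, replace = TRUE, prob = weights))
  sort(unique(picked))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Alternates forced exponential shrinkage of the channel set with
#' coefficient-weighted competitive resampling. Per sampling run `i`:
#'
#' 1. draw `sample_fraction` of the calibration rows;
#' 2. fit PLS on the currently retained channels (latent-variable count
#'    re-chosen by k-fold CV on the drawn rows, capped at `max_nlv`);
#' 3. EDF step: keep the top `round(r_i * p)` channels by absolute
#'    regression coefficient (floored at 2, capped by the current count);
#' 4. ARS step on the survivors' normalised absolute coefficients (the
#'    result is topped up to 2 channels if the competitive draw
#'    collapses below the EDF floor);
#' 5. score the resulting subset by k-fold RMSECV on the full calibration
#'    block (one shared fold assignment across runs, so scores are
#'    paired).
#'
#' The subset of the lowest-RMSECV run is returned (lowest run index on
#' ties).
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result`.
#' @param n_runs number of sampling runs `N` (default 100).
#' @param sample_fraction calibration rows drawn per run (default 0.8).
#' @param cv_folds folds (default 5).
#' @param max_nlv cap on latent variables (default 10).
#' @param seed RNG seed driving all randomness in the call.
#' @return A `selection_result`; `diagnostics$trace` is a data frame with
#'   one row per run (`run`, `n_pre_ars`, `n_retained`, `n_lv`, `rmsecv`)
#'   and `diagnostics$coef_path` the p x N matrix of per-run coefficient
#'   vectors (zero once a channel is knocked out).
#' @export
select_cars <- function(ds, split, n_runs = 100, sample_fraction = 0.8,
                        cv_folds = 5, max_nlv = 10, seed = 1) {
  with_seed(seed, {
    cb <- cal_block(ds, split, cv_folds)
    n <- nrow(cb$X); p <- ncol(cb$X)
    sched <- edf_schedule(p, n_runs)
    m_draw <- max(2L, as.integer(round_half_up(sample_fraction * n)))
    live <- seq_len(p)
    subsets <- vector("list", n_runs)
    trace <- data.frame(run = seq_len(n_runs), n_pre_ars = NA_integer_,
                        n_retained = NA_integer_, n_lv = NA_integer_,
                        rmsecv = NA_real_)
    coef_path <- matrix(0, p, n_runs)
    for (i in seq_len(n_runs)) {
      rows <- sample.int(n, m_draw)
      Xs <- cb$X[rows, live, drop = FALSE]
      ys <- cb$y[rows]
      sub_fold <- make_folds(m_draw, min(cv_folds, m_draw))
      fit_eval <- .cpp_cv_subsets(Xs, ys, sub_fold,
                                  list(seq_along(live)), max_nlv)
      nlv_i <- as.integer(fit_eval[1, 2])
      Xsc <- sweep(Xs, 2, colMeans(Xs))
      b <- .cpp_pls1(Xsc, ys - mean(ys), nlv_i)
      b <- as.numeric(b$B[, b$ncomp])
      coef_path[live, i] <- b
      keep_n <- min(length(live),
                    max(2L, as.integer(round_half_up(sched$ratios[i] * p))))
      trace$n_pre_ars[i] <- keep_n
      ord <- order(-abs(b), seq_along(live))[seq_len(keep_n)]
      live_pre <- live[ord]
      w <- abs(b)[ord]
      if (all(w == 0)) w <- rep(1, length(w))
      w <- w / sum(w)
      live <- live_pre[ars_sample(w, draws = length(live_pre))]
      # keep at least 2 channels (the EDF's own floor), topping up with
      # the highest-weight survivors if ARS collapsed the set
      if (length(live) < 2)
        live <- sort(union(live, live_pre[order(-w)])[1:2])
      score <- .cpp_cv_subsets(cb$X, cb$y, cb$foldid, list(live), max_nlv)
      subsets[[i]] <- live
      trace$n_retained[i] <- length(live)
      trace$n_lv[i] <- as.integer(score[1, 2])
      trace$rmsecv[i] <- score[1, 1]
    }
    best <- which.min(trace$rmsecv)
    new_selection_result(
      "CARS", subsets[[best]], trace$n_lv[best], trace$rmsecv[best],
      diagnostics = list(trace = trace, best_run = best,
                         schedule = sched, coef_path = coef_path,
                         foldid = cb$foldid))
  })
}
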