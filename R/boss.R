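#' Weighted bootstrap subsets (WBS)
#'
#' Generates channel subsets by drawing `draws` indices with replacement
#' under the given sampling weights and keeping the unique values, so
#' channels with larger weights appear in more (and larger share of)
#' subsets while zero-weight channels never appear.
#'
#' @param w non-negative sampling weights over channels (at least one
#'   positive entry).
#' @param K number of subsets to generate.
#' @param draws with-replacement draws per subset (bootstrap convention:
#'   one per channel).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List of `K` sorted unique integer index vectors.
#' @export
weighted_bootstrap_subsets <- function(w, K, draws = length(w), seed = NULL) {
  if (K < 1) stop_ss("K must be >= 1")
  if (any(w < 0)) stop_ss("weights must be non-negative")
  if (sum(w > 0) < 1) stop_ss("need at least one positive weight")
  with_seed(seed, lapply(seq_len(K), function(k)
    sort(unique(sample.int(length(w), draws, replace = TRUE, prob = w)))))
}

#' Bootstrapping soft shrinkage (BOSS)
#'
#' Iterated weighted-bootstrap subset selection. Each iteration generates
#' `K` channel subsets under the current sampling weights (uniform at the
#' start), scores every subset by k-fold RMSECV (latent-variable count
#' re-chosen per subset), and rebuilds the weights from the best
#' `best_fraction` of sub-models: each best model's absolute regression
#' coefficient vector is normalised to unit L1 mass and the vectors are
#' summed, channels outside a subset contributing zero. Channels absent
#' from every best model get weight zero and can never return ("soft
#' shrinkage"). The subset with the lowest RMSECV over all iterations is
#' returned.
#'
#' Iteration stops when the current best subset is no larger than its
#' latent-variable count plus one, when the weight support has stopped
#' shrinking for 3 consecutive iterations, or after `max_iterations`.
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result`.
#' @param n_subsets subsets per iteration `K` (default 1000).
#' @param best_fraction fraction of sub-models feeding the new weights
#'   (default 0.1).
#' @param cv_folds folds (default 5).
#' @param max_nlv cap on latent variables (default 10).
#' @param max_iterations safety cap on iterations (default 30).
#' @param seed RNG seed driving all randomness in the call.
#' @return A `selection_result`; `diagnostics$trace` has one row per
#'   iteration (`iteration`, `support`, `mean_size`, `best_rmsecv`) and
#'   `diagnostics$weight_path` the p x n_iter matrix of weight vectors.
#' @export
select_boss <- function(ds, split, n_subsets = 1000, best_fraction = 0.1,
                        cv_folds = 5, max_nlv = 10, max_iterations = 30,
                        seed = 1) {
  with_seed(seed, {
    cb <- cal_block(ds, split, cv_folds)
    p <- ncol(cb$X)
    Xc <- sweep(cb$X, 2, colMeans(cb$X))
    yc <- cb$y - mean(cb$y)
    w <- rep(1 / p, p)
    n_best <- max(1L, as.integer(round_half_up(best_fraction * n_subsets)))
    best_global <- list(rmsecv = Inf, subset = NULL, n_lv = NA_integer_)
    trace <- data.frame(iteration = integer(0), support = integer(0),
                        mean_size = numeric(0), best_rmsecv = numeric(0))
    weight_path <- matrix(numeric(0), nrow = p, ncol = 0)
    stalled <- 0L
    for (it in seq_len(max_iterations)) {
      subsets <- weighted_bootstrap_subsets(w, n_subsets, draws = p)
      res <- .cpp_cv_subsets(cb$X, cb$y, cb$foldid, subsets, max_nlv)
      ord <- order(res[, 1], seq_len(n_subsets))
      top <- ord[seq_len(n_best)]
      it_best <- top[1]
      if (res[it_best, 1] < best_global$rmsecv) {
        best_global <- list(rmsecv = res[it_best, 1],
                            subset = subsets[[it_best]],
                            n_lv = as.integer(res[it_best, 2]))
      }
      w_new <- numeric(p)
      for (k in top) {
        idx <- subsets[[k]]
        fit <- .cpp_pls1(Xc[, idx, drop = FALSE], yc,
                         as.integer(res[k, 2]))
        babs <- abs(fit$B[, fit$ncomp])
        if (sum(babs) > 0) w_new[idx] <- w_new[idx] + babs / sum(babs)
      }
      if (sum(w_new) == 0) break
      w_prev_support <- sum(w > 0)
      w <- w_new / sum(w_new)
      trace <- rbind(trace, data.frame(
        iteration = it, support = sum(w > 0),
        mean_size = mean(lengths(subsets)), best_rmsecv = res[it_best, 1]))
      weight_path <- cbind(weight_path, w, deparse.level = 0)
      best_size <- length(subsets[[it_best]])
      if (best_size <= res[it_best, 2] + 1) break
      stalled <- if (sum(w > 0) < w_prev_support) 0L else stalled + 1L
      if (stalled >= 3L) break
    }
    new_selection_result(
      "BOSS", best_global$subset, best_global$n_lv, best_global$rmsecv,
      diagnostics = list(trace = trace, weight_path = weight_path,
                         foldid = cb$foldid))
  })
}
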