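#' Binary matrix sampling design (BMS)
#'
#' Random 0/1 inclusion matrix giving every live channel the same
#' inclusion probability in each of `K` sub-models. Rows with fewer than
#' two included channels are redrawn (a PLS sub-model needs at least two).
#'
#' @param m number of live channels (>= 2).
#' @param K number of sub-models (>= 10).
#' @param inclusion_ratio per-cell inclusion probability in (0, 1),
#'   default 0.5.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A `K x m` binary matrix.
#' @export
bms_matrix <- function(m, K, inclusion_ratio = 0.5, seed = NULL) {
  if (m < 2) stop_ss("m must be >= 2")
  if (K < 10) stop_ss("K must be >= 10")
  if (inclusion_ratio <= 0 || inclusion_ratio >= 1)
    stop_ss("inclusion_ratio must be in (0, 1)")
  with_seed(seed, {
    B <- matrix(stats::rbinom(K * m, 1, inclusion_ratio), K, m)
    repeat {
      bad <- which(rowSums(B) < 2)
      if (length(bad) == 0) break
      B[bad, ] <- stats::rbinom(length(bad) * m, 1, inclusion_ratio)
    }
    B
  })
}

#' Live-set size schedule for VCPA
#'
#' Geometric interpolation of the live channel count from `p` down to
#' `omega` over the EDF runs:
#' `n_i = round(p * (omega / p)^((i - 1) / (runs - 1)))`, so `n_1 = p`
#' and `n_runs = omega`, non-increasing.
#'
#' @param p initial channel count (`p > omega`).
#' @param omega final candidate count (>= 2; 14 in the reference
#'   protocol).
#' @param runs number of EDF runs (>= 2).
#' @return Integer vector of length `runs`.
#' @examples
#' vcpa_edf_counts(56, 14, 3)  # 56 28 14
#' @export
vcpa_edf_counts <- function(p, omega, runs) {
  if (!(p > omega && omega >= 2)) stop_ss("need p > omega >= 2")
  if (runs < 2) stop_ss("runs must be >= 2")
  i <- seq_len(runs)
  counts <- as.integer(round_half_up(p * (omega / p)^((i - 1) / (runs - 1))))
  counts <- cummin(counts)  # guard against rounding blips
  counts[1] <- as.integer(p); counts[runs] <- as.integer(omega)
  counts
}

#' Variable combination population analysis (VCPA)
#'
#' Model population analysis over binary-matrix-sampled channel subsets,
#' with an exponentially shrinking live set and a final exhaustive
#' combination search:
#'
#' 1. per EDF run, draw a [bms_matrix()] over the live channels and score
#'    the `K` sub-models by k-fold RMSECV (one shared seeded fold
#'    assignment for the whole procedure, so all comparisons are paired);
#' 2. rank live channels by their frequency of appearance in the best
#'    `best_fraction` of sub-models and shrink the live set to the next
#'    size of the geometric schedule [vcpa_edf_counts()];
#' 3. after the last run `omega` candidates remain; every one of the
#'    `2^omega - 1` non-empty candidate subsets is scored by RMSECV and
#'    the minimum returned (fewest channels, then lexicographically
#'    smallest, on ties).
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_result`.
#' @param edf_runs number of EDF runs (default 50).
#' @param n_bms sub-models per run `K` (default 1000).
#' @param omega candidates surviving the last EDF run (default 14).
#' @param best_fraction fraction of best sub-models used for the
#'   frequency ranking (default 0.1).
#' @param cv_folds folds (default 5).
#' @param max_nlv cap on latent variables (default 10).
#' @param seed RNG seed driving all randomness in the call.
#' @return A `selection_result`; `diagnostics` carries the per-run trace
#'   (`run`, `n_live`, `best_mean_rmsecv`), `final_candidates` (the
#'   `omega` channels entering the exhaustive stage) and
#'   `exhaustive_rmsecv` (score of every candidate subset, in
#'   cardinality-then-lexicographic order).
#' @export
select_vcpa <- function(ds, split, edf_runs = 50, n_bms = 1000, omega = 14,
                        best_fraction = 0.1, cv_folds = 5, max_nlv = 10,
                        seed = 1) {
  with_seed(seed, {
    cb <- cal_block(ds, split, cv_folds)
    p <- ncol(cb$X)
    if (omega >= p) stop_ss("omega must be smaller than the channel count")
    counts <- vcpa_edf_counts(p, omega, edf_runs)
    live <- seq_len(p)
    n_best <- max(1L, as.integer(round_half_up(best_fraction * n_bms)))
    trace <- data.frame(run = seq_len(edf_runs), n_live = NA_integer_,
                        best_mean_rmsecv = NA_real_)
    for (i in seq_len(edf_runs)) {
      m <- length(live)
      trace$n_live[i] <- m
      B <- bms_matrix(m, n_bms)
      subsets <- lapply(seq_len(n_bms), function(k) live[B[k, ] == 1])
      res <- .cpp_cv_subsets(cb$X, cb$y, cb$foldid, subsets, max_nlv)
      top <- order(res[, 1], seq_len(n_bms))[seq_len(n_best)]
      trace$best_mean_rmsecv[i] <- mean(res[top, 1])
      freq <- integer(p)
      for (k in top) freq[subsets[[k]]] <- freq[subsets[[k]]] + 1L
      if (i < edf_runs) {
        keep <- counts[i + 1]
        live <- live[order(-freq[live], live)][seq_len(keep)]
        live <- sort(live)
      }
    }
    final_candidates <- sort(live)
    cand_subsets <- enumerate_subsets(length(final_candidates))
    cand_global <- lapply(cand_subsets, function(s) final_candidates[s])
    res <- .cpp_cv_subsets(cb$X, cb$y, cb$foldid, cand_global, max_nlv)
    best <- which.min(res[, 1])  # order is cardinality-then-lex: first
                                 # minimum realises the tie-break
    new_selection_result(
      "VCPA", cand_global[[best]], res[best, 2], res[best, 1],
      diagnostics = list(trace = trace, final_candidates = final_candidates,
                         exhaustive_rmsecv = res[, 1], schedule = counts,
                         foldid = cb$foldid))
  })
}

# All non-empty subsets of 1..m, ordered by cardinality then
# lexicographically within each cardinality.
enumerate_subsets <- function(m) {
  out <- vector("list", 2^m - 1)
  pos <- 1L
  for (k in seq_len(m)) {
    cmb <- utils::combn(m, k)
    for (j in seq_len(ncol(cmb))) {
      out[[pos]] <- cmb[, j]
      pos <- pos + 1L
    }
  }
  out
}
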