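# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so package functions never clobber the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# round() in R is round-half-to-even; the retention schedules use the
# conventional half-away-from-zero rounding.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Seeded fold labels: random permutation cut into k near-equal
# contiguous blocks.
make_folds <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, k <= n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  foldid <- integer(n)
  foldid[perm] <- rep(seq_len(k), times = sizes)
  foldid
}

stop_ss <- function(...) stop(..., call. = FALSE)
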