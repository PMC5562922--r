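# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  Keeps cohort generation and permutation
# testing reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# round-half-away-from-zero; base round() rounds half to even, which would
# make edge budgets depend on the parity of the nearest integer.
round_half_up <- function(x) floor(x + 0.5)

# Number of unordered node pairs in an n-node simple graph.
n_pairs <- function(n) n * (n - 1) / 2

# Upper-triangle index pairs (i < j) in column-major order, as a 2-column
# matrix.  The canonical edge ordering used throughout.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
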