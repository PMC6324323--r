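# Internal helpers: deterministic seeding and stratified fold assignment.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. If seed is NULL, run as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a sequence of non-negative
# counters (repetition, fold, ...). Linear congruential mixing keeps the
# result a valid 32-bit seed and makes the scheme order-sensitive, so
# (seed, r, k) and (seed, k, r) differ.
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so class balance is as even as arithmetic allows.
# Returns an integer vector of fold labels in 1..k.
make_folds <- function(y, k, seed = NULL) {
  stopifnot(k >= 2, length(y) >= k)
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
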