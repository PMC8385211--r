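# Internal helpers shared across modules. No global RNG state is ever left
# modified: every stochastic operation takes an explicit seed and restores
# the caller's .Random.seed on exit.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded operations do
#' not perturb global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for an unordered pair of sample identifiers,
# derived from a master seed. Keyed on the identifiers themselves (not
# their positions), so results are independent of sample order; bounded
# below 2^31 so it is a valid R seed.
pair_seed <- function(seed, id_a, id_b) {
  h <- function(s) {
    v <- utf8ToInt(as.character(s))
    sum(v * 131^(seq_along(v) %% 7)) %% 999983
  }
  a <- min(h(id_a), h(id_b))
  b <- max(h(id_a), h(id_b))
  (((as.double(seed) %% 1000003) * 7919 + a * 104729 + b * 131) %% 2147483629) + 1
}

# Derive a named stage seed from a master seed (stable small offsets).
stage_seed <- function(seed, k) {
  ((as.double(seed) %% 1000003) * 31 + k * 9973) %% 2147483629 + 1
}

# Row-wise minima of D restricted to a set of columns.
row_mins <- function(D, cols) {
  if (length(cols) == 1L) {
    D[, cols]
  } else {
    do.call(pmin.int, lapply(cols, function(j) D[, j]))
  }
}

# All permutations of a small vector (used by exact enumeration oracles).
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- all_permutations(v[-i])
    for (p in rest) {
      k <- k + 1L
      out[[k]] <- c(v[i], p)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
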