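#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded internals never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Largest-remainder apportionment of n among proportions
#'
#' Rounds `n * proportions` to integers summing exactly to `n`: each part
#' gets its floor, and the remaining units go to the largest fractional
#' remainders (ties to the earlier part).
#'
#' @param n Total count.
#' @param proportions Non-negative weights summing to 1.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder_sizes <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  raw <- n * proportions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
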