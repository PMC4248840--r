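# Internal helpers: deterministic RNG scoping and structured validation errors.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic functions in the
# package route randomness through this so a single seed argument fully
# determines output without clobbering the user's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  expr
}

# Derive a child seed from a master seed and integer context indices.
# Multiplicative-congruential fold modulo the Mersenne prime 2^31 - 1:
# deterministic, order-sensitive, and always a valid 32-bit R seed.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in ks) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Structured validation failure: all invariant violations raise a condition
# of class "workloadbci_invalid" naming the violated invariant.
abort_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("workloadbci_invalid", "error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort_invalid("'%s' must be a finite scalar >= %g", name, min)
  }
  invisible(x)
}
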