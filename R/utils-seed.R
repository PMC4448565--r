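#' Derive a child seed from a master seed and a stream index
#'
#' All stochastic operations in the package draw from seeds produced by this
#' mixing function, so that a single master seed fixes every random choice in
#' a run (splits, hidden-layer weights, genetic operators) while distinct
#' streams stay decorrelated.
#'
#' The mix is a SplitMix-style multiply/xor on 31-bit integer arithmetic done
#' in doubles (exact below 2^53), returning a value in [1, 2^31 - 2] that is
#' always a valid `set.seed()` input.
#'
#' @param seed Integer master seed.
#' @param ... One or more integer stream indices (e.g. generation, split).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L, all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (k in as.numeric(idx)) {
    x <- (x * 48271 + (k %% m) * 16807 + 12345) %% m
    # one extra scramble round breaks lattice structure across streams
    x <- (x * 69621) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Thin wrapper over [withr::with_seed()] pinning the RNG kind, so results
#' are reproducible across sessions regardless of the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
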