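#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that generators are pure functions of their arguments and seed without
#' side effects on the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and stage indices
#'
#' Deterministic integer mixing kept below 2^31 so every stochastic stage
#' (fold, restart, augmented sample) gets its own reproducible stream.
#'
#' @param seed Master integer seed.
#' @param i,j,l Non-negative stage indices.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, i, j = 0L, l = 0L) {
  # doubles stay exact: max term ~ 1e6 * 1009 + i*9973 + ... << 2^53
  s <- (abs(seed) %% 1000003) * 1009 + i * 9973 + j * 99991 + l * 557
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
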