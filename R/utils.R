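#' @useDynLib maraq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd quantile
#' @importFrom utils write.csv packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls never perturb a user's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
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
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-series sub-seed derived from a master seed and a key.
# Stays below 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, key) {
  u <- utf8ToInt(as.character(key))
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 8191 + 1) %%
               2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min &&
    x == round(x)
}

is_len <- function(x, n = 1, min = NULL) {
  ok <- is.numeric(x) && length(x) == n && all(is.finite(x))
  if (ok && !is.null(min)) ok <- all(x > min)
  ok
}
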