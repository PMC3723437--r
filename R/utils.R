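#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive child seeds from one master seed
#'
#' All randomness in the package flows from explicit seeds. Stages that need
#' several independent RNG streams (cross-validation runs, Monte Carlo
#' sessions) draw child seeds from the master seed with this helper, so that
#' a single integer reproduces an entire analysis.
#'
#' @param seed master seed (integer) or `NULL` for non-reproducible draws.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Rolling mean of the current and up to `k - 1` preceding values
# (warm-up ticks average whatever history exists).
rolling_mean <- function(x, k = 3L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  lag <- c(rep(0, k), cs[seq_len(max(0L, n - k))])
  (cs - lag) / pmin(seq_len(n), k)
}
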