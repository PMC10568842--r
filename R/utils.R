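#' @useDynLib octapseudo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Clip to [0,1] without touching NA (inputs are validated finite upstream).
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All generators in the package are pure
# functions of (params, seed) through this helper.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer"))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stream child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
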