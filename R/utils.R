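# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components (generators, bootstrap intervals) never
#' disturb the surrounding random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string, for seeding per-token embeddings.
string_seed <- function(x, offset = 0L) {
  h <- as.numeric(offset) %% 2147483647
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# sample() without the scalar-x surprise: draws `n` elements of `x` itself.
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

# A value is "absent" when it is NA; used for branched instrument items.
is_absent <- function(x) is.null(x) || (length(x) == 1L && is.na(x))
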