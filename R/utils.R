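# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's \code{.Random.seed} so package functions
#' are deterministic for a given \code{seed} without disturbing the global
#' random stream.
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic stream splitting: one root seed, one sub-seed per named
# stage (events, participation, background, turnover, ...), so regenerating
# a single stage is stable under changes elsewhere. Kept below 2^31.
subSeed <- function(seed, stage) {
  stopifnot(is.numeric(stage), length(stage) == 1L)
  s <- (abs(as.double(seed)) %% 2147483647)
  as.integer((s * 48271 + as.double(stage) * 100003) %% 2147483647)
}

# Circularly shift each row of a binary matrix to the right by per-row
# offsets `off` (in frames). Vectorised through a single linear index.
shiftRows <- function(x, off) {
  n <- nrow(x)
  f <- ncol(x)
  idx <- (rep(0:(f - 1L), each = n) - off) %% f
  matrix(x[idx * n + seq_len(n)], n, f)
}

# k-th order statistic per row of a matrix (used for surrogate thresholds).
rowOrderStat <- function(x, k) {
  apply(x, 1L, function(v) sort.int(v, partial = k)[k])
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  as.double(x)
}

assertCount <- function(x, name, lower = 0L) {
  x <- assertNumber(x, name, lower = lower)
  if (x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  as.integer(x)
}

# Jaccard index of two index sets.
setJaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

stageError <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
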