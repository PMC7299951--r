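# Internal helpers shared across modules.

#' Run code with a private RNG stream
#'
#' Evaluates `expr` under `set.seed(seed)` while preserving (and afterwards
#' restoring) the caller's `.Random.seed`, so no package function mutates
#' global random state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed (< 2^31) from a base seed and an offset.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal draw by resampling below the floor; adequate for the mild
# truncation used for ages, follow-up durations and clinical scores.
rnorm_floor <- function(n, mean, sd, floor) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor)
  guard <- 0L
  while (length(bad) > 0L && guard < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < floor)
    guard <- guard + 1L
  }
  x[x < floor] <- floor
  x
}

# Integer score in [lo, hi] from a rounded normal.
rscore_int <- function(n, mean, sd, lo = 0L, hi = 6L) {
  pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
}
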