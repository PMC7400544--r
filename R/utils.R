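# Internal helpers shared across modules.

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
# Every stochastic entry point funnels through here so a user-supplied seed
# makes the whole pipeline reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Root-mean-square error, NA-safe.
rmse <- function(x, y) sqrt(mean((x - y)^2))

# Pearson correlation that degrades gracefully: zero variance in either
# argument yields 0 with a "degenerate" attribute instead of NA/error.
safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    structure(0, degenerate = TRUE)
  } else {
    structure(stats::cor(x, y), degenerate = FALSE)
  }
}

assert_beta_range <- function(x, what = "value", tol = 1e-6) {
  bad <- !is.na(x) & (x < -tol | x > 1 + tol)
  if (any(bad)) {
    stop(sprintf("%s out of [0,1]: found %g", what, x[which(bad)[1]]),
         call. = FALSE)
  }
  clip01(x)
}
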