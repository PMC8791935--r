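# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Weighted-free empirical percentile with inclusive linear interpolation
# (stats::quantile type 7); kept in one place so every interval in the
# package uses the same convention.
empirical_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, probs = c(a, 1 - a), type = 7, names = FALSE))
}
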