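#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards,
# so generators are reproducible without clobbering the session stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector with `estimate`, `lower`, `upper`
#'   (all on the proportion scale).
#' @examples
#' wilson_ci(39, 57)
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n > 0, x >= 0, x <= n)
  # the chi-square warning concerns prop.test's test statistic, not the
  # Wilson interval taken from it
  pt <- suppressWarnings(stats::prop.test(x, n, conf.level = conf_level,
                                          correct = FALSE))
  c(estimate = x / n, lower = pt$conf.int[1], upper = pt$conf.int[2])
}

# Integer NRS-style draw: latent normal, rounded and clamped to [lo, hi].
clamp_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

fmt_pct <- function(p, digits = 0) formatC(100 * p, format = "f", digits = digits)
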