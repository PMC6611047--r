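# Solve the intercept a such that E[plogis(a + slope * Z)] = p for Z ~ N(0,1),
# by Gauss quadrature over the normal density. Also used for cumulative-logit
# thresholds (the latent slope*Z + logistic error is symmetric in Z).
calib_intercept <- function(p, slope) {
  stopifnot(p > 0, p < 1)
  f <- function(a) {
    stats::integrate(function(z) stats::plogis(a + slope * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-10)$value - p
  }
  hw <- 3 + 3 * abs(slope)
  stats::uniroot(f, interval = stats::qlogis(p) + c(-hw, hw), tol = 1e-9)$root
}

ordinal_thresholds <- function(probs, slope) {
  stopifnot(abs(sum(probs) - 1) < 1e-8, all(probs > 0))
  cum <- cumsum(probs)[-length(probs)]
  vapply(cum, calib_intercept, numeric(1), slope = slope)
}

#' Marginal calibration targets of the synthetic ATLAS-like cohort
#'
#' Targets for means, standard deviations, prevalences, and latent-severity
#' loadings of every generated variable, chosen to match the published
#' baseline tables of the development cohort (with in-work status and item
#' spreads filled in with values typical of UK primary-care sciatica
#' cohorts where unpublished). Pain and bothersomeness items share a high
#' loading on the latent severity so that the pain block is strongly
#' intercorrelated, as in the source data.
#'
#' @return Nested list of per-variable targets; see [cohort_config()].
#' @export
default_marginals <- function() {
  list(
    age = list(mean = 50.2, sd = 14, min = 18, max = 95),
    pain_latent_load = 0.55,
    female = list(p = 0.606),
    in_work = list(p = 0.55),
    nrs = list(
      leg_pain_current = list(mean = 5.7, sd = 2.9, load = 0.90),
      leg_pain_usual = list(mean = 6.9, sd = 2.3, load = 0.90),
      back_pain_current = list(mean = 5.5, sd = 2.7, load = 0.90),
      back_pain_usual = list(mean = 7.0, sd = 2.2, load = 0.90),
      work_interference = list(mean = 5.8, sd = 2.6, load = 0.70)
    ),
    bothersomeness = list(
      both_leg = list(mean = 4.6, sd = 1.5, load = 0.90),
      both_paraesthesia = list(mean = 3.9, sd = 1.7, load = 0.90),
      both_weakness = list(mean = 3.1, sd = 1.8, load = 0.90),
      both_sitting = list(mean = 4.1, sd = 1.5, load = 0.90)
    ),
    pain_self_efficacy = list(mean = 33.3, sd = 14.6, load = -0.55),
    illness_identity = list(mean = 6, sd = 1.5, load = 0.40),
    rmdq = list(p = {p <- seq(0.25, 0.83, length.out = 24); p[6] <- 0.77; p},
                slope = 1.1),
    binary = list(
      pain_below_knee = list(p = 0.737, slope = 0.50),
      leg_worse_than_back = list(p = 0.562, slope = 0.20),
      tingling_numbness = list(p = 0.655, slope = 0.40),
      cough_sneeze_positive = list(p = 0.273, slope = 0.35),
      myotomal_weakness = list(p = 0.238, slope = 0.60),
      neural_tension_positive = list(p = 0.727, slope = 0.20)
    ),
    duration = list(p = c(0.442, 0.220, 0.338), slope = 0.30),
    reflex = list(p = c(0.753, 0.070, 0.133, 0.044), slope = 0.50),
    pinprick = list(p = c(0.490, 0.392, 0.118), slope = 0.70),
    startback = list(
      physical_p = c(0.86, 0.84, 0.80, 0.78), physical_slope = 1.1,
      psych_p = c(0.63, 0.59, 0.55, 0.52), psych_slope = 1.3,
      psych_latent_load = 0.60,
      item9_p = c(0.07, 0.13, 0.25, 0.33, 0.22)
    )
  )
}

#' Referral-generating logistic coefficients
#'
#' Conditional log-odds of specialist referral given the four clinical
#' characteristics and STarT Back risk class (reference: low risk, no
#' characteristics). The defaults are calibrated so that, on large
#' generated cohorts, the implied marginal (unadjusted) odds ratios and the
#' referral prevalence approximate the published development-cohort values
#' (impact OR 2.64, referral prevalence 13.3%, and the risk-class gradient).
#'
#' @return Named numeric vector: `intercept`, `impact`, `leg_pain`,
#'   `sensory`, `below_knee`, `medium`, `high`.
#' @export
referral_coefficients <- function() {
  c(intercept = -4.686,
    impact = 0.664,
    leg_pain = 0.693,
    sensory = 0.419,
    below_knee = 0.405,
    medium = 1.456,
    high = 1.705)
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_screened Number of invited patients to generate (default 609).
#' @param eligible_fraction Probability a screened patient receives a
#'   diagnosis with confidence in the eligible range (default 429/609).
#' @param marginals Per-variable calibration targets; see
#'   [default_marginals()].
#' @param referral Referral-generating coefficients; see
#'   [referral_coefficients()].
#' @param confidence_range List with integer ranges `eligible` and
#'   `ineligible` from which diagnostic confidence is drawn uniformly.
#' @param missing_exam_rate Probability each neurological-examination field
#'   is missing completely at random (default 0.02).
#' @param seed Integer random seed; the same config and seed always produce
#'   an identical cohort.
#' @return Validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_screened = 609,
                          eligible_fraction = 429 / 609,
                          marginals = default_marginals(),
                          referral = referral_coefficients(),
                          confidence_range = list(eligible = c(70, 100),
                                                  ineligible = c(0, 69)),
                          missing_exam_rate = 0.02,
                          seed = 20190704) {
  cfg <- list(n_screened = n_screened, eligible_fraction = eligible_fraction,
              marginals = marginals, referral = referral,
              confidence_range = confidence_range,
              missing_exam_rate = missing_exam_rate, seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  if (!is.numeric(cfg$n_screened) || length(cfg$n_screened) != 1 ||
      cfg$n_screened < 1 || cfg$n_screened != round(cfg$n_screened))
    fail("n_screened", "must be a positive integer")
  if (!is.numeric(cfg$eligible_fraction) || cfg$eligible_fraction <= 0 ||
      cfg$eligible_fraction > 1)
    fail("eligible_fraction", "must be in (0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed))
    fail("seed", "must be an integer")
  if (!is.numeric(cfg$missing_exam_rate) || cfg$missing_exam_rate < 0 ||
      cfg$missing_exam_rate > 1)
    fail("missing_exam_rate", "must be in [0, 1]")
  m <- cfg$marginals
  for (nm in names(m$binary)) {
    p <- m$binary[[nm]]$p
    if (!is.numeric(p) || p < 0 || p > 1)
      fail(paste0("marginals$binary$", nm), "prevalence must be in [0, 1]")
  }
  if (any(m$rmdq$p < 0 | m$rmdq$p > 1))
    fail("marginals$rmdq", "item prevalences must be in [0, 1]")
  if (m$female$p < 0 || m$female$p > 1)
    fail("marginals$female", "prevalence must be in [0, 1]")
  if (m$in_work$p < 0 || m$in_work$p > 1)
    fail("marginals$in_work", "prevalence must be in [0, 1]")
  for (nm in names(m$nrs)) {
    mu <- m$nrs[[nm]]$mean
    if (!is.numeric(mu) || mu < 0 || mu > 10)
      fail(paste0("marginals$nrs$", nm), "NRS mean must be in [0, 10]")
  }
  for (nm in names(m$bothersomeness)) {
    mu <- m$bothersomeness[[nm]]$mean
    if (mu < 0 || mu > 6)
      fail(paste0("marginals$bothersomeness$", nm), "mean must be in [0, 6]")
  }
  for (nm in c("duration", "reflex", "pinprick")) {
    p <- m[[nm]]$p
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-6)
      fail(paste0("marginals$", nm), "level probabilities must be positive and sum to 1")
  }
  sb <- m$startback
  if (any(c(sb$physical_p, sb$psych_p) <= 0 | c(sb$physical_p, sb$psych_p) >= 1))
    fail("marginals$startback", "item prevalences must be in (0, 1)")
  if (any(sb$item9_p <= 0) || abs(sum(sb$item9_p) - 1) > 1e-6)
    fail("marginals$startback$item9_p", "level probabilities must sum to 1")
  req <- c("intercept", "impact", "leg_pain", "sensory", "below_knee",
           "medium", "high")
  if (!all(req %in% names(cfg$referral)) || !is.numeric(cfg$referral))
    fail("referral", paste("must be a named numeric vector with elements",
                           paste(req, collapse = ", ")))
  for (nm in c("eligible", "ineligible")) {
    r <- cfg$confidence_range[[nm]]
    if (length(r) != 2 || any(r < 0) || any(r > 100) || r[1] > r[2])
      fail(paste0("confidence_range$", nm), "must be an increasing pair in [0, 100]")
  }
  invisible(cfg)
}
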