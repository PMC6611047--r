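#' Generate a synthetic ATLAS-like cohort
#'
#' Simulates one row per screened patient. A standard-normal latent severity
#' drives the pain, disability, psychological, and examination variables
#' (high loadings within the pain block reproduce its strong
#' intercorrelation); STarT Back items load on a partially shared
#' psychological latent. Referral is then drawn from a logistic model in
#' the four derived clinical characteristics and STarT Back risk class
#' (see [referral_coefficients()]), so that characteristic-referral odds
#' ratios converge to their configured magnitudes as the cohort grows.
#' Eligibility is encoded through diagnostic confidence: eligible patients
#' draw confidence uniformly in the eligible range (70-100 by default).
#' Finally a small configurable fraction of each neurological-examination
#' field is set missing completely at random.
#'
#' The same configuration (including seed) always yields an identical
#' cohort, and the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return Data frame in the canonical cohort schema ([cohort_schema()]),
#'   `config$n_screened` rows.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  m <- config$marginals
  n <- config$n_screened
  with_seed(config$seed, {
    L <- stats::rnorm(n)                       # latent severity
    pll <- m$startback$psych_latent_load
    Lp <- pll * L + sqrt(1 - pll^2) * stats::rnorm(n)  # psychological latent
    bll <- m$pain_latent_load
    Lb <- bll * L + sqrt(1 - bll^2) * stats::rnorm(n)  # pain-block latent

    nrs_draw <- function(spec, lo, hi, latent = L) {
      x <- spec$mean + spec$sd * (spec$load * latent +
                                    sqrt(1 - spec$load^2) * stats::rnorm(n))
      as.integer(clamp_round(x, lo, hi))
    }
    bin_draw <- function(spec) {
      a <- calib_intercept(spec$p, spec$slope)
      stats::rbinom(n, 1, stats::plogis(a + spec$slope * L)) == 1
    }
    ord_draw <- function(spec, latent = L) {
      t <- ordinal_thresholds(spec$p, spec$slope)
      lat <- spec$slope * latent + stats::rlogis(n)
      findInterval(lat, t) + 1L
    }

    d <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
    d$age <- as.integer(clamp_round(stats::rnorm(n, m$age$mean, m$age$sd),
                                    m$age$min, m$age$max))
    d$sex <- ifelse(stats::rbinom(n, 1, m$female$p) == 1, "female", "male")
    d$in_work <- stats::rbinom(n, 1, m$in_work$p) == 1
    wi <- nrs_draw(m$nrs$work_interference, 0, 10)
    d$work_interference <- ifelse(d$in_work, wi, NA_integer_)
    for (v in c("leg_pain_current", "leg_pain_usual", "back_pain_current",
                "back_pain_usual"))
      d[[v]] <- nrs_draw(m$nrs[[v]], 0, 10, latent = Lb)
    for (v in names(m$binary)) d[[v]] <- bin_draw(m$binary[[v]])
    for (j in seq_along(m$rmdq$p))
      d[[sprintf("rmdq_%02d", j)]] <-
        as.integer(bin_draw(list(p = m$rmdq$p[j], slope = m$rmdq$slope)))
    sb <- m$startback
    for (j in 1:4)
      d[[paste0("sb_", j)]] <- as.integer(stats::rbinom(
        n, 1, stats::plogis(calib_intercept(sb$physical_p[j],
                                            sb$physical_slope) +
                              sb$physical_slope * L)))
    for (j in 1:4)
      d[[paste0("sb_", j + 4)]] <- as.integer(stats::rbinom(
        n, 1, stats::plogis(calib_intercept(sb$psych_p[j], sb$psych_slope) +
                              sb$psych_slope * Lp)))
    d$sb_9 <- startback_item9_levels[
      ord_draw(list(p = sb$item9_p, slope = sb$psych_slope), latent = Lp)]
    for (v in names(m$bothersomeness))
      d[[v]] <- nrs_draw(m$bothersomeness[[v]], 0, 6, latent = Lb)
    d$pain_self_efficacy <- as.integer(clamp_round(
      m$pain_self_efficacy$mean + m$pain_self_efficacy$sd *
        (m$pain_self_efficacy$load * L +
           sqrt(1 - m$pain_self_efficacy$load^2) * stats::rnorm(n)), 0, 60))
    d$illness_identity <- as.integer(clamp_round(
      m$illness_identity$mean + m$illness_identity$sd *
        (m$illness_identity$load * L +
           sqrt(1 - m$illness_identity$load^2) * stats::rnorm(n)), 0, 10))
    d$duration_category <- c("<6 weeks", "6 weeks-3 months",
                             ">3 months")[ord_draw(m$duration)]
    d$reflex_status <- c("normal", "slightly reduced", "absent",
                         "significantly reduced")[ord_draw(m$reflex)]
    d$pinprick_sensation <- c("normal", "reduced", "loss")[ord_draw(m$pinprick)]

    eligible <- stats::rbinom(n, 1, config$eligible_fraction) == 1
    cr <- config$confidence_range
    d$diagnostic_confidence <- ifelse(
      eligible,
      sample(seq(cr$eligible[1], cr$eligible[2]), n, replace = TRUE),
      sample(seq(cr$ineligible[1], cr$ineligible[2]), n, replace = TRUE))

    # referral drawn from the configured logistic model over the derived
    # characteristics and STarT Back risk (computed before missingness)
    chars <- derive_characteristics(d)
    risk <- score_startback(d[, paste0("sb_", 1:9)])$sb_risk
    b <- config$referral
    lin <- b[["intercept"]] +
      b[["impact"]] * chars$c_impact +
      b[["leg_pain"]] * chars$c_leg_pain +
      b[["sensory"]] * chars$c_sensory +
      b[["below_knee"]] * chars$c_below_knee +
      b[["medium"]] * (risk == "medium") +
      b[["high"]] * (risk == "high")
    d$referred <- stats::rbinom(n, 1, stats::plogis(lin)) == 1

    exam <- c("myotomal_weakness", "reflex_status", "pinprick_sensation",
              "neural_tension_positive")
    for (v in exam)
      d[[v]][stats::runif(n) < config$missing_exam_rate] <- NA
    d[, cohort_schema()$column]
  })
}
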