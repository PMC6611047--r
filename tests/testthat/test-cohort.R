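test_that("the generator is deterministic in (config, seed)", {
  cfg <- cohort_config(n_screened = 300, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_screened = 300, seed = 8)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_config(n_screened = 100, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(n_screened = -1), "n_screened")
  expect_error(cohort_config(n_screened = 10.5), "n_screened")
  expect_error(cohort_config(eligible_fraction = 1.5), "eligible_fraction")
  expect_error(cohort_config(missing_exam_rate = 2), "missing_exam_rate")
  m <- default_marginals()
  m$nrs$leg_pain_current$mean <- 11
  expect_error(cohort_config(marginals = m), "leg_pain_current")
  m <- default_marginals()
  m$binary$pain_below_knee$p <- -0.1
  expect_error(cohort_config(marginals = m), "pain_below_knee")
  b <- referral_coefficients()
  expect_error(cohort_config(referral = b[-2]), "referral")
})

test_that("marginals, prevalence, and configured odds ratios converge on large cohorts", {
  n <- 100000
  d <- prepare_cohort(generate_cohort(cohort_config(n_screened = n, seed = 42,
                                                    missing_exam_rate = 0)))
  m <- default_marginals()
  tol <- function(p) 4 * sqrt(p * (1 - p) / n)
  # binary prevalences
  for (v in c("pain_below_knee", "tingling_numbness", "myotomal_weakness")) {
    p <- m$binary[[v]]$p
    expect_lt(abs(mean(d[[v]]) - p), tol(p))
  }
  expect_lt(abs(mean(d$sex == "female") - m$female$p), tol(m$female$p))
  # NRS and questionnaire means (integer discretization allows a small bias)
  expect_lt(abs(mean(d$leg_pain_current) - m$nrs$leg_pain_current$mean), 0.15)
  expect_lt(abs(mean(d$pain_self_efficacy) - m$pain_self_efficacy$mean), 0.5)
  # STarT Back risk distribution close to the development cohort's
  risk <- prop.table(table(d$sb_risk))
  expect_lt(abs(risk[["low"]] - 0.112), 0.02)
  expect_lt(abs(risk[["high"]] - 0.387), 0.02)
  # referral prevalence among eligible patients near 13.3%
  el <- d[d$diagnostic_confidence >= 70, ]
  expect_lt(abs(mean(el$referred) - 0.133), 0.01)
  # empirical unadjusted impact odds ratio near its configured magnitude
  t <- table(el$c_impact, el$referred)
  or_impact <- (t[2, 2] * t[1, 1]) / (t[2, 1] * t[1, 2])
  expect_lt(abs(or_impact - 2.64), 0.15)
  # pain-block items are strongly intercorrelated
  pain_vars <- c("back_pain_usual", "leg_pain_usual", "back_pain_current",
                 "leg_pain_current", "both_leg", "both_sitting")
  cm <- cor(d[, pain_vars])
  expect_gt(min(cm[upper.tri(cm)]), 0.7)
})

test_that("exam fields carry the configured missingness and others are complete", {
  d <- generate_cohort(cohort_config(n_screened = 20000, seed = 3,
                                     missing_exam_rate = 0.02))
  for (v in c("myotomal_weakness", "reflex_status", "pinprick_sensation",
              "neural_tension_positive")) {
    r <- mean(is.na(d[[v]]))
    expect_gt(r, 0.005)
    expect_lt(r, 0.04)
  }
  expect_false(anyNA(d$referred))
  expect_false(anyNA(d$leg_pain_current))
  # work interference is present exactly for patients in work
  expect_identical(is.na(d$work_interference), !d$in_work)
})

test_that("generated values respect the instrument ranges", {
  d <- generate_cohort(cohort_config(n_screened = 5000, seed = 9))
  rng <- function(v) range(d[[v]], na.rm = TRUE)
  for (v in c("leg_pain_current", "leg_pain_usual", "back_pain_current",
              "back_pain_usual", "work_interference"))
    expect_true(all(rng(v) >= 0 & rng(v) <= 10))
  for (v in c("both_leg", "both_paraesthesia", "both_weakness", "both_sitting"))
    expect_true(all(rng(v) >= 0 & rng(v) <= 6))
  expect_true(all(rng("pain_self_efficacy") >= 0 & rng("pain_self_efficacy") <= 60))
  expect_true(all(rng("diagnostic_confidence") >= 0 &
                    rng("diagnostic_confidence") <= 100))
  expect_true(all(d$sb_9 %in% startback_item9_levels))
})
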