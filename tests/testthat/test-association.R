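test_that("odds ratios and Wald CIs reproduce hand-computable tables", {
  r <- odds_ratio_2x2(43, 14, 200, 172)
  expect_equal(round(r$odds_ratio, 2), 2.64)
  expect_equal(round(r$ci_low, 2), 1.40)
  expect_equal(round(r$ci_high, 2), 4.99)
  expect_lt(r$p_value, 0.05)
  # symmetry: equal cells give OR exactly 1
  for (k in c(1, 5, 50)) {
    rs <- odds_ratio_2x2(k, k, k, k)
    expect_equal(rs$odds_ratio, 1)
    expect_equal(rs$p_value, 1)
  }
})

test_that("OR equals exp(univariable logistic coefficient) and inverts under recoding", {
  set.seed(31)
  for (i in 1:5) {
    cells <- sample(3:80, 4)
    r <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    oracle <- or_glm_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$odds_ratio, unname(oracle), tolerance = 1e-6)
    inv <- odds_ratio_2x2(cells[2], cells[1], cells[4], cells[3])
    expect_equal(inv$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  }
})

test_that("zero cells trigger the continuity correction; zero margins error", {
  r <- odds_ratio_2x2(0, 10, 5, 20)
  expect_true(r$continuity)
  expect_equal(r$odds_ratio, (0.5 * 20.5) / (10.5 * 5.5))
  expect_error(odds_ratio_2x2(0, 0, 5, 20), "row or column")
  expect_error(odds_ratio_2x2(0, 10, 0, 20), "row or column")
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("collinearity screen drops duplicates, constants, and respects force_keep", {
  set.seed(5)
  n <- 400
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- d$x1                       # perfect copy
  d$x3 <- rnorm(n)
  d$x4 <- rep(1, n)                  # constant
  scr <- collinearity_screen(d, c("x1", "x2", "x3", "x4"))
  expect_setequal(scr$retained, c("x1", "x3") )
  expect_true("zero variance" %in% scr$dropped$reason)
  dup <- scr$dropped[scr$dropped$reason == "pairwise correlation", ]
  expect_equal(dup$value, 1, tolerance = 1e-12)
  # force_keep decides which member of a correlated pair survives
  scr2 <- collinearity_screen(d, c("x1", "x2", "x3"), force_keep = "x2")
  expect_true("x2" %in% scr2$retained)
  expect_false("x1" %in% scr2$retained)
})

test_that("independent variables pass the screen and VIF matches brute force", {
  set.seed(8)
  n <- 10000
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  scr <- collinearity_screen(d, c("a", "b", "c"))
  expect_setequal(scr$retained, c("a", "b", "c"))
  expect_true(all(scr$vif < 5))
  expect_equal(unname(scr$vif[c("a", "b", "c")]),
               vif_brute_force(d[, c("a", "b", "c")]), tolerance = 1e-6)
})

test_that("the synthetic pain block collapses to the forced clinical survivor", {
  d <- test_cohort(seed = 17, n = 8000)
  pain <- atlas_blocks()$pain
  scr <- collinearity_screen(d, pain, force_keep = "leg_pain_current")
  expect_equal(scr$retained, "leg_pain_current")
})

test_that("block-wise selection is deterministic and traces every candidate once", {
  d <- test_cohort(seed = 23)
  m1 <- referral_model(d)
  m2 <- referral_model(d)
  expect_identical(m1$trace, m2$trace)
  expect_identical(coef(m1), coef(m2))
  vars <- unlist(atlas_blocks(), use.names = FALSE)
  expect_setequal(m1$trace$variable, vars)
  expect_equal(anyDuplicated(m1$trace$variable), 0L)
  expect_false(anyNA(m1$trace$disposition))
  # a single-variable block never gets a within-block multivariable model
  expect_false("impact" %in% names(m1$block_models))
  # predict returns probabilities for the analyzed patients
  p <- predict(m1)
  expect_true(all(p > 0 & p < 1))
  expect_length(p, m1$n_used)
})

test_that("selection under a known truth keeps the real factor and controls the rest", {
  b <- referral_coefficients()
  b[c("leg_pain", "sensory", "below_knee", "medium", "high")] <- 0
  b[["impact"]] <- 1.2
  b[["intercept"]] <- -2.6
  n_rep <- 60
  kept_impact <- 0
  null_kept <- 0
  null_total <- 0
  fails <- 0
  null_vars <- setdiff(unlist(atlas_blocks(), use.names = FALSE), "c_impact")
  for (i in seq_len(n_rep)) {
    d <- test_cohort(seed = 5000 + i, referral = b)
    m <- tryCatch(referral_model(d), error = function(e) NULL)
    if (is.null(m)) {
      fails <- fails + 1
      next
    }
    kept_impact <- kept_impact + ("c_impact" %in% m$retained)
    null_kept <- null_kept + length(intersect(m$retained, null_vars))
    null_total <- null_total + length(null_vars)
  }
  done <- n_rep - fails
  expect_gt(done, n_rep * 0.8)
  expect_gt(kept_impact / done, 0.5)
  # false-retention rate of truly null factors stays near the nominal level
  expect_lt(null_kept / null_total, 0.1)
})
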