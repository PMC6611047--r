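test_that("allocation follows the published three-group rule", {
  expect_equal(allocate("low", 4L), 1L)
  expect_equal(allocate("low", 0L), 1L)
  expect_equal(allocate("medium", 4L), 3L)
  expect_equal(allocate("high", 3L), 3L)
  expect_equal(allocate("high", 4L), 3L)
  expect_equal(allocate("high", 2L), 2L)
  expect_equal(allocate("medium", 3L), 2L)
  expect_error(allocate("severe", 2L), "risk class")
  expect_error(allocate("high", 5L), "0..4")
})

test_that("allocation partitions and is monotone over all 15 (risk, count) cells", {
  grid <- expand.grid(risk = c("low", "medium", "high"), count = 0:4,
                      stringsAsFactors = FALSE)
  g <- allocate(grid$risk, grid$count)
  expect_false(anyNA(g))
  expect_true(all(g %in% 1:3))
  # adding a characteristic never lowers the group (and never leaves group 3)
  for (r in c("low", "medium", "high"))
    expect_true(all(diff(g[grid$risk == r][order(grid$count[grid$risk == r])]) >= 0))
  # raising risk at fixed count never lowers the group
  for (k in 0:4) {
    gk <- g[grid$count == k][match(c("low", "medium", "high"),
                                   grid$risk[grid$count == k])]
    expect_true(all(diff(gk) >= 0))
  }
})

test_that("indeterminate flags are refused only when they could change the group", {
  flags <- function(...) {
    v <- list(...)
    data.frame(c_impact = v[[1]], c_leg_pain = v[[2]], c_sensory = v[[3]],
               c_below_knee = v[[4]])
  }
  # low risk is forced to group 1 whatever the flags
  expect_equal(allocate("low", flags(NA, NA, NA, NA)), 1L)
  # high risk with three confirmed TRUE allocates regardless of the fourth
  expect_equal(allocate("high", flags(TRUE, TRUE, TRUE, NA)), 3L)
  # high risk with at most two reachable is group 2
  expect_equal(allocate("high", flags(FALSE, FALSE, TRUE, NA)), 2L)
  # high risk with two TRUE and two unknown could go either way
  expect_true(is.na(allocate("high", flags(TRUE, TRUE, NA, NA))))
  # medium risk needs all four: any FALSE decides group 2
  expect_equal(allocate("medium", flags(TRUE, TRUE, TRUE, FALSE)), 2L)
  expect_true(is.na(allocate("medium", flags(TRUE, TRUE, TRUE, NA))))
})

test_that("classification metrics satisfy their confusion-table identities", {
  set.seed(19)
  for (i in 1:5) {
    k <- as.list(sample(1:60, 4))
    names(k) <- c("tp", "fp", "fn", "tn")
    m <- do.call(classification_metrics, k)
    expect_equal(m$sensitivity[["estimate"]], k$tp / (k$tp + k$fn))
    expect_equal(m$specificity[["estimate"]], k$tn / (k$tn + k$fp))
    expect_equal(m$ppv[["estimate"]], k$tp / (k$tp + k$fp))
    expect_equal(m$npv[["estimate"]] * (k$tn + k$fn), k$tn)
    expect_equal(m$fraction_fast_tracked[["estimate"]],
                 (k$tp + k$fp) / m$n)
    expect_true(m$sensitivity[["lower"]] <= m$sensitivity[["estimate"]],
                m$sensitivity[["estimate"]] <= m$sensitivity[["upper"]])
  }
  # zero predicted-positive margin leaves PPV undefined and flagged
  m0 <- classification_metrics(0, 0, 10, 30)
  expect_true(is.na(m0$ppv[["estimate"]]))
  expect_true("ppv" %in% m0$undefined)
})

test_that("a fast-track-everyone rule is degenerate as expected", {
  d <- test_cohort(seed = 81)
  rule <- scenario_rule("all", overall_min = 0, low_risk_excluded = FALSE)
  m <- evaluate_rule(rule, d)
  expect_equal(m$sensitivity[["estimate"]], 1)
  expect_equal(m$specificity[["estimate"]], 0)
  expect_equal(m$fraction_fast_tracked[["estimate"]], 1)
})

test_that("the adopted scenario's fast-track set is exactly allocation group 3", {
  d <- test_cohort(seed = 91)
  ok <- !is.na(d$sb_risk) & !is.na(d$n_characteristics) & !is.na(d$referred)
  d <- d[ok, ]
  rule <- scenario_rule("S3", high_min = 3, medium_min = 4)
  ft <- rule$predicate(d$sb_risk, d$n_characteristics)
  g <- allocate(d$sb_risk, d$n_characteristics)
  expect_identical(ft, g == 3L)
  # low-risk patients stay in the denominators without ever being fast-tracked
  m <- evaluate_rule(rule, d)
  expect_equal(m$n, nrow(d))
  expect_false(any(ft[d$sb_risk == "low"]))
})

test_that("group summaries partition the cohort and order severity as built", {
  d <- test_cohort(seed = 101)
  d <- d[!is.na(d$sb_risk) & !is.na(d$n_characteristics), ]
  g <- allocate(d$sb_risk, d$n_characteristics)
  gs <- group_summary(d, g)
  expect_equal(sum(gs$n), length(g[!is.na(g)]))
  leg <- gs$continuous[gs$continuous$variable == "leg_pain_current", ]
  expect_gt(leg$mean[leg$group == 3], leg$mean[leg$group == 1])
  # an all-low-risk cohort lands entirely in group 1
  g1 <- allocate(rep("low", 10), rep(2L, 10))
  gs1 <- group_summary(d[1:10, ], g1)
  expect_equal(unname(gs1$n), c(10L, 0L, 0L))
  expect_output(print(gs1), "group 3: 0")
})
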