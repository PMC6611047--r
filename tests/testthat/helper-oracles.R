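# Independent brute-force oracles used to cross-check package computations.

# AUC as explicit enumeration of all case/non-case pairs, ties counted 1/2.
auc_brute_force <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  cases <- scores[outcomes]
  controls <- scores[!outcomes]
  tot <- 0
  for (u in cases) for (v in controls)
    tot <- tot + (u > v) + 0.5 * (u == v)
  tot / (length(cases) * length(controls))
}

# VIF by direct regression of each column on the others: 1 / (1 - R^2).
vif_brute_force <- function(X) {
  X <- as.data.frame(X)
  vapply(seq_along(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[-j])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}

# Odds ratio via a univariable logistic fit on expanded 0/1 records.
or_glm_oracle <- function(a, b, c, d) {
  exposure <- c(rep(1, a + b), rep(0, c + d))
  outcome <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  exp(coef(glm(outcome ~ exposure, family = binomial()))[2])
}

# All 2^8 x 5 STarT Back item combinations with rule-derived scores.
startback_grid <- function() {
  g <- expand.grid(rep(list(0:1), 8))
  g <- g[rep(seq_len(nrow(g)), each = 5), ]
  g$i9 <- rep(0:4, times = 256)
  names(g) <- c(paste0("it", 1:8), "i9")
  g
}

# A small eligible, prepared synthetic cohort for module tests.
test_cohort <- function(seed = 1, n = 609, ...) {
  d <- prepare_cohort(generate_cohort(cohort_config(n_screened = n,
                                                    seed = seed, ...)))
  d[d$diagnostic_confidence >= 70, ]
}
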