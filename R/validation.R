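# Fast tie-aware concordance (AUC) via the rank statistic; used inside the
# bootstrap loop where pROC's object construction would dominate runtime.
auc_stat <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: outcomes contain a single class", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' AUC is the probability that a randomly chosen case scores higher than a
#' randomly chosen non-case, with ties counted 1/2; the 95% CI uses DeLong's
#' method.
#'
#' @param scores Numeric risk scores (higher = more likely case).
#' @param outcomes Binary outcome (logical or 0/1); at least one case and
#'   one non-case.
#' @return List with `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
auc_ci <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  est <- auc_stat(scores, outcomes)  # validates inputs
  r <- pROC::roc(response = outcomes, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  # DeLong variance is zero for a perfectly separating score; the CI then
  # degenerates to the point estimate
  ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
                 error = function(e) c(est, est, est))
  list(auc = est, ci_low = ci[1], ci_high = ci[3],
       n_cases = sum(outcomes == 1L), n_controls = sum(outcomes == 0L))
}

#' Calibration slope of a logistic linear predictor
#'
#' The slope coefficient from refitting the outcome on the model's linear
#' predictor (log-odds scale), with a Wald 95% CI. A model evaluated on its
#' own development data has slope 1 by the maximum-likelihood score
#' equations; a slope below 1 in new data indicates overfitting.
#'
#' @param linear_predictor Numeric vector on the log-odds scale.
#' @param outcomes Binary outcome.
#' @return List with `slope`, `ci_low`, `ci_high`, `intercept`.
#' @export
calibration_slope <- function(linear_predictor, outcomes) {
  if (stats::sd(linear_predictor) == 0)
    stop("calibration slope undefined: zero-variance linear predictor",
         call. = FALSE)
  y <- as.integer(as.logical(outcomes))
  fit <- stats::glm(y ~ linear_predictor, family = stats::binomial())
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  list(slope = cf[2, 1],
       ci_low = cf[2, 1] - z * cf[2, 2],
       ci_high = cf[2, 1] + z * cf[2, 2],
       intercept = cf[1, 1])
}

#' Bootstrap optimism-corrected discrimination of a logistic model
#'
#' Enhanced bootstrap internal validation: the model specification is refit
#' in each bootstrap resample (patients resampled with replacement,
#' coefficients re-estimated), its AUC is computed in the resample
#' ("train") and in the original cohort ("test"), and optimism is the mean
#' of train minus test. The optimism-corrected AUC is the apparent AUC minus
#' the optimism. Replicates whose resampled outcome is single-class or whose
#' fit separates are discarded and counted; a warning is raised when more
#' than 10% are discarded.
#'
#' @param data Complete-case data frame for the model variables.
#' @param formula Final model formula (binary outcome on the left).
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Integer RNG seed; recorded in the report.
#' @return Object of class `"validation_report"`: apparent AUC with DeLong
#'   CI, mean bootstrap ("train") AUC with a normal-approximation CI over
#'   replicates, `optimism`, `corrected_auc`, apparent `calibration` slope
#'   with CI, `n_replicates`, `n_discarded`, `seed`, and the per-replicate
#'   `optimism_values`.
#' @export
bootstrap_optimism <- function(data, formula, n_replicates = 500, seed = 1) {
  formula <- stats::as.formula(formula)
  outcome <- all.vars(formula)[1]
  mf_vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, mf_vars, drop = FALSE]), ,
               drop = FALSE]
  data[[outcome]] <- as.integer(as.logical(data[[outcome]]))
  fit0 <- stats::glm(formula, family = stats::binomial(), data = data)
  lp0 <- stats::predict(fit0, type = "link")
  apparent <- auc_ci(lp0, data[[outcome]])
  calib <- calibration_slope(lp0, data[[outcome]])

  train <- test <- numeric(0)
  n_discarded <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      db <- data[idx, , drop = FALSE]
      if (length(unique(db[[outcome]])) < 2) {
        n_discarded <- n_discarded + 1L
        next
      }
      fitb <- suppressWarnings(
        stats::glm(formula, family = stats::binomial(), data = db))
      # discard only fits that cannot rank patients: aliased or non-finite
      # coefficients (a separated fit with finite estimates still orders
      # the linear predictor correctly)
      cfb <- stats::coef(fitb)
      if (anyNA(cfb) || any(!is.finite(cfb))) {
        n_discarded <- n_discarded + 1L
        next
      }
      train <- c(train, auc_stat(stats::predict(fitb, type = "link"),
                                 db[[outcome]]))
      test <- c(test, auc_stat(stats::predict(fitb, newdata = data,
                                              type = "link"),
                               data[[outcome]]))
    }
  })
  if (n_discarded > 0.1 * n_replicates)
    warning(sprintf("%d of %d bootstrap replicates discarded", n_discarded,
                    n_replicates))
  optimism_values <- train - test
  optimism <- mean(optimism_values)
  z <- stats::qnorm(0.975)
  se_train <- stats::sd(train) / sqrt(length(train))
  out <- list(apparent_auc = apparent$auc,
              apparent_ci = c(apparent$ci_low, apparent$ci_high),
              bootstrap_mean_auc = mean(train),
              bootstrap_ci = c(mean(train) - z * se_train,
                               mean(train) + z * se_train),
              optimism = optimism,
              corrected_auc = apparent$auc - optimism,
              calibration = calib,
              n_replicates = n_replicates,
              n_discarded = n_discarded,
              optimism_values = optimism_values,
              seed = seed,
              formula = formula)
  class(out) <- "validation_report"
  out
}

#' Internal validation of a fitted model
#'
#' @param object Object to validate.
#' @param ... Method arguments.
#' @export
validate <- function(object, ...) UseMethod("validate")

#' @describeIn validate Bootstrap optimism correction of a
#'   [referral_model()] fit, refitting the final model specification in each
#'   resample.
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Integer RNG seed.
#' @export
validate.referral_model <- function(object, n_replicates = 500, seed = 1, ...) {
  bootstrap_optimism(object$data, stats::formula(object$fit),
                     n_replicates = n_replicates, seed = seed)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Internal validation (bootstrap optimism correction)\n")
  cat(sprintf("  apparent AUC:  %.3f (%.3f, %.3f)\n", x$apparent_auc,
              x$apparent_ci[1], x$apparent_ci[2]))
  cat(sprintf("  bootstrap mean AUC: %.3f (%.3f, %.3f) over %d replicates\n",
              x$bootstrap_mean_auc, x$bootstrap_ci[1], x$bootstrap_ci[2],
              x$n_replicates - x$n_discarded))
  cat(sprintf("  optimism: %.3f%s\n", x$optimism,
              if (x$optimism < 0) " [negative optimism]" else ""))
  cat(sprintf("  optimism-corrected AUC: %.3f\n", x$corrected_auc))
  cat(sprintf("  apparent calibration slope: %.2f (%.2f, %.2f)\n",
              x$calibration$slope, x$calibration$ci_low, x$calibration$ci_high))
  if (x$n_discarded > 0)
    cat(sprintf("  discarded replicates: %d\n", x$n_discarded))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
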