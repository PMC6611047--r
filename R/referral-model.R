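#' Candidate-factor domains for the referral analysis
#'
#' The candidate predictors of specialist referral, grouped into the five
#' clinical domains used by the block-wise selection: impact of the
#' condition, pain levels/symptoms, psychological perceptions, symptom
#' behaviour and presentation, and clinical examination findings. Column
#' names refer to the prepared cohort (see [prepare_cohort()]).
#'
#' @return Named list of character vectors, one per block.
#' @export
atlas_blocks <- function() {
  list(
    impact = "c_impact",
    pain = c("back_pain_usual", "leg_pain_usual", "back_pain_current",
             "leg_pain_current", "both_leg", "both_paraesthesia",
             "both_weakness", "both_sitting", "both_composite"),
    psychological = c("pain_self_efficacy", "illness_identity"),
    symptoms = c("leg_worse_than_back", "tingling_numbness",
                 "cough_sneeze_positive"),
    examination = c("myotomal_weakness", "reflex_status",
                    "pinprick_sensation", "neural_tension_positive")
  )
}

# Joint Wald test per model term (multi-df for factors), from coef and vcov.
term_wald <- function(fit) {
  tl <- attr(stats::terms(fit), "term.labels")
  if (length(tl) == 0)
    return(data.frame(term = character(), df = integer(),
                      chisq = numeric(), p = numeric()))
  asg <- attr(stats::model.matrix(fit), "assign")
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  rows <- lapply(seq_along(tl), function(i) {
    cols <- which(asg == i)
    cols <- cols[!is.na(cf[cols])]
    if (length(cols) == 0)
      return(data.frame(term = tl[i], df = 0L, chisq = NA_real_, p = NA_real_))
    b <- cf[cols]
    W <- drop(t(b) %*% solve(V[cols, cols, drop = FALSE]) %*% b)
    data.frame(term = tl[i], df = length(cols), chisq = W,
               p = stats::pchisq(W, length(cols), lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# Heuristic separation check for a logistic fit.
is_separated <- function(fit) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  !fit$converged || any(!is.finite(cf)) || any(abs(cf[-1]) > 15) ||
    any(!is.finite(se)) || any(se > 50)
}

glm_or_table <- function(fit) {
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(0.975)
  data.frame(term = rownames(cf),
             or = exp(cf[, 1]),
             ci_low = exp(cf[, 1] - z * cf[, 2]),
             ci_high = exp(cf[, 1] + z * cf[, 2]),
             p = cf[, 4], row.names = NULL)
}

#' Fit the block-wise logistic referral model
#'
#' Implements the three-stage procedure used to identify factors
#' independently associated with referral to spinal specialist services:
#' \enumerate{
#'   \item univariable logistic regression of the outcome on each candidate
#'     factor within each domain block;
#'   \item a collinearity screen per block (pairwise correlation > `cor_threshold`
#'     drops one of the pair; VIF > `vif_limit` flags the rest), followed by a
#'     within-block multivariable model; factors with a joint Wald p below
#'     `alpha` progress (a single-variable block progresses on its
#'     univariable result);
#'   \item an overall multivariable model over all block survivors, with
#'     backward elimination of the least-significant term while any term has
#'     Wald p >= `alpha` (strict: p exactly `alpha` is eliminated).
#' }
#' Factors with separated (non-finite) estimates are excluded from the
#' multivariable stages and recorded. Analysis is complete-case over the
#' candidate variables and outcome. Every candidate receives exactly one
#' final disposition in the selection trace.
#'
#' @param data A prepared cohort (see [prepare_cohort()]).
#' @param blocks Named list of candidate variable names per domain;
#'   default [atlas_blocks()].
#' @param outcome Name of the binary outcome column (default "referred").
#' @param alpha Significance level for retention (default 0.05).
#' @param cor_threshold,vif_limit Collinearity screen settings.
#' @param force_keep Named list (block name -> variables) of collinearity
#'   survivors forced on clinical grounds; default keeps current leg pain in
#'   the pain block, mirroring the clinical override used in development.
#' @return Object of class `"referral_model"`: list with `fit` (the final
#'   [stats::glm]), `trace` (data frame: variable, block, disposition,
#'   detail), `univariable`, `block_models`, `screen`, `elimination`,
#'   `n_used`, `call`.
#' @export
referral_model <- function(data, blocks = atlas_blocks(), outcome = "referred",
                           alpha = 0.05, cor_threshold = 0.7, vif_limit = 5,
                           force_keep = list(pain = "leg_pain_current")) {
  cl <- match.call()
  vars <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(vars))
    stop("blocks must partition the candidate list; duplicated: ",
         vars[duplicated(vars)][1], call. = FALSE)
  missing_cols <- setdiff(c(vars, outcome), names(data))
  if (length(missing_cols) > 0)
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cc <- stats::complete.cases(data[, c(vars, outcome)])
  d <- data[cc, , drop = FALSE]
  d[[outcome]] <- as.integer(as.logical(d[[outcome]]))

  trace <- data.frame(variable = vars,
                      block = rep(names(blocks), lengths(blocks)),
                      disposition = NA_character_, detail = NA_character_)
  set_disp <- function(v, disp, detail = "") {
    trace[trace$variable %in% v, c("disposition", "detail")] <<-
      list(disp, detail)
  }

  uni_fit <- function(v) stats::glm(stats::reformulate(v, outcome),
                                    family = stats::binomial(), data = d)
  univariable <- lapply(stats::setNames(vars, vars), function(v) {
    fit <- uni_fit(v)
    list(table = glm_or_table(fit), wald = term_wald(fit),
         separated = is_separated(fit))
  })

  screens <- list()
  block_models <- list()
  survivors <- character()
  for (bn in names(blocks)) {
    bv <- blocks[[bn]]
    sep <- bv[vapply(bv, function(v) univariable[[v]]$separated, logical(1))]
    set_disp(sep, "excluded", "separation in univariable fit")
    bv <- setdiff(bv, sep)
    if (length(bv) == 0) next
    if (length(bv) == 1) {
      # single-variable block: stage 2 is the univariable result unchanged
      p <- univariable[[bv]]$wald$p
      if (p < alpha) survivors <- c(survivors, bv)
      else set_disp(bv, "dropped", sprintf("within-block p = %.3f", p))
      next
    }
    scr <- collinearity_screen(d, bv, threshold = cor_threshold,
                               vif_limit = vif_limit,
                               force_keep = force_keep[[bn]] %||% character())
    screens[[bn]] <- scr
    for (i in seq_len(nrow(scr$dropped)))
      set_disp(scr$dropped$variable[i], "dropped",
               sprintf("collinearity: %s (%.2f)", scr$dropped$reason[i],
                       scr$dropped$value[i]))
    bv <- scr$retained
    if (length(bv) == 0) next
    if (length(bv) == 1) {
      p <- univariable[[bv]]$wald$p
      if (p < alpha) survivors <- c(survivors, bv)
      else set_disp(bv, "dropped", sprintf("within-block p = %.3f", p))
      next
    }
    bfit <- stats::glm(stats::reformulate(bv, outcome),
                       family = stats::binomial(), data = d)
    block_models[[bn]] <- bfit
    tw <- term_wald(bfit)
    keep <- tw$term[!is.na(tw$p) & tw$p < alpha]
    drop <- setdiff(bv, keep)
    set_disp(drop, "dropped", "within-block p >= alpha")
    survivors <- c(survivors, keep)
  }

  if (length(survivors) == 0)
    stop("no factor survived the within-block stage", call. = FALSE)

  current <- survivors
  elimination <- data.frame(variable = character(), p = numeric())
  repeat {
    fit <- stats::glm(stats::reformulate(current, outcome),
                      family = stats::binomial(), data = d)
    tw <- term_wald(fit)
    if (all(tw$p < alpha, na.rm = TRUE) || length(current) == 1 &&
        tw$p[1] < alpha) break
    worst <- tw$term[which.max(tw$p)]
    elimination <- rbind(elimination,
                         data.frame(variable = worst, p = max(tw$p, na.rm = TRUE)))
    set_disp(worst, "dropped", sprintf("final-model p = %.3f", max(tw$p, na.rm = TRUE)))
    current <- setdiff(current, worst)
    if (length(current) == 0)
      stop("backward elimination removed every factor", call. = FALSE)
  }
  set_disp(current, "retained", "final model")

  out <- list(fit = fit, trace = trace, univariable = univariable,
              block_models = block_models, screen = screens,
              elimination = elimination, retained = current,
              outcome = outcome, alpha = alpha, n_used = nrow(d),
              data = d, call = cl)
  class(out) <- "referral_model"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.referral_model <- function(x, ...) {
  cat("Block-wise logistic referral model\n")
  cat(sprintf("  complete cases used: %d (%d events)\n", x$n_used,
              sum(x$data[[x$outcome]])))
  cat("  retained factors:", paste(x$retained, collapse = ", "), "\n")
  tab <- glm_or_table(x$fit)
  cat("\nAdjusted odds ratios (final model):\n")
  print(data.frame(term = tab$term,
                   OR = sprintf("%.2f (%.2f, %.2f)", tab$or, tab$ci_low,
                                tab$ci_high),
                   p = signif(tab$p, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.referral_model <- function(object, ...) {
  cat("Selection trace:\n")
  print(object$trace, row.names = FALSE)
  cat("\n")
  print(object)
  invisible(object$trace)
}

#' @export
coef.referral_model <- function(object, ...) stats::coef(object$fit)

#' Predicted referral probabilities or linear predictor
#'
#' @param object A fitted [referral_model()].
#' @param newdata Optional prepared cohort; defaults to the development data.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... Unused.
#' @export
predict.referral_model <- function(object, newdata = NULL,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stats::predict(object$fit, type = type)
  else stats::predict(object$fit, newdata = newdata, type = type)
}

#' @export
residuals.referral_model <- function(object, ...) stats::residuals(object$fit, ...)

#' ROC curve of the fitted referral model
#'
#' @param x A fitted [referral_model()].
#' @param ... Passed to [pROC::plot.roc].
#' @export
plot.referral_model <- function(x, ...) {
  r <- pROC::roc(response = x$data[[x$outcome]],
                 predictor = stats::predict(x$fit, type = "link"),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pROC::plot.roc(r, print.auc = TRUE, ...)
  invisible(r)
}
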