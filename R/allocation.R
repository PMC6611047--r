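#' Allocate patients to the three matched-care-pathway groups
#'
#' The subgrouping algorithm combines STarT Back prognostic risk with the
#' count of the four clinical characteristics: low-risk patients go to
#' group 1 irrespective of characteristics; high-risk patients with three or
#' more characteristics, and medium-risk patients with all four, go to
#' group 3 (fast-track referral); everyone else goes to group 2.
#'
#' Indeterminate characteristics are tolerated when they cannot change the
#' group (low risk always allocates; a high-risk patient with three flags
#' already TRUE allocates to group 3 even if the fourth is missing); when
#' the missing flag could tip the decision the allocation is refused (NA).
#'
#' @param risk_class Factor/character vector in {"low","medium","high"}.
#' @param characteristics Data frame of the four logical flags as produced
#'   by [derive_characteristics()] (columns `c_impact`, `c_leg_pain`,
#'   `c_sensory`, `c_below_knee`), or an integer vector of characteristic
#'   counts 0-4.
#' @return Integer vector of groups (1, 2, 3; NA where refused).
#' @export
allocate <- function(risk_class, characteristics) {
  risk <- as.character(risk_class)
  bad <- !is.na(risk) & !(risk %in% c("low", "medium", "high"))
  if (any(bad)) stop("invalid risk class: ", unique(risk[bad])[1], call. = FALSE)
  if (is.data.frame(characteristics)) {
    flags <- as.matrix(characteristics[, c("c_impact", "c_leg_pain",
                                           "c_sensory", "c_below_knee")])
    lo <- rowSums(flags, na.rm = TRUE)                    # confirmed TRUE
    hi <- lo + rowSums(is.na(flags))                      # upper bound
  } else {
    cnt <- as.integer(characteristics)
    if (any(!is.na(cnt) & (cnt < 0L | cnt > 4L)))
      stop("characteristic count must be in 0..4", call. = FALSE)
    lo <- hi <- cnt
  }
  n <- length(risk)
  group <- rep(NA_integer_, n)
  group[risk == "low"] <- 1L
  high <- !is.na(risk) & risk == "high"
  med <- !is.na(risk) & risk == "medium"
  # group 3 when the threshold is met on confirmed flags; group 2 when even
  # the upper bound cannot reach it; otherwise indeterminate.
  group[high & !is.na(lo) & lo >= 3L] <- 3L
  group[high & !is.na(hi) & hi < 3L] <- 2L
  group[med & !is.na(lo) & lo == 4L] <- 3L
  group[med & !is.na(hi) & hi < 4L] <- 2L
  group
}

#' Define a fast-track scenario rule
#'
#' A scenario rule is a predicate over (STarT Back risk class,
#' characteristic count) that decides who is fast-tracked to specialist
#' services. The three development scenarios are:
#' `scenario_rule("S1", overall_min = 3, low_risk_excluded = FALSE)`,
#' `scenario_rule("S2", overall_min = 4, low_risk_excluded = FALSE)`, and
#' `scenario_rule("S3", high_min = 3, medium_min = 4)` — the last being the
#' adopted algorithm (its fast-track set is exactly allocation group 3).
#'
#' @param rule_id Label for the rule.
#' @param overall_min Minimum characteristic count regardless of risk class
#'   (NULL to disable).
#' @param high_min,medium_min Per-risk-class minimum counts (NULL = that
#'   class is never fast-tracked by this clause).
#' @param low_risk_excluded When TRUE (default), low-risk patients are never
#'   fast-tracked but remain in every denominator.
#' @return Object of class `"scenario_rule"` with a vectorized `predicate(risk, count)`.
#' @export
scenario_rule <- function(rule_id, overall_min = NULL, high_min = NULL,
                          medium_min = NULL, low_risk_excluded = TRUE) {
  for (v in list(overall_min, high_min, medium_min))
    if (!is.null(v) && (v < 0 || v > 4))
      stop("characteristic-count thresholds must be in 0..4", call. = FALSE)
  predicate <- function(risk, count) {
    risk <- as.character(risk)
    ft <- rep(FALSE, length(risk))
    if (!is.null(overall_min)) ft <- ft | count >= overall_min
    if (!is.null(high_min)) ft <- ft | (risk == "high" & count >= high_min)
    if (!is.null(medium_min)) ft <- ft | (risk == "medium" & count >= medium_min)
    if (low_risk_excluded) ft[risk == "low"] <- FALSE
    ft
  }
  structure(list(rule_id = rule_id, overall_min = overall_min,
                 high_min = high_min, medium_min = medium_min,
                 low_risk_excluded = low_risk_excluded,
                 predicate = predicate),
            class = "scenario_rule")
}

#' Classification metrics from a fast-track confusion table
#'
#' @param tp,fp,fn,tn Confusion-table counts: predicted fast-track vs
#'   observed referral.
#' @return Object of class `"rule_metrics"`: sensitivity, specificity, PPV,
#'   NPV (each a proportion with Wilson 95% CI), `fraction_fast_tracked`,
#'   and the confusion counts. Metrics whose denominator is zero are NA and
#'   flagged in `undefined`.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  met <- function(x, d) if (d == 0) c(estimate = NA, lower = NA, upper = NA)
                        else wilson_ci(x, d)
  undefined <- character()
  if (tp + fn == 0) undefined <- c(undefined, "sensitivity")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  if (tp + fp == 0) undefined <- c(undefined, "ppv")
  if (tn + fn == 0) undefined <- c(undefined, "npv")
  out <- list(sensitivity = met(tp, tp + fn),
              specificity = met(tn, tn + fp),
              ppv = met(tp, tp + fp),
              npv = met(tn, tn + fn),
              fraction_fast_tracked = met(tp + fp, n),
              confusion = counts, n = n, undefined = undefined)
  class(out) <- "rule_metrics"
  out
}

#' Evaluate a fast-track scenario rule on a cohort
#'
#' Applies the rule's predicate to each complete-case patient and tabulates
#' predicted fast-track against observed referral. Patients with
#' indeterminate characteristics, missing risk class, or missing outcome are
#' excluded (complete-case) and counted in the result. Low-risk patients are
#' retained in all denominators even when the rule never fast-tracks them.
#'
#' @param rule A [scenario_rule()].
#' @param data Prepared cohort with `sb_risk`, `n_characteristics`, and the
#'   outcome column.
#' @param outcome Outcome column name (default "referred").
#' @return A `"rule_metrics"` object (see [classification_metrics()]) with
#'   the rule and `n_excluded` attached.
#' @export
evaluate_rule <- function(rule, data, outcome = "referred") {
  stopifnot(inherits(rule, "scenario_rule"))
  risk <- data$sb_risk
  count <- data$n_characteristics
  y <- as.logical(data[[outcome]])
  ok <- !is.na(risk) & !is.na(count) & !is.na(y)
  risk <- risk[ok]; count <- count[ok]; y <- y[ok]
  if (sum(y) == 0)
    warning("no observed referrals: sensitivity undefined")
  ft <- rule$predicate(risk, count)
  out <- classification_metrics(tp = sum(ft & y), fp = sum(ft & !y),
                                fn = sum(!ft & y), tn = sum(!ft & !y))
  out$rule <- rule
  out$n_excluded <- sum(!ok)
  out
}

#' @export
print.rule_metrics <- function(x, ...) {
  if (!is.null(x$rule)) cat(sprintf("Scenario rule '%s'\n", x$rule$rule_id))
  cat(sprintf("Fast-track classification on n = %d (TP %d, FP %d, FN %d, TN %d)\n",
              x$n, x$confusion[["tp"]], x$confusion[["fp"]],
              x$confusion[["fn"]], x$confusion[["tn"]]))
  line <- function(lbl, m) {
    if (is.na(m[["estimate"]])) cat(sprintf("  %-22s undefined\n", lbl))
    else cat(sprintf("  %-22s %s%% (%s-%s)\n", lbl, fmt_pct(m[["estimate"]]),
                     fmt_pct(m[["lower"]]), fmt_pct(m[["upper"]])))
  }
  line("sensitivity", x$sensitivity)
  line("specificity", x$specificity)
  line("PPV", x$ppv)
  line("NPV", x$npv)
  line("fast-tracked", x$fraction_fast_tracked)
  if (!is.null(x$n_excluded) && x$n_excluded > 0)
    cat(sprintf("  excluded (incomplete): %d\n", x$n_excluded))
  invisible(x)
}

#' Descriptive summaries by allocation group
#'
#' Per-group sample sizes with means/SDs for continuous variables and
#' counts/percentages for categorical ones, complete-case per variable.
#' Empty groups are reported with n = 0 and NA statistics.
#'
#' @param data Prepared cohort.
#' @param group Integer allocation vector (from [allocate()]).
#' @param continuous,categorical Character vectors of column names to
#'   summarize; defaults cover the key baseline characteristics.
#' @return Object of class `"group_summary"`: list with `n` (named vector),
#'   `continuous` (variable, group, n, mean, sd) and `categorical`
#'   (variable, level, group, count, pct).
#' @export
group_summary <- function(data, group,
                          continuous = c("age", "back_pain_current",
                                         "leg_pain_current",
                                         "pain_self_efficacy", "rmdq_total"),
                          categorical = c("sex", "pain_below_knee",
                                          "leg_worse_than_back",
                                          "duration_category",
                                          "myotomal_weakness", "c_sensory",
                                          "neural_tension_positive")) {
  if ("rmdq_total" %in% continuous && !"rmdq_total" %in% names(data)) {
    rm_cols <- grep("^rmdq_[0-9]+$", names(data), value = TRUE)
    if (length(rm_cols) > 0) data$rmdq_total <- rowSums(data[, rm_cols])
    else continuous <- setdiff(continuous, "rmdq_total")
  }
  continuous <- intersect(continuous, names(data))
  categorical <- intersect(categorical, names(data))
  g <- factor(group, levels = 1:3)
  n <- table(g, useNA = "no")
  cont <- do.call(rbind, lapply(continuous, function(v) {
    do.call(rbind, lapply(levels(g), function(gg) {
      x <- data[[v]][!is.na(g) & g == gg]
      x <- x[!is.na(x)]
      data.frame(variable = v, group = as.integer(gg), n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }))
  }))
  cat_rows <- do.call(rbind, lapply(categorical, function(v) {
    x <- data[[v]]
    if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE))
    x <- as.factor(x)
    do.call(rbind, lapply(levels(g), function(gg) {
      xx <- x[!is.na(g) & g == gg]
      xx <- xx[!is.na(xx)]
      tab <- table(xx)
      data.frame(variable = v, level = names(tab), group = as.integer(gg),
                 count = as.integer(tab),
                 pct = if (length(xx)) 100 * as.integer(tab) / length(xx)
                       else NA_real_)
    }))
  }))
  structure(list(n = stats::setNames(as.integer(n), levels(g)),
                 continuous = cont, categorical = cat_rows),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 1, ...) {
  cat("Allocation group sizes:",
      paste(sprintf("group %s: %d", names(x$n), x$n), collapse = ", "), "\n")
  cat("\nContinuous (mean (SD)):\n")
  wide <- stats::reshape(
    transform(x$continuous,
              cell = ifelse(is.na(mean), "-",
                            sprintf("%.*f (%.*f)", digits, mean, digits, sd))),
    idvar = "variable", timevar = "group", direction = "wide",
    drop = c("n", "mean", "sd"))
  print(wide, row.names = FALSE)
  invisible(x)
}
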