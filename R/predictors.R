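#' Apply the diagnostic-confidence eligibility filter
#'
#' Retains patients whose assessing clinician reported diagnostic confidence
#' of 70% or more (inclusive bound). Records with missing confidence are
#' excluded and counted separately.
#'
#' @param cohort Cohort data frame with a `diagnostic_confidence` column
#'   (0-100).
#' @return A list of class `"eligibility_report"` with elements `eligible`
#'   (the retained data frame), `n_screened`, `n_eligible`, and `excluded`,
#'   a data frame of exclusion reasons and counts.
#' @export
filter_eligible <- function(cohort) {
  if (!"diagnostic_confidence" %in% names(cohort))
    stop("cohort has no 'diagnostic_confidence' column", call. = FALSE)
  conf <- cohort$diagnostic_confidence
  keep <- !is.na(conf) & conf >= 70
  excluded <- data.frame(
    reason = c("confidence below 70", "confidence missing"),
    n = c(sum(!is.na(conf) & conf < 70), sum(is.na(conf)))
  )
  out <- list(eligible = cohort[keep, , drop = FALSE],
              n_screened = nrow(cohort),
              n_eligible = sum(keep),
              excluded = excluded)
  class(out) <- "eligibility_report"
  out
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility filter (diagnostic confidence >= 70%)\n")
  cat(sprintf("  screened: %d, eligible: %d\n", x$n_screened, x$n_eligible))
  for (i in seq_len(nrow(x$excluded)))
    cat(sprintf("  excluded - %s: %d\n", x$excluded$reason[i], x$excluded$n[i]))
  invisible(x)
}

#' Sciatica bothersomeness composite score
#'
#' Sum of the four bothersomeness items (leg pain, paraesthesia, weakness,
#' pain while sitting), each scored 0-6, giving a 0-24 composite.
#'
#' @param leg,paraesthesia,weakness,sitting Integer vectors in 0-6.
#' @return Integer vector of composite scores (NA where any item is NA).
#' @export
bothersomeness_composite <- function(leg, paraesthesia, weakness, sitting) {
  items <- list(leg = leg, paraesthesia = paraesthesia,
                weakness = weakness, sitting = sitting)
  for (nm in names(items)) {
    v <- items[[nm]]
    if (any(!is.na(v) & (v < 0 | v > 6)))
      stop("bothersomeness item '", nm, "' outside 0-6", call. = FALSE)
  }
  as.integer(leg + paraesthesia + weakness + sitting)
}

#' Derive the four clinical referral characteristics
#'
#' The four binary characteristics used by the subgrouping algorithm:
#' \describe{
#'   \item{c_impact}{pain interferes with ability to do work/home activities:
#'     work-interference NRS > 6 for patients in work, otherwise a "yes" on
#'     the RMDQ jobs-around-the-house item. A patient in work whose NRS is
#'     missing falls back to the RMDQ item.}
#'   \item{c_leg_pain}{current leg pain intensity NRS > 6 (strict).}
#'   \item{c_sensory}{sensory deficit on pin-prick testing (reduced or loss).}
#'   \item{c_below_knee}{pain radiating below the knee.}
#' }
#' A characteristic whose source field is missing is left indeterminate (NA)
#' and the record is flagged for complete-case exclusion downstream.
#'
#' @param cohort Cohort data frame carrying `in_work`, `work_interference`,
#'   the RMDQ house item (`rmdq_06`), `leg_pain_current`,
#'   `pinprick_sensation`, and `pain_below_knee`.
#' @return Data frame with logical columns `c_impact`, `c_leg_pain`,
#'   `c_sensory`, `c_below_knee`, integer `n_characteristics` (count of TRUE
#'   flags; NA if any flag indeterminate) and logical `cc_indeterminate`.
#' @export
derive_characteristics <- function(cohort) {
  need <- c("in_work", "work_interference", "rmdq_06", "leg_pain_current",
            "pinprick_sensation", "pain_below_knee")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rmdq_yes <- as.logical(cohort$rmdq_06)
  wi <- cohort$work_interference
  in_work <- as.logical(cohort$in_work)

  c_impact <- ifelse(!is.na(in_work) & in_work & !is.na(wi), wi > 6, NA)
  fall_back <- is.na(c_impact)
  c_impact[fall_back] <- rmdq_yes[fall_back]

  c_leg_pain <- cohort$leg_pain_current > 6
  pin <- as.character(cohort$pinprick_sensation)
  bad <- !is.na(pin) & !(pin %in% c("normal", "reduced", "loss"))
  if (any(bad))
    stop("invalid pinprick_sensation value: ", unique(pin[bad])[1], call. = FALSE)
  c_sensory <- ifelse(is.na(pin), NA, pin %in% c("reduced", "loss"))
  c_below_knee <- as.logical(cohort$pain_below_knee)

  flags <- cbind(c_impact, c_leg_pain, c_sensory, c_below_knee)
  n_char <- as.integer(rowSums(flags))
  data.frame(c_impact = as.logical(c_impact),
             c_leg_pain = c_leg_pain,
             c_sensory = as.logical(c_sensory),
             c_below_knee = c_below_knee,
             n_characteristics = n_char,
             cc_indeterminate = apply(flags, 1, anyNA))
}

#' Attach all derived analysis columns to a cohort
#'
#' Convenience wrapper used throughout the pipeline: scores the STarT Back
#' tool (`sb_total`, `sb_psych`, `sb_risk`), derives the four clinical
#' characteristics, and adds the bothersomeness composite. Categorical
#' examination fields are converted to factors with their clinical reference
#' level first ("normal").
#'
#' Records with incomplete STarT Back items are tolerated here (scored NA)
#' because downstream analyses are complete-case; use [score_startback()]
#' directly when a hard refusal is wanted.
#'
#' @param cohort Cohort data frame in the canonical schema
#'   (see [cohort_schema()]).
#' @return The cohort with derived columns appended.
#' @export
prepare_cohort <- function(cohort) {
  sb_cols <- paste0("sb_", 1:9)
  sb <- cohort[, sb_cols]
  complete <- stats::complete.cases(sb)
  scored <- data.frame(sb_total = rep(NA_integer_, nrow(cohort)),
                       sb_psych = rep(NA_integer_, nrow(cohort)),
                       sb_risk = factor(rep(NA_character_, nrow(cohort)),
                                        levels = c("low", "medium", "high"),
                                        ordered = TRUE))
  if (any(complete)) scored[complete, ] <- score_startback(sb[complete, ])
  chars <- derive_characteristics(cohort)
  out <- cbind(cohort, scored, chars)
  out$both_composite <- bothersomeness_composite(
    cohort$both_leg, cohort$both_paraesthesia,
    cohort$both_weakness, cohort$both_sitting)
  out$pinprick_sensation <- factor(out$pinprick_sensation,
                                   levels = c("normal", "reduced", "loss"))
  out$reflex_status <- factor(out$reflex_status,
                              levels = c("normal", "slightly reduced",
                                         "absent", "significantly reduced"))
  out$duration_category <- factor(out$duration_category,
                                  levels = c("<6 weeks", "6 weeks-3 months",
                                             ">3 months"))
  out
}
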