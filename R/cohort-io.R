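#' Canonical cohort column schema
#'
#' One row per column of the cohort file: name, storage type, and the
#' permitted range or level set. The on-disk format is comma-separated text
#' with a header row and empty cells for missing values.
#'
#' @return Data frame with columns `column`, `type` ("integer", "logical",
#'   "character"), `min`, `max`, `levels` (comma-joined, "" if free text).
#' @export
cohort_schema <- function() {
  rng <- function(column, min, max)
    data.frame(column = column, type = "integer", min = min, max = max,
               levels = "")
  lgl <- function(column)
    data.frame(column = column, type = "logical", min = NA, max = NA,
               levels = "")
  chr <- function(column, levels)
    data.frame(column = column, type = "character", min = NA, max = NA,
               levels = paste(levels, collapse = "|"))
  rbind(
    chr("patient_id", character()),
    rng("age", 0, 120),
    chr("sex", c("female", "male")),
    lgl("in_work"),
    rng("work_interference", 0, 10),
    rng("leg_pain_current", 0, 10),
    rng("leg_pain_usual", 0, 10),
    rng("back_pain_current", 0, 10),
    rng("back_pain_usual", 0, 10),
    lgl("pain_below_knee"),
    lgl("leg_worse_than_back"),
    lgl("tingling_numbness"),
    lgl("cough_sneeze_positive"),
    lgl("myotomal_weakness"),
    lgl("neural_tension_positive"),
    do.call(rbind, lapply(sprintf("rmdq_%02d", 1:24), rng, min = 0, max = 1)),
    do.call(rbind, lapply(paste0("sb_", 1:8), rng, min = 0, max = 1)),
    chr("sb_9", startback_item9_levels),
    rng("both_leg", 0, 6),
    rng("both_paraesthesia", 0, 6),
    rng("both_weakness", 0, 6),
    rng("both_sitting", 0, 6),
    rng("pain_self_efficacy", 0, 60),
    rng("illness_identity", 0, 10),
    chr("duration_category", c("<6 weeks", "6 weeks-3 months", ">3 months")),
    chr("reflex_status", c("normal", "slightly reduced", "absent",
                           "significantly reduced")),
    chr("pinprick_sensation", c("normal", "reduced", "loss")),
    rng("diagnostic_confidence", 0, 100),
    lgl("referred")
  )
}

#' Write a cohort to a comma-separated file
#'
#' Missing values are written as empty cells; logical fields as TRUE/FALSE.
#' Round-trips losslessly through [read_cohort()].
#'
#' @param cohort Cohort data frame in the canonical schema.
#' @param destination File path.
#' @export
write_cohort <- function(cohort, destination) {
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(cohort[, sch$column], destination, row.names = FALSE,
                   na = "")
}

#' Read and validate a cohort file
#'
#' Reads the comma-separated cohort format, enforcing the canonical schema:
#' unknown or absent columns, out-of-range values, and invalid level labels
#' are schema errors naming the offending row and column. Empty cells load
#' as missing values and are tallied in a load report attached as the
#' `"load_report"` attribute (a data frame of per-column missing counts).
#'
#' @param source File path.
#' @return Cohort data frame with a `"load_report"` attribute.
#' @export
read_cohort <- function(source) {
  sch <- cohort_schema()
  header <- names(utils::read.csv(source, nrows = 1, check.names = FALSE))
  unknown <- setdiff(header, sch$column)
  if (length(unknown) > 0)
    stop("schema error: unknown column '", unknown[1], "'", call. = FALSE)
  absent <- setdiff(sch$column, header)
  if (length(absent) > 0)
    stop("schema error: missing column '", absent[1], "'", call. = FALSE)
  classes <- stats::setNames(
    c(integer = "integer", logical = "logical",
      character = "character")[sch$type], sch$column)
  d <- utils::read.csv(source, na.strings = "", colClasses = classes[header],
                       check.names = FALSE)
  d <- d[, sch$column]
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    v <- d[[col]]
    bad <- rep(FALSE, length(v))
    if (sch$type[i] == "integer" && !is.na(sch$min[i]))
      bad <- !is.na(v) & (v < sch$min[i] | v > sch$max[i])
    if (sch$type[i] == "character" && nzchar(sch$levels[i])) {
      lev <- strsplit(sch$levels[i], "|", fixed = TRUE)[[1]]
      bad <- !is.na(v) & !(v %in% lev)
    }
    if (any(bad))
      stop(sprintf("schema error in column '%s', row %d: value '%s' out of range",
                   col, which(bad)[1], v[which(bad)[1]]), call. = FALSE)
  }
  report <- data.frame(column = sch$column,
                       n_missing = vapply(sch$column,
                                          function(cl) sum(is.na(d[[cl]])),
                                          integer(1)))
  # work_interference is structurally absent for patients not in work;
  # only count it as missing where it was expected
  expected <- is.na(d$in_work) | d$in_work
  report$n_missing[report$column == "work_interference"] <-
    sum(is.na(d$work_interference[expected]))
  attr(d, "load_report") <- report[report$n_missing > 0, , drop = FALSE]
  d
}
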