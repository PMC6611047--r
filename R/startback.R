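#' Response levels of STarT Back item 9
#'
#' The bothersomeness item of the 9-item STarT Back tool is answered on a
#' five-point scale; it scores 1 when the response is "very much" or
#' "extremely", 0 otherwise.
#'
#' @export
startback_item9_levels <- c("not at all", "slightly", "moderately",
                            "very much", "extremely")

# Dichotomize item 9: accepts the level labels, a factor on them, or an
# integer code 0..4 in the order of `startback_item9_levels`.
score_item9 <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !is.na(x) & !(x %in% startback_item9_levels)
    if (any(bad)) {
      stop("invalid STarT Back item 9 response: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    idx <- match(x, startback_item9_levels) - 1L
  } else {
    idx <- as.integer(x)
    if (any(!is.na(idx) & (idx < 0L | idx > 4L)))
      stop("STarT Back item 9 code must be in 0..4", call. = FALSE)
  }
  as.integer(idx >= 3L)
}

#' Score the 9-item STarT Back tool and classify prognostic risk
#'
#' Items 1-8 are binary (disagree = 0, agree = 1); item 9 is the five-level
#' bothersomeness item, scored 1 for "very much" or "extremely". The total
#' score is the sum of the nine dichotomized items (0-9) and the
#' psychological subscore is the sum of items 5-9 (0-5). Risk is classified
#' as low when the total score is 3 or less, high when the psychological
#' subscore is 4 or more, and medium otherwise. (A psychological subscore of
#' 4 or more forces a total of at least 4, so the two rules never conflict.)
#'
#' Incomplete item sets are refused: there is no imputation, and the error
#' names the offending item and row.
#'
#' @param items Either a data frame / matrix with nine columns (items 1-8
#'   binary, item 9 a level from [startback_item9_levels] or an integer code
#'   0-4), or a single patient's vector of nine responses.
#' @return A data frame with one row per patient: `sb_total` (0-9),
#'   `sb_psych` (0-5), and `sb_risk`, an ordered factor low < medium < high.
#' @examples
#' score_startback(c(1, 1, 0, 0, 1, 1, 1, 0, "very much"))
#' @export
score_startback <- function(items) {
  if (is.null(dim(items))) items <- as.data.frame(as.list(items))
  items <- as.data.frame(items)
  if (ncol(items) != 9)
    stop("expected 9 STarT Back items, got ", ncol(items), call. = FALSE)
  bin <- items[, 1:8]
  bin[] <- lapply(bin, function(col) {
    col <- if (is.logical(col)) as.integer(col) else as.integer(as.character(col))
    if (any(!is.na(col) & !(col %in% c(0L, 1L))))
      stop("STarT Back items 1-8 must be 0/1", call. = FALSE)
    col
  })
  i9 <- score_item9(items[[9]])
  scored <- cbind(as.matrix(bin), item9 = i9)
  miss <- which(is.na(scored), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf("STarT Back scoring refused: item %d missing for row %d",
                 miss[1, "col"], miss[1, "row"]), call. = FALSE)
  }
  total <- as.integer(rowSums(scored))
  psych <- as.integer(rowSums(scored[, 5:9, drop = FALSE]))
  risk <- ifelse(total <= 3L, "low", ifelse(psych >= 4L, "high", "medium"))
  data.frame(sb_total = total, sb_psych = psych,
             sb_risk = factor(risk, levels = c("low", "medium", "high"),
                              ordered = TRUE))
}
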