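#' Odds ratio from a 2x2 contingency table
#'
#' Computes the cross-product odds ratio (a*d)/(b*c) with a Wald 95%
#' confidence interval, exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)),
#' and a Wald p-value. When any single cell is zero the Haldane-Anscombe
#' correction (0.5 added to all four cells) is applied and flagged; a whole
#' zero row or column leaves the odds ratio undefined and is an error.
#'
#' @param a Exposed with outcome.
#' @param b Exposed without outcome.
#' @param c Unexposed with outcome.
#' @param d Unexposed without outcome.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `"odds_ratio"`: list with `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `continuity` (TRUE when the 0.5 correction was
#'   used) and the (uncorrected) cell counts.
#' @examples
#' odds_ratio_2x2(43, 14, 200, 172) # 2.64 (1.40, 4.99)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("odds ratio undefined: a whole row or column of the table is zero",
         call. = FALSE)
  continuity <- any(cells == 0)
  cc <- if (continuity) cells + 0.5 else cells
  log_or <- log(cc[["a"]]) + log(cc[["d"]]) - log(cc[["b"]]) - log(cc[["c"]])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(odds_ratio = exp(log_or),
              ci_low = exp(log_or - z * se),
              ci_high = exp(log_or + z * se),
              p_value = 2 * stats::pnorm(-abs(log_or / se)),
              continuity = continuity,
              cells = cells)
  class(out) <- "odds_ratio"
  out
}

#' @export
print.odds_ratio <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (95%% CI %.*f, %.*f), p = %.3g%s\n",
              digits, x$odds_ratio, digits, x$ci_low, digits, x$ci_high,
              x$p_value,
              if (x$continuity) " [Haldane-Anscombe 0.5 correction]" else ""))
  invisible(x)
}

# Type-appropriate pairwise correlation: Pearson for two numeric scales,
# point-biserial (numerically Pearson) when one is binary, Spearman when
# either is ordinal.
pairwise_correlation <- function(x, y) {
  ordinal <- function(v) is.ordered(v) || (is.factor(v) && nlevels(v) > 2)
  method <- if (ordinal(x) || ordinal(y)) "spearman" else "pearson"
  to_num <- function(v) {
    if (is.factor(v)) as.numeric(v) else if (is.logical(v)) as.numeric(v) else v
  }
  stats::cor(to_num(x), to_num(y), use = "complete.obs", method = method)
}

#' Collinearity screen: pairwise correlations then variance inflation
#'
#' Within a candidate set, computes type-appropriate pairwise correlations
#' (Pearson for numeric, Spearman for ordinal, point-biserial for binary);
#' while any pair exceeds the threshold in absolute value, one member is
#' dropped (never a variable in `force_keep`; otherwise the member more
#' correlated on average with the rest, ties broken by list order). Variance
#' inflation factors are then computed on the survivors and any above the
#' limit are flagged and dropped. Constant variables are dropped up front
#' with reason "zero variance".
#'
#' @param data Data frame of complete cases (rows with any NA in `vars` are
#'   removed).
#' @param vars Character vector of column names to screen (>= 1).
#' @param threshold Absolute correlation above which one of a pair is
#'   dropped (default 0.7, strict inequality).
#' @param vif_limit VIF above which a survivor is flagged as collinear
#'   (default 5, strict).
#' @param force_keep Variables never dropped in the correlation stage.
#' @return List with `retained` (character), `dropped` (data frame of
#'   variable, reason, value) and `vif` (named vector over the final
#'   retained set; NA when fewer than two survive).
#' @export
collinearity_screen <- function(data, vars, threshold = 0.7, vif_limit = 5,
                                force_keep = character()) {
  stopifnot(length(vars) >= 1, all(vars %in% names(data)))
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
               drop = FALSE]
  dropped <- data.frame(variable = character(), reason = character(),
                        value = numeric())
  constant <- vars[vapply(data[vars], function(v) length(unique(v[!is.na(v)])) < 2,
                          logical(1))]
  for (v in constant)
    dropped <- rbind(dropped, data.frame(variable = v, reason = "zero variance",
                                         value = NA_real_))
  retained <- setdiff(vars, constant)

  repeat {
    if (length(retained) < 2) break
    cm <- matrix(0, length(retained), length(retained),
                 dimnames = list(retained, retained))
    for (i in seq_along(retained)) for (j in seq_along(retained)) {
      if (i < j) cm[i, j] <- cm[j, i] <-
          pairwise_correlation(data[[retained[i]]], data[[retained[j]]])
    }
    amax <- max(abs(cm))
    if (is.na(amax) || amax <= threshold) break
    idx <- which(abs(cm) == amax, arr.ind = TRUE)[1, ]
    pair <- retained[sort(unname(idx))]  # keep list order: pair[1] is earlier
    victim <- if (pair[1] %in% force_keep && !(pair[2] %in% force_keep)) {
      pair[2]
    } else if (pair[2] %in% force_keep && !(pair[1] %in% force_keep)) {
      pair[1]
    } else {
      # drop the member with the larger mean absolute correlation to the rest
      ma <- rowMeans(abs(cm[pair, , drop = FALSE]))
      pair[which.max(ma + c(0, 1e-12))]  # tie -> later in list order
    }
    dropped <- rbind(dropped, data.frame(
      variable = victim, reason = "pairwise correlation", value = amax))
    retained <- setdiff(retained, victim)
  }

  vifs <- rep(NA_real_, length(retained))
  names(vifs) <- retained
  if (length(retained) >= 2) {
    mm <- data.frame(lapply(data[retained], function(v) {
      if (is.factor(v) || is.logical(v)) as.numeric(v) else v
    }))
    names(mm) <- retained
    mm$.y <- seq_len(nrow(mm))  # response irrelevant to VIF
    fit <- stats::lm(.y ~ ., data = mm)
    vifs <- car::vif(fit)[retained]
    high <- names(vifs)[vifs > vif_limit]
    for (v in high)
      dropped <- rbind(dropped, data.frame(variable = v,
                                           reason = "VIF", value = vifs[[v]]))
    retained <- setdiff(retained, high)
  }
  list(retained = retained, dropped = dropped, vif = vifs)
}
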