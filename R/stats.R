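#' Paired and unpaired Student's t tests
#'
#' Thin wrappers around [stats::t.test()] returning the statistic and
#' two-sided p-value, with explicit handling of degenerate inputs that the
#' underlying test rejects: identical paired samples (all differences zero)
#' return `t = 0, p = 1`; paired differences that are a nonzero constant
#' return `p = 0` with `degenerate = TRUE` (the location shift is known
#' exactly, the test statistic diverges).
#'
#' @param x,y Numeric vectors; equal length for the paired test, each of
#'   length >= 2.
#' @return List with `t`, `p_value`, `df`, `mean_diff` (paired) or
#'   `mean_x`/`mean_y` (unpaired), and `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    .stop_empredict("paired samples must have equal length", "empredict_insufficient_data")
  if (length(x) < 2)
    .stop_empredict("need at least 2 pairs", "empredict_insufficient_data")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p_value = 1, df = length(d) - 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' @rdname paired_t
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    .stop_empredict("need at least 2 observations per group",
                    "empredict_insufficient_data")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (eq) 1 else 0,
                df = NA_real_, mean_x = mean(x), mean_y = mean(y),
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_x = unname(tt$estimate[1]),
       mean_y = unname(tt$estimate[2]), degenerate = FALSE)
}

#' Pearson product-moment correlation
#'
#' Wrapper around [stats::cor.test()] (two-sided p from the t transform of
#' r) returning a compact result.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stop_empredict("need paired vectors of length >= 3", "empredict_insufficient_data")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' One-way ANOVA across groups
#'
#' Thin wrapper over [stats::aov()] for comparing mean values across
#' multiple conditions.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor.
#' @return List with `F`, `p_value`, `df_between`, `df_within`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    .stop_empredict("need at least 2 groups", "empredict_insufficient_data")
  s <- summary(stats::aov(values ~ groups))[[1]]
  list(F = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}

#' Empirical ROC analysis with Hanley-McNeil error and Youden cutoff
#'
#' Builds the empirical ROC of a continuous score against a binary outcome,
#' computes the trapezoidal AUC (identical to Mann-Whitney concordance with
#' half credit for ties), the Hanley-McNeil standard error, a normal 95%
#' confidence interval clipped to `[0, 1]`, and the operating point
#' maximizing the Youden index J = sensitivity + specificity - 1, with ties
#' broken toward higher sensitivity. Thresholds are placed midway between
#' adjacent distinct scores.
#'
#' @param scores Numeric scores (e.g. capacitated-sperm Em in mV).
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive class
#'   (e.g. successful IVF). Both classes must be present.
#' @param orientation `"lower"` when smaller scores indicate the positive
#'   class (the default: more-negative capacitated Em predicts success) or
#'   `"higher"`.
#' @param level Confidence level for the AUC interval.
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `se`, `ci95` (clipped), `cutoff`
#'   (in original score units), `sensitivity` and `specificity` (percent),
#'   `orientation`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_analysis(c(-60, -55, -42, -45, -40), c(TRUE, TRUE, TRUE, FALSE, FALSE))
roc_analysis <- function(scores, labels, orientation = c("lower", "higher"),
                         level = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) || any(is.na(labels)))
    .stop_empredict("scores and labels must be equal-length and complete",
                    "empredict_invalid_input")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    .stop_empredict("both classes must be present", "empredict_invalid_input")

  # orient so that HIGHER oriented score = more positive-like
  s <- if (orientation == "lower") -scores else scores

  # thresholds midway between adjacent distinct oriented scores, plus
  # sentinels giving the (0,0) and (1,1) corners
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  tp <- vapply(thr, function(t) sum(s[labels] > t), numeric(1))
  fp <- vapply(thr, function(t) sum(s[!labels] > t), numeric(1))
  ord <- order(fp, tp)  # from (0,0) at thr=Inf to (1,1) at thr=-Inf
  tp <- tp[ord]; fp <- fp[ord]
  pts <- data.frame(threshold = thr[ord], fpr = fp / n_neg, tpr = tp / n_pos)

  # trapezoid area over integer counts: twice the area in count units is an
  # integer, so the result is bit-identical to Mann-Whitney pair
  # concordance with half credit for ties
  k <- length(tp)
  num2 <- sum(diff(fp) * (tp[-1] + tp[-k]))
  auc <- (num2 / 2) / (n_pos * n_neg)

  # Hanley & McNeil (1982) standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  ci <- ci_from_auc(auc, se, level)

  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[which.max(pts$tpr[best])]  # tie-break toward sensitivity
  cut_oriented <- pts$threshold[best]
  cutoff <- if (orientation == "lower") -cut_oriented else cut_oriented

  structure(
    list(points = pts, auc = auc, se = se, ci95 = ci,
         cutoff = cutoff, sensitivity = 100 * pts$tpr[best],
         specificity = 100 * (1 - pts$fpr[best]),
         orientation = orientation, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<roc_result: AUC %.4f +/- %.3f (95%% CI %.4f-%.4f), n+ = %d, n- = %d>\n",
    "  cutoff %.2f (%s scores positive): sensitivity %.1f%%, specificity %.1f%%\n"),
    x$auc, x$se, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg,
    x$cutoff, x$orientation, x$sensitivity, x$specificity))
  invisible(x)
}

#' Clipped normal confidence interval for an AUC
#'
#' `auc +/- z * se`, with both bounds clipped to `[0, 1]` — an AUC interval
#' cannot extend past the unit limits, and published intervals with an
#' upper bound of exactly 1 arise from this clipping.
#'
#' @param auc Area under the curve.
#' @param se Standard error of the AUC.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' ci_from_auc(0.8571, 0.098)   # approx c(0.665, 1)
ci_from_auc <- function(auc, se, level = 0.95) {
  if (se < 0 || auc < 0 || auc > 1)
    .stop_empredict("need auc in [0,1] and se >= 0", "empredict_invalid_input")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}
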