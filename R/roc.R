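#' Empirical ROC curve of a continuous or ordinal marker
#'
#' Evaluates sensitivity and specificity at every distinct observed marker
#' value as candidate cutoff and computes the empirical AUC via the
#' Mann-Whitney statistic (ties counted one half), which is identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' Positivity is strict: for direction `"greater"` a patient is called
#' positive when the value exceeds the cutoff, for `"less"` when it falls
#' below it. With `direction = "auto"` the orientation giving AUC >= 0.5 is
#' chosen.
#'
#' @param values Numeric marker values.
#' @param labels Logical (or 0/1) outcome labels, `TRUE` = reclassified.
#'   Pairs with a missing value or label are dropped.
#' @param direction `"auto"`, `"greater"` (high values indicate
#'   reclassification) or `"less"`.
#' @param marker Marker name used in reports.
#' @return An object of class `"uev_roc"`: a list with `marker`,
#'   `direction`, `thresholds`, `sns_at`, `spc_at`, `auc`, `n1`, `n0`, and
#'   the DeLong placement values `v10`, `v01`.
#' @export
roc_curve <- function(values, labels,
                      direction = c("auto", "greater", "less"),
                      marker = "marker") {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present")

  auc_of <- function(w) {
    r <- rank(w, ties.method = "average")
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (direction == "auto")
    direction <- if (auc_of(values) >= 0.5) "greater" else "less"
  w <- if (direction == "greater") values else -values
  auc <- auc_of(w)

  # DeLong placements via midranks: v10[i] = P(control < case i) + .5 P(=)
  r_all <- rank(w, ties.method = "average")
  r_cas <- rank(w[labels], ties.method = "average")
  r_con <- rank(w[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r_cas) / n0
  v01 <- 1 - (r_all[!labels] - r_con) / n1

  # sensitivity/specificity at every distinct observed value (strict rule)
  thr <- sort(unique(values))
  s1 <- sort(values[labels])
  s0 <- sort(values[!labels])
  if (direction == "greater") {
    sns_at <- 1 - findInterval(thr, s1) / n1           # cases  >  t
    spc_at <- findInterval(thr, s0) / n0               # controls <= t
  } else {
    sns_at <- findInterval(thr, s1, left.open = TRUE) / n1  # cases  <  t
    spc_at <- 1 - findInterval(thr, s0, left.open = TRUE) / n0
  }

  structure(list(marker = marker, direction = direction, thresholds = thr,
                 sns_at = sns_at, spc_at = spc_at, auc = auc,
                 n1 = n1, n0 = n0, v10 = v10, v01 = v01),
            class = "uev_roc")
}

#' @export
print.uev_roc <- function(x, ...) {
  cat(sprintf("ROC curve for %s (direction: %s)\n", x$marker, x$direction))
  cat(sprintf("  AUC %.3f  (%d reclassified vs %d stable)\n",
              x$auc, x$n1, x$n0))
  invisible(x)
}

#' Confidence interval and p-value for an empirical AUC
#'
#' The default variance estimator is DeLong's (based on the placement
#' values); `"hanley"` gives the Hanley-McNeil approximation. The two-sided
#' p-value tests the null of no discrimination (AUC = 0.5) with the same
#' standard error.
#'
#' @param curve A [roc_curve()] object.
#' @param conf_level Confidence level, default 0.95.
#' @param method `"delong"` (default) or `"hanley"`.
#' @return A list with `auc_ci` (length-2, clipped to \[0, 1\]), `p_value`,
#'   `se`, and `degenerate` (`TRUE` when the variance estimate is zero, in
#'   which case CI and p are undefined).
#' @export
auc_inference <- function(curve, conf_level = 0.95,
                          method = c("delong", "hanley")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "uev_roc"))
  a <- curve$auc
  if (method == "delong") {
    v <- stats::var(curve$v10) / curve$n1 + stats::var(curve$v01) / curve$n0
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    v <- (a * (1 - a) + (curve$n1 - 1) * (q1 - a^2) +
            (curve$n0 - 1) * (q2 - a^2)) / (curve$n1 * curve$n0)
  }
  if (!is.finite(v) || v <= 0)
    return(list(auc_ci = c(NA_real_, NA_real_), p_value = NA_real_,
                se = 0, degenerate = TRUE))
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(a + c(-1, 1) * z * se, 0), 1)
  p <- 2 * stats::pnorm(-abs(a - 0.5) / se)
  list(auc_ci = ci, p_value = p, se = se, degenerate = FALSE)
}

#' Youden-index optimal cutoff
#'
#' Exhaustive search over all observed candidate cutoffs for the one
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken in
#' favour of the higher sensitivity (the screening context penalizes missed
#' reclassifications), then the lower cutoff.
#'
#' @param curve A [roc_curve()] object.
#' @return A list with `cutoff` (an observed marker value), `direction`,
#'   `youden_j`, `sns`, and `spc`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "uev_roc"))
  j <- curve$sns_at + curve$spc_at - 1
  # maximize in exact integer arithmetic (counts, not float fractions) so
  # mathematically tied cutoffs are treated as ties
  k <- round(curve$sns_at * curve$n1)       # true positives at cutoff
  m <- round(curve$spc_at * curve$n0)       # true negatives at cutoff
  score <- k * curve$n0 + m * curve$n1
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[k[best] == max(k[best])]
  if (length(best) > 1L) best <- best[which.min(curve$thresholds[best])]
  list(cutoff = curve$thresholds[best], direction = curve$direction,
       youden_j = j[best], sns = curve$sns_at[best], spc = curve$spc_at[best])
}

#' Dichotomize a marker at a fixed cutoff
#'
#' Strict positivity rule matching the reported cutoffs: `value > cutoff`
#' for direction `"greater"`, `value < cutoff` for `"less"`. A value equal
#' to the cutoff is negative either way.
#'
#' @param values Numeric marker values; missing values give missing
#'   indicators.
#' @param cutoff Cutoff value.
#' @param direction `"greater"` or `"less"`.
#' @return Logical indicator vector.
#' @export
dichotomize <- function(values, cutoff, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (is.na(cutoff)) stop("`cutoff` must be defined")
  if (direction == "greater") values > cutoff else values < cutoff
}
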