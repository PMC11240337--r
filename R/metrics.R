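#' Round half away from zero
#'
#' The tables' formatting convention (87.15 -> 87.2), unlike base
#' [round()]'s round-half-to-even. Internal values are never rounded; this
#' is for the report layer and for comparing against printed values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Cross-tabulate a binary indicator against the outcome
#'
#' @param indicators Logical marker/panel positivity per patient.
#' @param labels Logical outcome labels (`TRUE` = reclassified). Pairs with
#'   a missing entry are dropped.
#' @return An object of class `"uev_confusion"`: a list of counts `tp`
#'   (positive & reclassified), `fp` (positive & stable), `fn`, `tn`.
#' @export
confusion <- function(indicators, labels) {
  if (length(indicators) != length(labels))
    stop("`indicators` and `labels` must have equal length")
  indicators <- as.logical(indicators)
  labels <- as.logical(labels)
  keep <- !is.na(indicators) & !is.na(labels)
  indicators <- indicators[keep]
  labels <- labels[keep]
  structure(list(tp = sum(indicators & labels),
                 fp = sum(indicators & !labels),
                 fn = sum(!indicators & labels),
                 tn = sum(!indicators & !labels)),
            class = "uev_confusion")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `"uev_confusion"`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(as.list(counts), class = "uev_confusion")
}

#' @export
print.uev_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(c("marker positive", "marker negative"),
                              c("reclassified", "stable")))
  print(m)
  invisible(x)
}

#' Seven-metric diagnostic accuracy summary of a 2x2 table
#'
#' Sensitivity, specificity, predictive values, likelihood ratios, and
#' accuracy. Metrics with a zero denominator are reported as `NA`; an
#' infinite positive likelihood ratio (perfect specificity) is reported as
#' `Inf` and flagged.
#'
#' @param cm A [confusion()] object.
#' @return A list with `sns`, `spc`, `ppv`, `npv`, `acc` (proportions in
#'   \[0, 1\]), `plr`, `nlr`, and `plr_infinite`.
#' @export
diagnostic_summary <- function(cm) {
  stopifnot(inherits(cm, "uev_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sns <- div(cm$tp, cm$tp + cm$fn)
  spc <- div(cm$tn, cm$tn + cm$fp)
  plr <- if (is.na(sns) || is.na(spc)) NA_real_
         else if (spc == 1) Inf else sns / (1 - spc)
  nlr <- if (is.na(sns) || is.na(spc)) NA_real_
         else if (spc == 0) NA_real_ else (1 - sns) / spc
  list(sns = sns, spc = spc,
       ppv = div(cm$tp, cm$tp + cm$fp),
       npv = div(cm$tn, cm$tn + cm$fn),
       plr = plr, nlr = nlr,
       acc = div(cm$tp + cm$tn, n),
       plr_infinite = is.infinite(plr))
}

#' Odds ratio with Woolf/Wald confidence interval from a 2x2 table
#'
#' OR = (tp * tn) / (fp * fn), with the Wald interval
#' `exp(log OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))` and a two-sided
#' Wald p-value. With a zero cell the estimate is undefined unless the
#' Haldane-Anscombe correction (add 0.5 to every cell) is requested.
#'
#' @param cm A [confusion()] object.
#' @param zero_cell_correction Apply the 0.5 continuity correction when a
#'   cell is zero. Default `FALSE`.
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `or`, `ci_low`, `ci_high`, `p_value`, and
#'   `correction_applied`.
#' @export
odds_ratio <- function(cm, zero_cell_correction = FALSE, conf_level = 0.95) {
  stopifnot(inherits(cm, "uev_confusion"))
  a <- cm$tp; b <- cm$fp; c <- cm$fn; d <- cm$tn
  corrected <- FALSE
  if (any(c(a, b, c, d) == 0)) {
    if (!zero_cell_correction)
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p_value = NA_real_, correction_applied = FALSE))
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
       p_value = 2 * stats::pnorm(-abs(lor) / se),
       correction_applied = corrected)
}
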