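#' Define a binary risk-factor panel
#'
#' A panel is an ordered set of dichotomization rules (marker, direction,
#' cutoff) plus an "at least X of Y" positivity threshold. Component cutoffs
#' are frozen inputs: they come from the marker-evaluation stage or from
#' published values and are not re-estimated at scoring time, so a panel is
#' a pure function of new data.
#'
#' @param markers Character vector of component marker names.
#' @param directions `"greater"`/`"less"` per component (recycled).
#' @param cutoffs Numeric cutoffs per component.
#' @param threshold Integer X in "at least X of Y", or `"youden"` to choose
#'   X from the score's ROC curve at evaluation time.
#' @param name Panel label used in reports.
#' @return An object of class `"uev_panel"`.
#' @export
panel_definition <- function(markers, directions, cutoffs,
                             threshold = "youden", name = "panel") {
  y <- length(markers)
  directions <- rep_len(directions, y)
  cutoffs <- rep_len(cutoffs, y)
  if (!all(directions %in% c("greater", "less")))
    stop("directions must be 'greater' or 'less'")
  if (is.numeric(threshold) &&
      (threshold < 1 || threshold > y || threshold != round(threshold)))
    stop("`threshold` must be an integer in 1..", y, " or \"youden\"")
  structure(list(name = name,
                 components = data.frame(marker = markers,
                                         direction = directions,
                                         cutoff = cutoffs,
                                         stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "uev_panel")
}

#' Component indicator matrix for a panel
#'
#' Applies each component's frozen dichotomization rule to a table of
#' marker values.
#'
#' @param data Data frame or matrix containing one column per component
#'   marker (relative expression or clinical index values).
#' @param panel A [panel_definition()] object.
#' @return Logical matrix, patients x components.
#' @export
panel_indicators <- function(data, panel) {
  stopifnot(inherits(panel, "uev_panel"))
  comp <- panel$components
  miss <- setdiff(comp$marker, colnames(data))
  if (length(miss) > 0L)
    stop("data lacks component column(s): ", paste(miss, collapse = ", "))
  ind <- vapply(seq_len(nrow(comp)), function(i)
    dichotomize(data[, comp$marker[i]], comp$cutoff[i], comp$direction[i]),
    logical(nrow(data)))
  colnames(ind) <- comp$marker
  ind
}

#' Per-patient risk-factor sum score
#'
#' Counts, per patient, how many panel components call risk reclassification.
#' Patients with any missing component indicator get a missing score (they
#' are excluded from panel evaluation) and are reported in a warning.
#'
#' @param indicator_matrix Logical matrix, patients x components.
#' @return Integer vector of scores in 0..Y (`NA` for incomplete rows).
#' @export
sum_score <- function(indicator_matrix) {
  m <- as.matrix(indicator_matrix)
  if (!is.logical(m)) storage.mode(m) <- "logical"
  score <- rowSums(m)
  if (anyNA(score))
    warning(sum(is.na(score)),
            " patient(s) with missing component indicators excluded")
  as.integer(score)
}

#' Evaluate a sum score against the outcome
#'
#' ROC analysis of the integer score, choice of the positivity threshold X
#' (fixed, or by the Youden index on the score's ROC curve), and the full
#' accuracy work-up of the dichotomized score: confusion matrix,
#' seven-metric summary, odds ratio, and the biopsy-avoidance summary.
#'
#' @param scores Integer sum scores (see [sum_score()]).
#' @param labels Logical outcome labels.
#' @param threshold Integer X ("at least X of Y"), or `"youden"`.
#' @param name Label used in reports.
#' @return An object of class `"uev_panel_eval"`: a list with `name`,
#'   `roc`, `auc_inference`, `threshold` (the X used), `positivity`,
#'   `confusion`, `summary`, `odds_ratio`, and `avoidance`.
#' @export
evaluate_panel <- function(scores, labels, threshold = "youden",
                           name = "panel") {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels)[keep]
  roc <- roc_curve(scores, labels, direction = "greater", marker = name)
  inf <- auc_inference(roc)
  if (identical(threshold, "youden")) {
    # strict cutoff c on an integer score means positivity at score >= c + 1
    threshold <- as.integer(youden_cutoff(roc)$cutoff) + 1L
  }
  positivity <- scores >= threshold
  cm <- confusion(positivity, labels)
  structure(list(name = name, roc = roc, auc_inference = inf,
                 threshold = as.integer(threshold), positivity = positivity,
                 confusion = cm, summary = diagnostic_summary(cm),
                 odds_ratio = odds_ratio(cm),
                 avoidance = biopsy_avoidance(positivity, labels)),
            class = "uev_panel_eval")
}

#' @export
print.uev_panel_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s: AUC %.3f, positivity at >= %d risk factor(s)\n",
              x$name, x$roc$auc, x$threshold))
  cat(sprintf("  SNS %.1f%%  SPC %.1f%%  ACC %.1f%%  OR %.2f (%.2f-%.2f)\n",
              100 * s$sns, 100 * s$spc, 100 * s$acc,
              x$odds_ratio$or, x$odds_ratio$ci_low, x$odds_ratio$ci_high))
  cat(sprintf("  biopsies avoided %.0f%%, reclassified missed %.0f%%\n",
              x$avoidance$avoided_pct, x$avoidance$missed_pct))
  invisible(x)
}

#' Biopsy-avoidance summary of a panel
#'
#' Fractions of the whole cohort, as percentages: control biopsies that a
#' negative panel would have avoided (stable & panel-negative), reclassified
#' cancers a negative panel would have missed (reclassified &
#' panel-negative), and stable patients a positive panel would still have
#' sent to biopsy (stable & panel-positive). Together with the reclassified
#' & panel-positive fraction these total 100%.
#'
#' @param positivity Logical panel positivity per patient.
#' @param labels Logical outcome labels.
#' @return A list with `avoided_pct`, `missed_pct`, `overcalled_pct`
#'   (percent of the whole cohort).
#' @export
biopsy_avoidance <- function(positivity, labels) {
  if (length(positivity) != length(labels))
    stop("`positivity` and `labels` must have equal length")
  positivity <- as.logical(positivity)
  labels <- as.logical(labels)
  keep <- !is.na(positivity) & !is.na(labels)
  positivity <- positivity[keep]
  labels <- labels[keep]
  list(avoided_pct = 100 * mean(!labels & !positivity),
       missed_pct = 100 * mean(labels & !positivity),
       overcalled_pct = 100 * mean(!labels & positivity))
}
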