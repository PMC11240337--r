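#' Average qPCR replicate crossing points with a repeat-QC flag
#'
#' Two (or more) independent qPCR runs are averaged into a single crossing
#' point (CP) per sample and assay. Measurements whose replicates spread by
#' more than `max_dev` cycles would be repeated at the bench; in a reanalysis
#' they are flagged and, by default, excluded downstream.
#'
#' @param cp_replicates Numeric vector of replicate CP values (cycles),
#'   each in (0, 45].
#' @param max_dev Maximum tolerated replicate spread (max minus min) in
#'   cycles before the measurement is flagged for repetition. Default 0.5.
#' @return A list with `cp_mean` (arithmetic mean of the replicates) and
#'   `qc_repeat_flag` (`TRUE` when the spread exceeds `max_dev`).
#' @examples
#' average_replicates(c(28.0, 28.6))   # flagged: spread 0.6 > 0.5
#' @export
average_replicates <- function(cp_replicates, max_dev = 0.5) {
  cp_replicates <- cp_replicates[!is.na(cp_replicates)]
  if (length(cp_replicates) == 0L)
    stop("at least one non-missing CP replicate is required")
  if (any(cp_replicates <= 0) || any(cp_replicates > 45))
    stop("CP replicates must lie in (0, 45]")
  if (!is.numeric(max_dev) || length(max_dev) != 1L || max_dev <= 0)
    stop("`max_dev` must be a single positive number")
  spread <- max(cp_replicates) - min(cp_replicates)
  list(cp_mean = mean(cp_replicates), qc_repeat_flag = spread > max_dev)
}

#' Call a sample negative at the qPCR detection limit
#'
#' CP values at or above the detection limit indicate that the transcript was
#' not reliably detected.
#'
#' @param cp_mean Averaged CP value.
#' @param detection_limit Detection limit in cycles; the call is inclusive
#'   (`cp_mean >= detection_limit` is negative). Default 35.
#' @return Logical: `TRUE` when the sample is negative for the assay.
#' @export
call_negative <- function(cp_mean, detection_limit = 35) {
  if (any(is.na(cp_mean))) stop("`cp_mean` must be defined")
  cp_mean >= detection_limit
}

#' Geometric mean CP of the reference transcripts
#'
#' Normalization baseline (geoM): the geometric mean of the CP values of the
#' three reference RNAs (PPIA, RPLP0, TBP).
#'
#' @param cp_refs Numeric vector of exactly three reference CP values.
#' @return The geometric mean CP.
#' @export
reference_geomean <- function(cp_refs) {
  if (length(cp_refs) != 3L || any(is.na(cp_refs)))
    stop("exactly three non-missing reference CP values are required")
  if (any(cp_refs < 0)) stop("reference CP values must be non-negative")
  exp(mean(log(cp_refs)))
}

#' Relative transcript expression on the 2^-dCP scale
#'
#' Relative expression of a target transcript normalized to the reference
#' baseline: `2^-(cp_target - geoM)`. One PCR cycle corresponds to a factor
#' of two, so the result halves for every extra cycle of the target.
#'
#' @param cp_target Averaged target CP (not negative-flagged).
#' @param geoM Reference geometric mean CP, see [reference_geomean()].
#' @return Non-negative relative expression (unitless).
#' @export
relative_expression <- function(cp_target, geoM) {
  if (any(is.na(cp_target)) || any(is.na(geoM)))
    stop("`cp_target` and `geoM` must be defined")
  2^-(cp_target - geoM)
}

#' Fold change between reclassified and stable groups
#'
#' Ratio of the group medians (reclassified over stable). Ratios below one
#' are additionally reported on the reciprocal "x-fold down" scale, the
#' convention used for downregulated transcripts.
#'
#' @param values_reclassified,values_stable Non-negative relative expression
#'   values for the two groups; missing values are dropped.
#' @return A list with `ratio` (reclassified median / stable median), `fold`
#'   (the ratio, or its reciprocal when below one), `direction` (`"up"` or
#'   `"down"`), and `undefined` (`TRUE` when the stable median is zero).
#' @export
fold_change <- function(values_reclassified, values_stable) {
  values_reclassified <- values_reclassified[!is.na(values_reclassified)]
  values_stable <- values_stable[!is.na(values_stable)]
  if (length(values_reclassified) == 0L || length(values_stable) == 0L)
    stop("both groups must be non-empty")
  m1 <- stats::median(values_reclassified)
  m0 <- stats::median(values_stable)
  if (m0 == 0)
    return(list(ratio = NA_real_, fold = NA_real_, direction = NA_character_,
                undefined = TRUE))
  ratio <- m1 / m0
  if (ratio >= 1)
    list(ratio = ratio, fold = ratio, direction = "up", undefined = FALSE)
  else
    list(ratio = ratio, fold = 1 / ratio, direction = "down", undefined = FALSE)
}

relative_expression_or_na <- function(cp_target, geoM) {
  ifelse(is.na(cp_target) | is.na(geoM), NA_real_, 2^-(cp_target - geoM))
}

#' Quantify relative transcript expression from a CP table
#'
#' Runs the full crossing-point quantification: replicate averaging with the
#' repeat-QC rule, detection-limit negative calls, reference geometric-mean
#' normalization, and the 2^-dCP transform, yielding one relative expression
#' value (or an explicit missing) per patient and target transcript.
#'
#' Patients whose reference assays are missing, QC-flagged, or negative have
#' all expression values set missing (with a warning): without a baseline no
#' target can be normalized.
#'
#' @param cp_table Data frame with columns `sample_id`, `assay`, `cp_rep1`,
#'   `cp_rep2` and optionally `cp_rep3`, one row per sample x assay
#'   measurement (see [read_cp_table()]).
#' @param max_dev Replicate-spread QC limit in cycles (default 0.5).
#' @param detection_limit Negative-call limit in cycles (default 35).
#' @param normalization `"geometric"` (geometric mean of the reference CPs,
#'   the default) or `"arithmetic"` (arithmetic mean of the reference CPs).
#' @param reference_assays Names of the three reference transcripts.
#' @param keep_flagged Keep measurements whose replicate spread exceeds
#'   `max_dev` instead of setting them missing. Default `FALSE`.
#' @param negative_handling `"missing"` (default) records negative calls as
#'   missing; `"impute"` imputes them at the detection limit
#'   (`2^-(detection_limit - geoM)`).
#' @return A numeric matrix (patients x transcripts, reference assays
#'   excluded) of relative expression values with `NA` for missing cells.
#'   Attribute `"qc"` carries the per-measurement QC table.
#' @export
quantify_expression <- function(cp_table,
                                max_dev = 0.5,
                                detection_limit = 35,
                                normalization = c("geometric", "arithmetic"),
                                reference_assays = c("PPIA", "RPLP0", "TBP"),
                                keep_flagged = FALSE,
                                negative_handling = c("missing", "impute")) {
  normalization <- match.arg(normalization)
  negative_handling <- match.arg(negative_handling)
  req <- c("sample_id", "assay", "cp_rep1", "cp_rep2")
  if (!all(req %in% names(cp_table)))
    stop("`cp_table` must have columns ", paste(req, collapse = ", "))
  rep_cols <- intersect(c("cp_rep1", "cp_rep2", "cp_rep3"), names(cp_table))

  qc <- cp_table[c("sample_id", "assay")]
  avg <- apply(as.matrix(cp_table[rep_cols]), 1L, function(r) {
    a <- average_replicates(r, max_dev = max_dev)
    c(a$cp_mean, a$qc_repeat_flag)
  })
  qc$cp_mean <- avg[1L, ]
  qc$qc_repeat_flag <- as.logical(avg[2L, ])
  qc$negative_flag <- call_negative(qc$cp_mean, detection_limit)

  usable <- qc
  if (!keep_flagged) usable$cp_mean[usable$qc_repeat_flag] <- NA_real_

  patients <- unique(as.character(cp_table$sample_id))
  targets <- setdiff(unique(as.character(cp_table$assay)), reference_assays)
  expr <- matrix(NA_real_, length(patients), length(targets),
                 dimnames = list(patients, targets))

  key <- paste(usable$sample_id, usable$assay, sep = "\r")
  ref_cp <- vapply(reference_assays, function(r) {
    i <- match(paste(patients, r, sep = "\r"), key)
    ifelse(!is.na(i) & !usable$negative_flag[i], usable$cp_mean[i], NA_real_)
  }, numeric(length(patients)))
  ref_cp <- matrix(ref_cp, nrow = length(patients))
  geoM <- if (normalization == "geometric") exp(rowMeans(log(ref_cp)))
          else rowMeans(ref_cp)
  if (anyNA(geoM))
    warning("reference assays missing/flagged/negative for: ",
            paste(patients[is.na(geoM)], collapse = ", "),
            "; their expression values are set missing")

  tgt <- usable[usable$assay %in% targets, , drop = FALSE]
  pi <- match(as.character(tgt$sample_id), patients)
  ai <- match(as.character(tgt$assay), targets)
  val <- relative_expression_or_na(tgt$cp_mean, geoM[pi])
  val[tgt$negative_flag] <- if (negative_handling == "impute")
    2^-(detection_limit - geoM[pi][tgt$negative_flag]) else NA_real_
  expr[cbind(pi, ai)] <- val
  attr(expr, "qc") <- qc
  expr
}
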