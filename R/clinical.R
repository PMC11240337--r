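#' PSA density
#'
#' Ratio of the serum PSA level at control biopsy to the prostate volume.
#'
#' @param psa Serum PSA in ng/mL.
#' @param volume Prostate volume in mL; must be positive.
#' @return PSA density in ng/mL^2.
#' @export
compute_psad <- function(psa, volume) {
  if (any(!is.na(volume) & volume <= 0))
    stop("prostate volume must be positive")
  psa / volume
}

#' PSA velocity
#'
#' Change from the initial PSA at first diagnosis to the PSA at control
#' biopsy, divided by the time interval between the two measurements. May be
#' negative when the PSA has fallen.
#'
#' @param psa PSA at control biopsy (ng/mL).
#' @param ipsa Initial PSA at first diagnosis (ng/mL).
#' @param interval_years Interval between the two measurements in years;
#'   must be positive.
#' @return PSA velocity in ng/mL/year.
#' @export
compute_psav <- function(psa, ipsa, interval_years) {
  if (any(!is.na(interval_years) & interval_years <= 0))
    stop("interval must be positive")
  (psa - ipsa) / interval_years
}

#' Risk-reclassification label at control biopsy
#'
#' A patient is reclassified when the control-biopsy ISUP grading group is 2
#' or higher at any PSA level, or remains ISUP 1 with a PSA above 10 ng/mL.
#' Tumor-free control biopsies (coded ISUP 0) are stable regardless of the
#' PSA value.
#'
#' @param isup_control Integer ISUP grading group at control biopsy, 0
#'   (tumor-free) to 5. Missing values yield a missing label.
#' @param psa Serum PSA at control biopsy (ng/mL).
#' @return Logical vector: `TRUE` = reclassified, `FALSE` = stable.
#' @export
classify_reclassification <- function(isup_control, psa) {
  if (any(!is.na(isup_control) & !(isup_control %in% 0:5)))
    stop("`isup_control` must be an integer in 0..5")
  out <- rep(NA, length(isup_control))
  out[isup_control == 0] <- FALSE
  out[isup_control >= 2] <- TRUE
  i1 <- !is.na(isup_control) & isup_control == 1
  out[i1] <- psa[i1] > 10
  out
}

#' Derive clinical indices and the outcome label for a cohort table
#'
#' Adds `psad`, `psav`, and the binary `reclassified` label to a clinical
#' table. Patients without an ISUP grade at control biopsy get a missing
#' label and a warning (they cannot be analysed against the outcome).
#'
#' @param clinical Data frame with columns `patient_id`, `psa`, `ipsa`,
#'   `prostate_volume`, `interval_years`, `isup_control`, and optionally
#'   `age` and `max_pirads` (see [read_clinical_table()]).
#' @return The input with derived columns `psad`, `psav`, `reclassified`.
#' @export
derive_clinical <- function(clinical) {
  req <- c("patient_id", "psa", "ipsa", "prostate_volume", "interval_years",
           "isup_control")
  miss <- setdiff(req, names(clinical))
  if (length(miss) > 0L)
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  clinical$psad <- compute_psad(clinical$psa, clinical$prostate_volume)
  clinical$psav <- compute_psav(clinical$psa, clinical$ipsa,
                                clinical$interval_years)
  clinical$reclassified <- classify_reclassification(clinical$isup_control,
                                                     clinical$psa)
  if (anyNA(clinical$reclassified))
    warning(sum(is.na(clinical$reclassified)),
            " patient(s) without outcome label (missing ISUP)")
  clinical
}
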