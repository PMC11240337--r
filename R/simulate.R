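#' Default synthetic-cohort specification
#'
#' Parameters emulating the study conditions of the 72-patient active
#' surveillance cohort: 31/72 reclassification prevalence; group-wise
#' log-normal transcript expression with planted fold changes (AMACR
#' 1.4-fold up, HPN and PCA3 moderately up, PCAT29 1.7-fold up, MALAT1
#' 1.5-fold down, plus null transcripts); clinical distributions anchored at
#' the published group medians (PSA 4.82/7.54 ng/mL, PSAV -0.15/0.60
#' ng/mL/year, interval 1.4/1.6 years) and the maxPI-RADS >= 4 fractions
#' (29% stable vs 65% reclassified); reference-transcript CP levels around
#' 23.5-25.5 cycles with 0.15-cycle replicate noise and a 35-cycle
#' detection limit.
#'
#' Log2-scale spreads are calibrated so the planted AMACR fold of 1.4
#' yields an AUC near 0.65 at n = 72, the order of magnitude of the
#' published single-transcript AUCs.
#'
#' @param n Cohort size.
#' @param prevalence Reclassified fraction.
#' @return An object of class `"uev_cohort_spec"` (a named list). Fields of
#'   interest: `transcripts` (data frame: name, stable_median, fold,
#'   sd_log2), `references`, `clinical`, `replicate_sd`, `detection_limit`,
#'   `censor_rate` (per-measurement dropout probability to the
#'   non-detectable range).
#' @export
cohort_spec <- function(n = 72, prevalence = 31 / 72) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  structure(list(
    n = as.integer(n),
    prevalence = prevalence,
    transcripts = data.frame(
      name = c("AMACR", "HPN", "MALAT1", "PCA3", "PCAT29",
               "ERG", "KLK3", "STAT3"),
      stable_median = c(0.150, 0.0455, 0.060, 0.45, 0.0018,
                        0.010, 1.0, 0.020),
      fold = c(1.4, 1.3, 1 / 1.5, 1.3, 1.7, 1, 1, 1),
      sd_log2 = c(0.86, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9),
      stringsAsFactors = FALSE),
    references = data.frame(
      name = c("PPIA", "RPLP0", "TBP"),
      mean_cp = c(23.5, 24.5, 25.5),
      sd = c(1, 1, 1),
      stringsAsFactors = FALSE),
    replicate_sd = 0.15,
    detection_limit = 35,
    censor_rate = 0.02,
    clinical = list(
      psa_median = c(stable = 4.82, reclassified = 7.54),
      psa_sdlog = c(stable = 0.50, reclassified = 0.62),
      volume_median = 45, volume_sdlog = 0.35,
      psav_median = c(stable = -0.15, reclassified = 0.60),
      psav_sd = 1.8,
      interval_median = c(stable = 1.4, reclassified = 1.6),
      interval_sdlog = 0.8,
      age_mean = c(stable = 64, reclassified = 70), age_sd = 7,
      pirads_probs = rbind(stable = c(11, 18, 10, 2) / 41,
                           reclassified = c(2, 9, 7, 13) / 31),
      # reclassified: ISUP 1 & PSA > 10 (4/31) vs ISUP 2..5 (22,1,1,3)
      isup_reclassified = c(`1` = 4, `2` = 22, `3` = 1, `4` = 1, `5` = 3) / 31,
      # stable: tumor-free (25/41) vs ISUP 1 with PSA <= 10 (16/41)
      p_tumorfree_stable = 25 / 41)),
    class = "uev_cohort_spec")
}

# deterministic per-component substream seed (< 2^31) so adding one
# transcript never perturbs the draws of another
sub_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131)
  (abs(as.integer(seed)) %% 1000000000L + h * 97L) %% 2147483647L
}

qlnorm_trunc <- function(p_lo, p_hi, meanlog, sdlog, u) {
  # inverse-CDF draw from a lognormal truncated to (q_lo, q_hi) quantiles
  stats::qlnorm(p_lo + u * (p_hi - p_lo), meanlog, sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort (CP table + clinical table + ground truth) from
#' a [cohort_spec()]. Expression values are log-normal per group with the
#' planted fold changes; crossing points are back-computed as the patient's
#' reference geometric-mean CP minus log2(expression), plus replicate
#' noise; clinical variables follow the group-wise distributions of the
#' spec, and ISUP/PSA fields are drawn so that the reclassification rule
#' reproduces the planted labels exactly. Output is deterministic given
#' (spec, seed).
#'
#' @param spec A [cohort_spec()] object.
#' @param seed Integer master seed; per-component substreams are derived
#'   from it.
#' @return A list with `cp_table` (columns sample_id, assay, cp_rep1,
#'   cp_rep2), `clinical` (one row per patient), and `truth` (planted
#'   labels, folds, and medians).
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "uev_cohort_spec"))
  n <- spec$n
  ids <- sprintf("P%03d", seq_len(n))
  cl <- spec$clinical

  set.seed(sub_seed(seed, "labels"))
  n1 <- round(n * spec$prevalence)
  reclassified <- rep(FALSE, n)
  reclassified[sample.int(n, n1)] <- TRUE
  grp <- ifelse(reclassified, "reclassified", "stable")

  set.seed(sub_seed(seed, "clinical"))
  age <- round(stats::rnorm(n, cl$age_mean[grp], cl$age_sd))
  volume <- stats::rlnorm(n, log(cl$volume_median), cl$volume_sdlog)
  psav <- stats::rnorm(n, cl$psav_median[grp], cl$psav_sd)
  interval <- stats::rlnorm(n, log(cl$interval_median[grp]), cl$interval_sdlog)
  interval <- pmax(interval, 0.25)
  pirads <- vapply(grp, function(g)
    sample(2:5, 1L, prob = cl$pirads_probs[g, ]), integer(1))

  # ISUP and PSA, made consistent with the reclassification rule
  isup <- integer(n)
  psa <- numeric(n)
  u_isup <- stats::runif(n)
  u_psa <- stats::runif(n)
  for (i in seq_len(n)) {
    ml <- log(cl$psa_median[grp[i]])
    sl <- cl$psa_sdlog[grp[i]]
    p10 <- stats::plnorm(10, ml, sl)
    if (reclassified[i]) {
      cum <- cumsum(cl$isup_reclassified)
      isup[i] <- as.integer(names(cum)[findInterval(u_isup[i], c(0, cum),
                                                    left.open = TRUE)])
      psa[i] <- if (isup[i] == 1L)
        qlnorm_trunc(p10, 1, ml, sl, u_psa[i])   # ISUP 1 needs PSA > 10
      else stats::qlnorm(u_psa[i], ml, sl)
    } else {
      tumorfree <- u_isup[i] < cl$p_tumorfree_stable
      isup[i] <- if (tumorfree) 0L else 1L
      psa[i] <- if (tumorfree) stats::qlnorm(u_psa[i], ml, sl)
      else qlnorm_trunc(0, p10, ml, sl, u_psa[i])  # stable ISUP 1: PSA <= 10
    }
  }
  ipsa <- pmax(psa - psav * interval, 0.05)

  clinical <- data.frame(patient_id = ids, age = age,
                         psa = round(psa, 3), ipsa = round(ipsa, 3),
                         prostate_volume = round(volume, 2),
                         interval_years = round(interval, 2),
                         max_pirads = pirads, isup_control = isup,
                         stringsAsFactors = FALSE)

  # reference CPs: patient-level true values plus replicate noise
  set.seed(sub_seed(seed, "references"))
  ref_true <- sapply(seq_len(nrow(spec$references)), function(j)
    stats::rnorm(n, spec$references$mean_cp[j], spec$references$sd[j]))
  colnames(ref_true) <- spec$references$name
  ref_rep1 <- ref_true + stats::rnorm(length(ref_true), 0, spec$replicate_sd)
  ref_rep2 <- ref_true + stats::rnorm(length(ref_true), 0, spec$replicate_sd)
  geoM_true <- exp(rowMeans(log(ref_true)))

  cp_rows <- list()
  for (j in seq_len(nrow(spec$references))) {
    cp_rows[[length(cp_rows) + 1L]] <- data.frame(
      sample_id = ids, assay = spec$references$name[j],
      cp_rep1 = round(ref_rep1[, j], 3), cp_rep2 = round(ref_rep2[, j], 3),
      stringsAsFactors = FALSE)
  }

  expr_truth <- matrix(NA_real_, n, nrow(spec$transcripts),
                       dimnames = list(ids, spec$transcripts$name))
  for (j in seq_len(nrow(spec$transcripts))) {
    tr <- spec$transcripts[j, ]
    set.seed(sub_seed(seed, paste0("transcript:", tr$name)))
    expr <- tr$stable_median * ifelse(reclassified, tr$fold, 1) *
      2^stats::rnorm(n, 0, tr$sd_log2)
    expr_truth[, j] <- expr
    cp_true <- geoM_true - log2(expr)
    rep1 <- cp_true + stats::rnorm(n, 0, spec$replicate_sd)
    rep2 <- cp_true + stats::rnorm(n, 0, spec$replicate_sd)
    drop <- stats::runif(n) < spec$censor_rate
    shift <- spec$detection_limit + stats::runif(n, 0, 4)
    rep1[drop] <- shift[drop] + stats::rnorm(sum(drop), 0, spec$replicate_sd)
    rep2[drop] <- shift[drop] + stats::rnorm(sum(drop), 0, spec$replicate_sd)
    cp_rows[[length(cp_rows) + 1L]] <- data.frame(
      sample_id = ids, assay = tr$name,
      cp_rep1 = round(pmin(rep1, 45), 3),
      cp_rep2 = round(pmin(rep2, 45), 3),
      stringsAsFactors = FALSE)
  }
  cp_table <- do.call(rbind, cp_rows)
  rownames(cp_table) <- NULL

  list(cp_table = cp_table,
       clinical = clinical,
       truth = list(seed = seed,
                    reclassified = reclassified,
                    n_reclassified = n1,
                    folds = stats::setNames(spec$transcripts$fold,
                                            spec$transcripts$name),
                    stable_medians = stats::setNames(
                      spec$transcripts$stable_median, spec$transcripts$name),
                    expression = expr_truth))
}

#' Plant a panel with an exact confusion matrix
#'
#' Builds per-patient component indicators and labels whose panel confusion
#' matrix at the given positivity threshold equals the requested counts
#' exactly: panel-positive patients carry `threshold` positive components,
#' panel-negative patients `threshold - 1`. Useful as a worked-example
#' fixture for score evaluation.
#'
#' @param tp,fp,fn,tn Target confusion-matrix counts.
#' @param n_components Number of panel components Y.
#' @param threshold Positivity threshold X ("at least X of Y").
#' @return A list with `indicators` (logical matrix, patients x
#'   components), `labels`, and `threshold`.
#' @export
plant_panel <- function(tp, fp, fn, tn, n_components = 5, threshold = 3) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (threshold < 1 || threshold > n_components)
    stop("infeasible threshold for ", n_components, " components")
  # counts are given in (tp, fp, fn, tn) order
  labels <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
  positive <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
  score <- ifelse(positive, threshold, threshold - 1)
  ind <- t(vapply(score, function(s)
    seq_len(n_components) <= s, logical(n_components)))
  colnames(ind) <- paste0("component_", seq_len(n_components))
  list(indicators = ind, labels = labels, threshold = threshold)
}
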