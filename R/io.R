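read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

coerce_numeric <- function(df, cols) {
  bad <- rep(FALSE, nrow(df))
  for (cc in cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | (!is.na(df[[cc]]) & is.na(v)) | is.na(df[[cc]])
    df[[cc]] <- v
  }
  list(df = df, bad = bad)
}

#' Read a crossing-point (CP) table
#'
#' Expects a CSV/TSV with header columns `sample_id`, `assay`, `cp_rep1`,
#' `cp_rep2` and optionally `cp_rep3`. Rows with non-numeric or missing CP
#' replicates are rejected (and reported with their line numbers); a
#' duplicated (sample, assay) pair is an error.
#'
#' @param path Path to the file.
#' @return Validated data frame; rejected rows are reported in attribute
#'   `"rejected"` (line numbers and reasons).
#' @export
read_cp_table <- function(path) {
  df <- read_table_auto(path)
  req <- c("sample_id", "assay", "cp_rep1", "cp_rep2")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("CP table is missing required column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(df$sample_id, df$assay, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicated (sample, assay) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rep_cols <- intersect(c("cp_rep1", "cp_rep2", "cp_rep3"), names(df))
  co <- coerce_numeric(df, rep_cols[1:2])
  # an absent third replicate is fine; a present but non-numeric one is not
  if (length(rep_cols) == 3L) {
    v <- suppressWarnings(as.numeric(co$df$cp_rep3))
    co$bad <- co$bad | (!is.na(co$df$cp_rep3) & is.na(v))
    co$df$cp_rep3 <- v
  }
  out <- co$df[!co$bad, , drop = FALSE]
  rejected <- data.frame(line = which(co$bad) + 1L,
                         reason = rep("non-numeric or missing CP replicate",
                                      sum(co$bad)))
  if (nrow(rejected) > 0L)
    message(nrow(rejected), " CP row(s) rejected (lines ",
            paste(rejected$line, collapse = ", "), ")")
  attr(out, "rejected") <- rejected
  out
}

#' Read a clinical table
#'
#' Expects a CSV/TSV with one row per patient and columns `patient_id`,
#' `psa`, `ipsa`, `prostate_volume`, `interval_years`, `isup_control`, and
#' optionally `age` and `max_pirads`. Booleans are encoded 0/1.
#'
#' @param path Path to the file.
#' @return Validated data frame with numeric columns coerced.
#' @export
read_clinical_table <- function(path) {
  df <- read_table_auto(path)
  req <- c("patient_id", "psa", "ipsa", "prostate_volume", "interval_years",
           "isup_control")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  num_cols <- intersect(c("psa", "ipsa", "prostate_volume", "interval_years",
                          "isup_control", "age", "max_pirads"), names(df))
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df
}

#' Write a tab-separated report
#'
#' @param df Data frame.
#' @param path Output path; missing values become empty cells.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected. Defaults mirror the published analysis: detection
#' limit 35 cycles, replicate QC at 0.5 cycles, geometric-mean reference
#' normalization, fixed published cutoffs for PSA (>10 ng/mL), PSAD
#' (>0.2 ng/mL^2, both per PRIAS), PSAV (>0 ng/mL/year) and maxPI-RADS
#' (>=4), Youden-optimized cutoffs for the transcripts (MALAT1 oriented
#' "less", low expression indicating reclassification), stepwise entry/
#' removal alphas 0.05/0.10, and the 2C / 3T / 2C-3T panels with
#' Youden-chosen positivity thresholds.
#'
#' @param ... Overrides for any of the defaults (see the function body for
#'   the full key list): `cp_table`/`clinical` (data frames) or
#'   `cp_path`/`clinical_path`, `max_dev`, `detection_limit`,
#'   `normalization`, `negative_handling`, `markers`, `entry_alpha`,
#'   `removal_alpha`, `panels`, `seed`, `outdir`.
#' @return A validated configuration list of class `"uev_config"`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    cp_table = NULL, clinical = NULL, cp_path = NULL, clinical_path = NULL,
    max_dev = 0.5, detection_limit = 35,
    normalization = "geometric", negative_handling = "missing",
    markers = list(
      list(name = "PSA", source = "clinical", column = "psa",
           direction = "greater", cutoff = 10),
      list(name = "PSAD", source = "clinical", column = "psad",
           direction = "greater", cutoff = 0.2),
      list(name = "PSAV", source = "clinical", column = "psav",
           direction = "greater", cutoff = 0),
      list(name = "maxPI-RADS", source = "clinical", column = "max_pirads",
           direction = "greater", cutoff = 3),
      list(name = "AMACR", source = "expression", column = "AMACR",
           direction = "greater", cutoff = "youden"),
      list(name = "HPN", source = "expression", column = "HPN",
           direction = "greater", cutoff = "youden"),
      list(name = "MALAT1", source = "expression", column = "MALAT1",
           direction = "less", cutoff = "youden"),
      list(name = "PCA3", source = "expression", column = "PCA3",
           direction = "greater", cutoff = "youden"),
      list(name = "PCAT29", source = "expression", column = "PCAT29",
           direction = "greater", cutoff = "youden")),
    entry_alpha = 0.05, removal_alpha = 0.10,
    panels = list(
      `2C` = list(components = c("PSAD", "maxPI-RADS"), threshold = "youden"),
      `3T` = list(components = c("AMACR", "MALAT1", "PCAT29"),
                  threshold = "youden"),
      `2C-3T` = list(components = c("PSAD", "maxPI-RADS", "AMACR", "MALAT1",
                                    "PCAT29"), threshold = "youden")),
    seed = 1L, outdir = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, override)
  # marker and panel lists are replaced wholesale, not merged by name
  for (key in c("markers", "panels"))
    if (key %in% names(override)) cfg[[key]] <- override[[key]]
  structure(cfg, class = "uev_config")
}

#' Run the full analysis pipeline
#'
#' Executes the published analysis order on one cohort: CP quantification,
#' clinical index derivation and outcome labelling, per-marker ROC /
#' Youden / accuracy evaluation, univariate logistic screening,
#' forward-stepwise selection, sum-score panel construction and
#' evaluation, and the cohort comparison tables. With `outdir` set, writes
#' the TSV reports, a machine-readable JSON results bundle (all values
#' unrounded), and a plain-text log (versions, configuration echo, seed,
#' per-stage record counts).
#'
#' @param config A [pipeline_config()] object.
#' @return A result bundle (list): `expression`, `clinical`,
#'   `marker_report`, `marker_evals`, `indicators`, `univariate`,
#'   `stepwise`, `panel_evals`, `panel_report`, `cohort_tables`, `config`,
#'   `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "uev_config"))
  log_lines <- c(sprintf("uevpanel %s | R %s",
                         as.character(utils::packageVersion("uevpanel")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %s", config$seed))

  cp <- config$cp_table
  if (is.null(cp) && !is.null(config$cp_path)) cp <- read_cp_table(config$cp_path)
  clinical <- config$clinical
  if (is.null(clinical) && !is.null(config$clinical_path))
    clinical <- read_clinical_table(config$clinical_path)
  if (is.null(cp) || is.null(clinical))
    stop("both a CP table and a clinical table are required")

  expr <- quantify_expression(cp, max_dev = config$max_dev,
                              detection_limit = config$detection_limit,
                              normalization = config$normalization,
                              negative_handling = config$negative_handling)
  clinical <- derive_clinical(clinical)
  keep <- clinical$patient_id %in% rownames(expr)
  clinical <- clinical[keep, , drop = FALSE]
  expr <- expr[clinical$patient_id, , drop = FALSE]
  labels <- clinical$reclassified
  log_lines <- c(log_lines,
                 sprintf("patients: %d (%d reclassified, %d stable)",
                         nrow(clinical), sum(labels, na.rm = TRUE),
                         sum(!labels, na.rm = TRUE)),
                 sprintf("transcripts quantified: %d", ncol(expr)))

  # per-marker evaluation (reported-cutoff accuracy work-up)
  marker_evals <- list()
  indicators <- matrix(NA, nrow(clinical), length(config$markers),
                       dimnames = list(clinical$patient_id,
                                       vapply(config$markers, `[[`, "", "name")))
  rows <- list()
  for (m in config$markers) {
    vals <- if (m$source == "clinical") clinical[[m$column]]
            else expr[, m$column]
    roc <- roc_curve(vals, labels, direction = m$direction, marker = m$name)
    inf <- auc_inference(roc)
    cut <- if (identical(m$cutoff, "youden")) youden_cutoff(roc)$cutoff
           else m$cutoff
    ind <- dichotomize(vals, cut, roc$direction)
    cm <- confusion(ind, labels)
    s <- diagnostic_summary(cm)
    marker_evals[[m$name]] <- list(roc = roc, inference = inf, cutoff = cut,
                                   indicator = ind, confusion = cm,
                                   summary = s)
    indicators[, m$name] <- ind
    rows[[m$name]] <- data.frame(
      marker = m$name, auc = roc$auc, ci_low = inf$auc_ci[1],
      ci_high = inf$auc_ci[2], p_value = inf$p_value,
      direction = roc$direction, cutoff = cut,
      sns_pct = 100 * s$sns, spc_pct = 100 * s$spc, ppv_pct = 100 * s$ppv,
      npv_pct = 100 * s$npv, plr = s$plr, nlr = s$nlr, acc_pct = 100 * s$acc,
      stringsAsFactors = FALSE)
  }
  marker_report <- do.call(rbind, rows)
  rownames(marker_report) <- NULL

  ind_df <- as.data.frame(indicators)
  univariate <- univariate_screen(ind_df, labels)
  stepwise <- forward_stepwise(ind_df, labels,
                               entry_alpha = config$entry_alpha,
                               removal_alpha = config$removal_alpha)
  log_lines <- c(log_lines,
                 sprintf("stepwise selected: %s",
                         if (length(stepwise$selected))
                           paste(stepwise$selected, collapse = ", ")
                         else "(none)"))

  panel_evals <- list()
  prows <- list()
  for (pn in names(config$panels)) {
    p <- config$panels[[pn]]
    scores <- sum_score(indicators[, p$components, drop = FALSE])
    pe <- evaluate_panel(scores, labels, threshold = p$threshold, name = pn)
    panel_evals[[pn]] <- pe
    s <- pe$summary
    prows[[pn]] <- data.frame(
      panel = pn, n_components = length(p$components),
      threshold = pe$threshold, auc = pe$roc$auc,
      ci_low = pe$auc_inference$auc_ci[1],
      ci_high = pe$auc_inference$auc_ci[2],
      p_value = pe$auc_inference$p_value,
      sns_pct = 100 * s$sns, spc_pct = 100 * s$spc, ppv_pct = 100 * s$ppv,
      npv_pct = 100 * s$npv, plr = s$plr, nlr = s$nlr, acc_pct = 100 * s$acc,
      or = pe$odds_ratio$or, or_ci_low = pe$odds_ratio$ci_low,
      or_ci_high = pe$odds_ratio$ci_high,
      avoided_pct = pe$avoidance$avoided_pct,
      missed_pct = pe$avoidance$missed_pct,
      overcalled_pct = pe$avoidance$overcalled_pct,
      stringsAsFactors = FALSE)
  }
  panel_report <- do.call(rbind, prows)
  rownames(panel_report) <- NULL

  cohort_data <- cbind(clinical, as.data.frame(expr))
  cohort_data$pirads_high <- ifelse(is.na(clinical$max_pirads), NA,
                                    ifelse(clinical$max_pirads >= 4,
                                           "4+5", "2+3"))
  ct <- cohort_table(cohort_data, "reclassified",
                     continuous = intersect(c("age", "psa", "psad", "psav",
                                              "interval_years",
                                              colnames(expr)),
                                            names(cohort_data)),
                     categorical = "pirads_high")

  bundle <- list(expression = expr, clinical = clinical,
                 marker_report = marker_report, marker_evals = marker_evals,
                 indicators = indicators, univariate = univariate,
                 stepwise = stepwise, panel_evals = panel_evals,
                 panel_report = panel_report, cohort_tables = ct,
                 config = config, log = log_lines)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    em <- data.frame(patient_id = rownames(expr), expr, check.names = FALSE)
    write_tsv_report(em, out("expression_matrix.tsv"))
    write_tsv_report(marker_report, out("marker_report.tsv"))
    write_tsv_report(univariate, out("univariate_screen.tsv"))
    write_tsv_report(stepwise$trace, out("stepwise_trace.tsv"))
    write_tsv_report(panel_report, out("panel_report.tsv"))
    write_tsv_report(ct$table, out("cohort_table.tsv"))
    # echo the analysis parameters only; in-memory tables and output paths
    # are not part of the analytical configuration
    echo <- config
    echo$cp_table <- NULL; echo$clinical <- NULL
    echo$cp_path <- NULL; echo$clinical_path <- NULL; echo$outdir <- NULL
    jsonlite::write_json(
      list(config = unclass(echo), marker_report = marker_report,
           univariate = univariate, stepwise_trace = stepwise$trace,
           selected = stepwise$selected, panel_report = panel_report),
      out("results.json"), auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(c(log_lines, "config echo: results.json"), out("run.log"))
  }
  bundle
}
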