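#!/usr/bin/env Rscript
# Stage 4: per-marker predictive performance.
#
# ROC curve, DeLong AUC inference, cutoff (fixed published values for the
# clinical indices: PSA > 10 ng/mL, PSAD > 0.2 ng/mL^2, PSAV > 0,
# maxPI-RADS >= 4; Youden-optimal for the transcripts, MALAT1 oriented
# low-positive), and the seven accuracy metrics per marker. Also writes the
# per-patient dichotomized indicators used by the later selection and
# scoring stages.

library(uevpanel)

clin <- derive_clinical(read_clinical_table("results/simulated/clinical.tsv"))
expr <- utils::read.delim("results/expression_matrix.tsv", check.names = FALSE)
labels <- clin$reclassified

rows <- list(); ind <- list()
for (m in pipeline_config()$markers) {
  vals <- if (m$source == "clinical") clin[[m$column]] else expr[[m$column]]
  roc <- roc_curve(vals, labels, direction = m$direction, marker = m$name)
  inf <- auc_inference(roc)
  cut <- if (identical(m$cutoff, "youden")) youden_cutoff(roc)$cutoff
         else m$cutoff
  s <- diagnostic_summary(confusion(dichotomize(vals, cut, roc$direction),
                                    labels))
  ind[[m$name]] <- dichotomize(vals, cut, roc$direction)
  rows[[m$name]] <- data.frame(
    marker = m$name, auc = roc$auc, ci_low = inf$auc_ci[1],
    ci_high = inf$auc_ci[2], p_value = inf$p_value, direction = roc$direction,
    cutoff = cut, sns_pct = 100 * s$sns, spc_pct = 100 * s$spc,
    ppv_pct = 100 * s$ppv, npv_pct = 100 * s$npv, plr = s$plr, nlr = s$nlr,
    acc_pct = 100 * s$acc)
}
report <- do.call(rbind, rows)
write_tsv_report(report, "results/marker_report.tsv")
write_tsv_report(cbind(data.frame(patient_id = clin$patient_id,
                                  reclassified = as.integer(labels)),
                       as.data.frame(lapply(ind, as.integer),
                                     check.names = FALSE)),
                 "results/marker_indicators.tsv")

cat("marker AUCs:\n")
print(report[, c("marker", "auc", "p_value", "acc_pct")], row.names = FALSE,
      digits = 3)
cat("wrote results/marker_report.tsv and results/marker_indicators.tsv\n")
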