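#!/usr/bin/env Rscript
# Stage 6: risk-factor sum scores and biopsy-avoidance summary.
#
# Builds the three binary risk-factor sum scores -- 2C (PSAD, maxPI-RADS),
# 3T (AMACR, MALAT1, PCAT29) and the combined 2C-3T -- from the frozen
# per-marker indicators, picks each score's positivity threshold by the
# Youden index on its ROC curve, and reports AUC, accuracy metrics, odds
# ratio, and how many control biopsies a negative score would have spared
# at what miss rate.

library(uevpanel)

tab <- utils::read.delim("results/marker_indicators.tsv", check.names = FALSE)
labels <- tab$reclassified == 1
panels <- pipeline_config()$panels

rows <- list()
for (pn in names(panels)) {
  comp <- panels[[pn]]$components
  scores <- sum_score(as.matrix(tab[comp]) == 1)
  pe <- evaluate_panel(scores, labels, threshold = panels[[pn]]$threshold,
                       name = pn)
  s <- pe$summary
  rows[[pn]] <- data.frame(
    panel = pn, threshold = pe$threshold, n_components = length(comp),
    auc = pe$roc$auc, ci_low = pe$auc_inference$auc_ci[1],
    ci_high = pe$auc_inference$auc_ci[2],
    p_value = pe$auc_inference$p_value,
    sns_pct = 100 * s$sns, spc_pct = 100 * s$spc, ppv_pct = 100 * s$ppv,
    npv_pct = 100 * s$npv, plr = s$plr, nlr = s$nlr, acc_pct = 100 * s$acc,
    or = pe$odds_ratio$or, or_ci_low = pe$odds_ratio$ci_low,
    or_ci_high = pe$odds_ratio$ci_high,
    avoided_pct = pe$avoidance$avoided_pct,
    missed_pct = pe$avoidance$missed_pct,
    overcalled_pct = pe$avoidance$overcalled_pct)
  print(pe)
}
report <- do.call(rbind, rows)
write_tsv_report(report, "results/panel_report.tsv")
cat("wrote results/panel_report.tsv\n")
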