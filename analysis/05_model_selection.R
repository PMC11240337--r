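#!/usr/bin/env Rscript
# Stage 5: univariate screening and forward-stepwise selection.
#
# Every dichotomized marker is screened by single-predictor logistic
# regression (odds ratio, Wald CI and p), then forward-stepwise logistic
# regression (score-test entry at alpha = 0.05, likelihood-ratio removal at
# alpha = 0.10) identifies the independent predictors that the scoring
# stage combines.

library(uevpanel)

tab <- utils::read.delim("results/marker_indicators.tsv", check.names = FALSE)
labels <- tab$reclassified == 1
markers <- as.data.frame(lapply(tab[-(1:2)], function(x) x == 1))
names(markers) <- names(tab)[-(1:2)]

uni <- univariate_screen(markers, labels)
write_tsv_report(uni, "results/univariate_screen.tsv")

fs <- forward_stepwise(markers, labels)
write_tsv_report(fs$trace, "results/stepwise_trace.tsv")
if (!is.null(fs$fit))
  write_tsv_report(fs$fit$coefficients, "results/multivariate_fit.tsv")

cat("univariate odds ratios:\n")
print(uni, row.names = FALSE, digits = 3)
cat("\nstepwise trace:\n")
print(fs$trace, row.names = FALSE, digits = 3)
cat(sprintf("\nindependent predictors: %s\n",
            paste(fs$selected, collapse = ", ")))
cat("wrote results/{univariate_screen,stepwise_trace,multivariate_fit}.tsv\n")
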