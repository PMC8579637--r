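#!/usr/bin/env Rscript
# Stage 4: diagnostic performance of the pre-treatment markers.
#
# ROC analysis with Youden-optimal cutoffs for each significant marker and
# for the combined logistic score, pairwise DeLong comparisons, and the
# check of the summary-level metrics against the published reference
# operating points.

library(qmriresp)

fitted <- read.csv("results/fit/cohort_fitted.csv")
report <- run_stats(fitted, out_dir = "results/report")
print(report)

cat("\nPairwise DeLong comparisons:\n")
for (nm in names(report$delong)) {
  d <- report$delong[[nm]]
  cat(sprintf("  %-28s dAUC %+.3f  z %+.2f  p %.3f\n",
              nm, d$difference, d$z, d$p_value))
}

cat("\nPublished reference operating points, metrics recomputed at 36/20:\n")
ref <- reference_cohort()
for (i in seq_len(nrow(ref$markers))) {
  r <- ref$markers[i, ]
  m <- diagnostic_metrics(r$sensitivity, r$specificity, ref$n_rg, ref$n_nrg)
  cat(sprintf("  %-10s Youden %.3f  +LR %5.2f  -LR %.2f  +PV %.1f  -PV %.1f\n",
              r$marker, m$youden, m$plr, m$nlr, m$ppv, m$npv))
}
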