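#!/usr/bin/env Rscript
# Stage 3: paired control-vs-treatment contrasts, annual and restricted to
# the supplementation window, per trial and averaged across the three trials.
# The annual contrast is the window contrast diluted by the equalized
# outside-window period.
#
# Run from the repository root:  Rscript analysis/03_paired_comparison.R

library(dairyfootprint)

fix <- load_trial_fixtures()
dir.create("results", showWarnings = FALSE)

annual <- list(); window <- list()
for (cc in names(fix$pairs)) {
  p <- fix$pairs[[cc]]
  res <- assess_pair(p$control, p$treatment, fix$ef, fix$cf)
  annual[[cc]] <- compare(res$control, res$treatment)
  window[[cc]] <- supplementation_window_compare(p$control, p$treatment,
                                                 fix$ef, fix$cf)
}

agg_annual <- aggregate_comparisons(annual)
agg_window <- aggregate_comparisons(window)
write.csv(agg_annual, "results/comparison_annual.csv", row.names = FALSE)
write.csv(agg_window, "results/comparison_window.csv", row.names = FALSE)

cat("Per-trial climate-change contrast (negative = reduction):\n")
for (cc in names(annual)) {
  a <- annual[[cc]]$table; w <- window[[cc]]$table
  cat(sprintf("  %-7s annual %6.2f%%   window-only %6.2f%%\n", cc,
              a$diff_pct[a$category == "CC"], w$diff_pct[w$category == "CC"]))
}
cat("\nThree-trial means by category (annual accounting):\n\n")
print(transform(agg_annual,
                control_mean = signif(control_mean, 3),
                treatment_mean = signif(treatment_mean, 3),
                diff_pct_mean = round(diff_pct_mean, 2)),
      row.names = FALSE)
cat("\nThe supplementation-window reduction (~4-5%) roughly halves once\n",
    "diluted to the annual scale, as the equal-outside-window assumption\n",
    "implies.\n", sep = "")
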