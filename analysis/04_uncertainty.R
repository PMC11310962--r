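#!/usr/bin/env Rscript
# Stage 4: uncertainty of the paired contrast. Common-random-numbers Monte
# Carlo over the emission-factor spreads (shared draws for both groups, so
# chain-wide uncertainty cancels from the difference), plus one-at-a-time
# sensitivity of the control footprint and of the contrast to the key
# zootechnical and model parameters.
#
# Run from the repository root:  Rscript analysis/04_uncertainty.R [seed]

library(dairyfootprint)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20240729L

fix <- load_trial_fixtures()
dir.create("results", showWarnings = FALSE)

mc_rows <- list()
for (cc in names(fix$pairs)) {
  p <- fix$pairs[[cc]]
  mc <- monte_carlo(p$control, p$treatment, fix$ef, fix$cf,
                    n_iter = 1000, seed = seed)
  mc_rows[[cc]] <- data.frame(trial = cc, mc$summary)
}
mc_tab <- do.call(rbind, mc_rows)
write.csv(mc_tab, "results/mc_diff_pct.csv", row.names = FALSE)

cat(sprintf("Paired Monte Carlo (1000 iterations, seed %d), CC contrast:\n", seed))
cc_tab <- mc_tab[mc_tab$category == "CC", ]
for (i in seq_len(nrow(cc_tab))) {
  cat(sprintf("  %-7s point %6.2f%%  median %6.2f%%  95%% band [%6.2f, %6.2f]\n",
              cc_tab$trial[i], cc_tab$point[i], cc_tab$median[i],
              cc_tab$q025[i], cc_tab$q975[i]))
}

pars <- c("milk_yield_daily", "dmi_daily", "ym", "mcf", "gwp_ch4")
sens <- sensitivity_oat(fix$pairs$french$control, fix$pairs$french$treatment,
                        fix$ef, fix$cf, parameters = pars, perturbation = 0.05)
write.csv(sens, "results/sensitivity_oat.csv", row.names = FALSE)
cat("\nOne-at-a-time sensitivity (French trial), ranked:\n\n")
print(transform(sens,
                elasticity_cc_total = round(elasticity_cc_total, 3),
                sensitivity_diff_pct = round(sensitivity_diff_pct, 3)),
      row.names = FALSE)
cat("\nUnder pairing the shared feed-chain spreads cancel: the 95% band of\n",
    "the contrast stays within a few tenths of a percentage point of the\n",
    "deterministic value.\n", sep = "")
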