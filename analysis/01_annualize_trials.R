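#!/usr/bin/env Rscript
# Stage 1: annualize the three trials' window measurements against their
# country reference systems. Reproduces the zootechnical table: annual milk,
# FPCM, the intake decomposition (trial + outside + dry period), gross
# energy, and trial-window feed efficiency, for both groups of each trial.
#
# Run from the repository root:  Rscript analysis/01_annualize_trials.R

library(dairyfootprint)

fix <- load_trial_fixtures()
dir.create("results", showWarnings = FALSE)

rows <- list()
for (cc in names(fix$pairs)) {
  for (grp in c("control", "treatment")) {
    sys <- fix$pairs[[cc]][[grp]]
    pr <- annualize(sys$trial, sys$reference,
                    control_trial = fix$pairs[[cc]]$control$trial)
    rows[[paste(cc, grp)]] <- data.frame(
      trial = cc, group = grp,
      milk_annual = pr$milk_annual, fpcm_annual = pr$fpcm_annual,
      fi_trial = pr$fi_trial, fi_outside = pr$fi_outside, fi_dry = pr$fi_dry,
      fi_annual = pr$fi_annual, ge_annual = pr$ge_annual,
      fe_trial = pr$fe_trial,
      additive_kg_yr = pr$additive_mass_annual
    )
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/annual_profiles.csv", row.names = FALSE)

cat("Annualized per-cow profiles (kg, MJ, kg FPCM/kg DMI):\n\n")
print(transform(tab,
                fpcm_annual = round(fpcm_annual),
                ge_annual = round(ge_annual),
                fe_trial = round(fe_trial, 2)),
      row.names = FALSE)
cat("\nNotes: annual FPCM cells reproduce the published integers where the\n",
    "source is internally consistent (UK and German columns; the French\n",
    "annual-milk row disagrees with its own window sums by ~3 kg).\n", sep = "")
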