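# dairyfootprint

Cradle-to-farm-gate life cycle assessment (LCA) of dairy production, built to
quantify what a feed additive trial does to the environmental footprint of one
kilogram of fat- and protein-corrected milk (FPCM). The package is aimed at
LCA practitioners and animal scientists who have trial-window zootechnical
records (milk yield, composition, intake, dose, optionally measured methane)
and want a fully reproducible, offline accounting of the paired
control-vs-treatment contrast — including the places where commercial
inventory databases would normally sit.

## What it computes

**Functional unit and normalization.** All impacts are reported per kg FPCM
at the farm gate, with

```
FPCM (kg) = milk (kg) × (0.1226 × fat% + 0.0776 × protein% + 0.2534)
```

**Annualization.** A trial covers a window of the lactation (1-based
inclusive days in milk). Milk outside the window comes from the country
reference system and is identical across groups; feed intake outside the
window is extrapolated proportionally, `FI_out = FI_trial × MY_out /
MY_trial`, and the dry period adds a fixed intake. Annual intake decomposes
exactly into trial + outside + dry parts.

**On-farm emissions (IPCC Tier 2).** Enteric methane `CH4 = GE × (Ym/100) /
55.65` (a measured daily emission overrides the model inside the trial
window), manure methane `VS × B0 × 0.67 × MCF`, direct and indirect nitrous
oxide from excreted nitrogen (`Nex × EF3 × 44/28` plus volatilization and
leaching routes), ammonia, and direct utility CO2.

**Feed chain and allocation.** Upstream impacts of compound feed, roughages,
land-use change and the additive come from a pluggable emission-factor table
(plain CSV with lognormal uncertainty). Farm impacts are split between milk
and meat coproducts with the dairy biophysical allocation
`AF = 1 − 6.04 × M_meat / M_milk`.

**Comparison and uncertainty.** Paired control/treatment contrasts
(`diff% = (T − C)/C × 100`) per impact category, annually and restricted to
the supplementation window; contribution analysis by source; paired
(common-random-numbers) Monte Carlo so shared feed-chain uncertainty cancels
out of the difference; one-at-a-time sensitivity elasticities.

The shipped fixtures encode three European feeding trials (France, UK,
Germany) of a live-yeast probiotic fed at 5–10 g/cow/d. Their emission-factor
table is *calibrated* so the pipeline reproduces each trial's published
control contribution column — it is a synthetic stand-in for proprietary
database factors, not those factors.

## Worked example

```r
library(dairyfootprint)
fix <- load_trial_fixtures()
p   <- fix$pairs$uk
res <- assess_pair(p$control, p$treatment, fix$ef, fix$cf)
compare(res$control, res$treatment)
```

```
<comparison_report> (annual)
 category         unit   control treatment diff_pct additive_share_pct
       CC    kg CO2 eq  1.152000 1.121e+00    -2.72             0.0160
       LU           Pt 49.600000 4.833e+01    -2.55             0.0097
       WU m3 depriv eq  0.245000 2.395e-01    -2.23             0.3300
       RU           MJ  2.750000 2.684e+00    -2.40             0.1700
    TFWAC    mol H+ eq  0.019400 1.890e-02    -2.56             0.0000
      FEU      kg P eq  0.000105 1.023e-04    -2.53             0.0290
      MEU      kg N eq  0.008810 8.585e-03    -2.56             0.0046
      TEU     mol N eq  0.086600 8.439e-02    -2.55             0.0061
```

The UK control produces 1.152 kg CO2 eq per kg FPCM; supplementation reduces
the carbon footprint by 2.7% on the annual scale (5.3% within the
supplementation window — `supplementation_window_compare()` — before dilution
by the equalized rest of the year),
and the additive itself contributes 0.016% of the treatment total — its
production footprint (2.10 kg CO2 eq/kg) is negligible against the on-farm
methane and feed-chain sources it helps reduce.

The numbered scripts under `analysis/` run the full study: `01` annualizes
the trials, `02` builds the per-source contribution tables, `03` the paired
annual and window-only comparisons, `04` the Monte Carlo and sensitivity
analysis; each writes its tables under `results/`.
`analysis/00_build_fixtures.R` regenerates the calibrated fixtures from the
published inputs and documents the calibration.

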