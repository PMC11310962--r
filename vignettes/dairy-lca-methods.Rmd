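---
title: "Methods: cradle-to-farm-gate dairy LCA with a paired additive trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cradle-to-farm-gate dairy LCA with a paired additive trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyfootprint)
```

## The problem and the model

Feed additives that improve feed efficiency in dairy cows change the
environmental footprint of milk in two opposed ways: the additive's own
production chain adds a (small) burden, while the zootechnical response —
more milk, equal or lower intake — dilutes every per-kilogram impact. This
package implements the accounting needed to settle that balance for a
supplementation trial: a cradle-to-farm-gate life cycle assessment whose
functional unit is 1 kg of fat- and protein-corrected milk (FPCM) at the
farm gate,

$$\mathrm{FPCM} = \mathrm{milk} \times (0.1226\,\mathrm{fat\%} +
0.0776\,\mathrm{protein\%} + 0.2534).$$

A *trial* measures one group over a window of the lactation (1-based,
inclusive days in milk). The rest of the cow-year is filled in from a
country *reference system*: milk outside the window is the reference
system's and is identical for control and treatment (the additive's effect
is credited only where it was measured); intake outside the window scales
the trial-window intake by the milk ratio,
$FI_{out} = FI_{trial} \times MY_{out} / MY_{trial}$, with treatment groups
receiving the control group's value; a dry period (60 d by default) adds a
fixed intake (600 kg DM by default). Annual intake therefore decomposes
*exactly* into trial + outside + dry parts, a property the tests enforce.
When a source inventory states the outside-window intake directly, the
reference system can carry it as an override — the published figure is the
study input, and the extrapolation formula reproduces it to within a few kg.

On-farm emissions follow IPCC Tier-2 forms. Enteric methane is
$GE \times (Y_m/100) / 55.65$ with $Y_m$ defaulting to 6.5% of gross
energy; a measured daily emission, where a trial has one, overrides the
model inside the trial window (and only there — the override provably
touches no other flow). Manure methane is
$VS \times B_0 \times 0.67 \times MCF$, with volatile solids from
undigested plus urinary energy. Excreted nitrogen (crude-protein intake
route, $N = CP/6.25$, minus retention) drives direct
($N_{ex} \times EF_3 \times 44/28$) and indirect (volatilization and
leaching) nitrous oxide, plus ammonia at $17/14$ stoichiometry. Upstream
impacts of compound feed, roughages, land-use-change adders, utilities and
the additive itself come from a plain-text emission-factor table; the
additive's row is its own published cradle-to-plant-gate footprint
(2.10 kg CO2 eq per kg of product), consumed as an input.

Farm impacts are allocated between milk and the meat coproducts with the
dairy biophysical formula $AF = 1 - 6.04\, M_{meat}/M_{milk}$, where
$M_{milk}$ is annual FPCM sold. Because the treatment group corrects more
milk at equal coproduct mass, it receives a *larger* allocation factor — a
conservative choice that works against the additive. Characterization into
the eight midpoint categories (climate change, land use, water use, fossil
resource use, combined terrestrial/freshwater acidification, and
freshwater/marine/terrestrial eutrophication) multiplies each flow by a
configurable factor set: AR6 GWP100 defaults (biogenic CH4 27.0, N2O 273),
PEF-style midpoint magnitudes for ammonia and leached nitrogen.
Eutrophication factors are stored gram-based and converted once for
display, since upstream inventories print grams per kg of product while
per-kg-FPCM milk results are conventionally kilogram-scale.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| $Y_m$ | % of GE | 6.5 | Tier-2 dairy convention; dominant single knob on the carbon side |
| CH4 energy density | MJ/kg | 55.65 | physical constant of the Tier-2 form |
| $B_0$, MCF | m3/kg VS, – | 0.24, 0.17 | dairy manure, liquid/slurry storage in a temperate climate |
| digestibility, urinary, ash | – | 0.70, 0.04, 0.08 | volatile-solids model |
| CP fraction, N retention | – | 0.16, 0.25 | nitrogen route |
| $EF_3$, $Frac_{gas}$, $EF_4$, $Frac_{leach}$, $EF_5$ | – | 0.02, 0.30, 0.01, 0.30, 0.0075 | N2O direct/indirect split |
| GWP100 CH4 / N2O | kg CO2 eq/kg | 27.0 / 273 | AR6; configurable because absolute totals depend on the vintage |
| dry period, dry intake | d, kg DM | 60, 600 | reference-system convention |

Every value is a constructor argument; nothing is hard-coded in the flow
equations.

## The calibrated fixtures

The shipped fixtures encode three European trials of a live-yeast probiotic
(France, 5 g/d over days 1–108; UK, 10 g/d over days 1–120 with measured
enteric methane; Germany, 5 g/d over 92 days starting day 109). Their
zootechnical inputs are the published ones. Their emission-factor table is
**calibrated**: commercial database factors are proprietary, so
`calibrate_trial_factors()` solves, in closed form, one free factor per
contribution source row against each trial's published *control* column —
per-item factors for the table-driven rows, and two whole-system scale
factors (`ch4_scale`, `n2o_scale`) for the on-farm gas rows. The scales are
applied on top of the canonical Tier-2 parameters rather than by bending
$Y_m$ into implausible territory: they absorb what a per-lactating-cow model
cannot represent of the published farm — dry cows, youngstock, the manure
chain, database vintage. The calibrated values (CH4 scales 1.24–1.60, N2O
scales 0.39–0.48) are fixture artifacts, not biology.

Calibration closes on the control columns to machine precision (the tests
assert 1e-9). The treatment columns are deliberately *not* calibrated: they
are the model's out-of-sample behaviour, checked qualitatively (every trial's
treatment total falls below its control total, reductions in the 1–3%
range annually and 4–5.5% window-only, preserving the published dilution
pattern). The non-climate categories have no published per-source columns,
so their factors are derived by scaling the climate-calibrated structure to
land each control total on the published three-trial mean; they support the
cross-category comparison machinery and are never treated as reproductions
of database values. Allocation factors were not published either; the
fixtures use coproduct live weights (190–270 kg/cow-yr) giving milk factors
near 0.86, typical for the dairy biophysical formula.

Two source inconsistencies are handled explicitly. The French annual-milk
row disagrees with its own window sums by ~3 kg (and its printed FPCM with
the FPCM formula); the pipeline recomputes annual milk as window + outside,
and the printed annual totals are carried as metadata. The German window is
printed as "day 109 to day 197" *and* as 92 days; every trial-window
quantity uses 92 days, so the fixtures keep start day 109 with a 92-day
duration.

## Comparison and uncertainty

Contrasts use the control as denominator,
$\mathrm{diff\%} = (T - C)/C \times 100$, per category, annually and
window-only; multi-trial summaries are unweighted means of per-trial values.
The window-only accounting restricts impacts *and* FPCM to the
supplementation window (utilities prorated by duration, allocation kept
annual — it is a property of the farm's yearly coproduct balance). Because
the outside-window period is equalized, the annual contrast is provably a
diluted window contrast; the tests brute-force this inequality on
randomized fixtures with composition effects switched off (with them on,
the groups' differing fat/protein also recorrect the outside-window milk,
and the inequality is no longer guaranteed category by category).

Monte Carlo propagation is *paired* by default: each iteration draws one
lognormal multiplier per emission-factor row (from its geometric standard
deviation) and applies it to both systems, plus normal draws for any trial
inputs with standard errors. An unpaired mode exists for contrast. Pairing
is the methodological point: unpaired resampling lets chain-wide
uncertainty, which is common to both systems, swamp a small difference;
under common random numbers it cancels, and the contrast's interval
reflects only what actually differs. With all spreads degenerate the
simulation collapses to the point estimate exactly, and runs are
bit-reproducible from the seed (1000 iterations by default). One-at-a-time
sensitivity reports central-difference elasticities; for a linear driver
the elasticity of the total equals that driver's contribution share, which
the tests exploit as an analytic oracle ($Y_m$ vs the modeled enteric
share).

## The synthetic generator

`generate_scenario()` draws internally consistent control/treatment pairs:
control baselines from stated ranges, treatment multipliers on milk,
intake, fat and protein (defaults: milk +6% ± 3, intake 1.00 ± 0.04,
composition ~1 — the spread of published additive trials), a shared
reference system per pair so outside-window behaviour is equalized by
construction, and an emission-factor table with uncertainty. It emulates
the *structure* of real trial data — paired design, window accounting,
resolvable factor tables — but not its texture: no seasonality, no
lactation curve (the flat reference-system assumption is implemented as
stated), no correlated errors between milk and intake, no herd dynamics.
Passing tests on generated data therefore establish the accounting
identities and paired-design properties, not field realism.

## Numerical choices and limitations

Validation is eager and classed (validation vs resolution vs numerical
errors); allocation collapses with a clear error when
$6.04\,M_{meat}/M_{milk} \ge 1$; zero FPCM and zero trial milk are errors,
not NaNs; breakdown-total consistency is exact by construction and asserted
to 1e-12. Emission-factor files default absent spreads to gsd = 1 (no
uncertainty) rather than guessing. Degenerate trial windows (full
lactation) leave nothing to extrapolate and are supported.

Known limitations: no grazing/housing split or seasonal MCF; NMVOC and
particulate flows are computed as per-head masses but feed no reported
category; additive transport is folded into its factor; the absolute
per-category totals inherit whatever the emission-factor table encodes — for
the shipped fixtures that is a calibration, so only the *paired contrasts*
and the published-column closures carry evidential weight, never the
absolute fixture totals in the non-climate categories. Problem sizes
throughout (three trial pairs, 1000-iteration Monte Carlo, property loops
over a handful of seeds) were chosen so the full study runs in seconds on a
laptop.
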