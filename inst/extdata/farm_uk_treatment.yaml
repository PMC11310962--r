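schema_version: 1
allocation: biophysical
compound_share: 0.4
item_map:
  compound: compound_feed_uk
  roughage: roughage_uk
  luc: luc_uk
  additive: additive
  energy: energy_uk
  water: water_uk
  fuel: fuel_uk
trial:
  group_label: treatment
  start_day: 1
  end_day: 120
  milk_yield_daily: 50.100000000000001
  fat_pct: 3.97
  protein_pct: 3.23
  dmi_daily: 24.0
  additive_dose: 10.0
  n_cows: 50
  measured_ch4_daily: 0.462
  gaei: 122341.0
  reported_annual_milk: 12275.0
reference:
  country_label: UK
  annual_reference_milk: 12500.0
  lactation_days: 305.0
  dry_days: 60.0
  dry_period_fi: 600.0
  my_outside_trial: 6263.0
  fi_outside_override: 3151.0
  herd_coproduct_liveweight: 270.0
  utilities:
    energy: 500.0
    water: 30.0
    fuel: 120.0
  manure_system_label: liquid_slurry
params:
  ch4_scale: 1.239647134348443
  n2o_scale: 0.406886978311758
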