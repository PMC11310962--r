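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
  group_label: control
  start_day: 1
  end_day: 120
  milk_yield_daily: 47.5
  fat_pct: 3.9
  protein_pct: 3.25
  dmi_daily: 23.899999999999999
  additive_dose: 0.0
  n_cows: 50
  measured_ch4_daily: 0.467
  gaei: 122122.0
  reported_annual_milk: 11963.0
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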