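schema_version: 1
allocation: biophysical
compound_share: 0.4
item_map:
  compound: compound_feed_german
  roughage: roughage_german
  luc: luc_german
  additive: additive
  energy: energy_german
  water: water_german
  fuel: fuel_german
trial:
  group_label: control
  start_day: 109
  end_day: 200
  milk_yield_daily: 34.100000000000001
  fat_pct: 3.84
  protein_pct: 3.35
  dmi_daily: 21.899999999999999
  additive_dose: 0.0
  n_cows: 72
  gaei: 113430.0
  reported_annual_milk: 8639.200000000000728
reference:
  country_label: DE
  annual_reference_milk: 7748.0
  lactation_days: 305.0
  dry_days: 60.0
  dry_period_fi: 600.0
  my_outside_trial: 5502.0
  fi_outside_override: 3533.0
  herd_coproduct_liveweight: 195.0
  utilities:
    energy: 500.0
    water: 30.0
    fuel: 120.0
  manure_system_label: liquid_slurry
params:
  ch4_scale: 1.599949711548297
  n2o_scale: 0.385941670321768
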