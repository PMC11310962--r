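schema_version: 1
allocation: biophysical
compound_share: 0.4
item_map:
  compound: compound_feed_french
  roughage: roughage_french
  luc: luc_french
  additive: additive
  energy: energy_french
  water: water_french
  fuel: fuel_french
trial:
  group_label: control
  start_day: 1
  end_day: 108
  milk_yield_daily: 37.899999999999999
  fat_pct: 4.29
  protein_pct: 3.0
  dmi_daily: 21.899999999999999
  additive_dose: 0.0
  n_cows: 10
  gaei: 99464.0
  reported_annual_milk: 8802.0
reference:
  country_label: FR
  annual_reference_milk: 7373.0
  lactation_days: 305.0
  dry_days: 60.0
  dry_period_fi: 600.0
  my_outside_trial: 4206.0
  fi_outside_override: 2427.0
  herd_coproduct_liveweight: 190.0
  utilities:
    energy: 500.0
    water: 30.0
    fuel: 120.0
  manure_system_label: liquid_slurry
params:
  ch4_scale: 1.247981484064373
  n2o_scale: 0.477151833641828
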