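buffer:
  ms:
    reducing_agent: MS
    reducing_agent_percent_wv: 15.0
    monobasic_molarity: 1.24
    dibasic_molarity: 1.25
    saponin_g_per_l: 4.0
  hs:
    reducing_agent: HS
    reducing_agent_percent_wv: 3.0
    monobasic_molarity: 1.24
    dibasic_molarity: 1.25
    saponin_g_per_l: 4.0
cost_ledger:
  component:
  - Foil pouch
  - Reagent dropper
  - Blood dropper
  - Chromatography paper
  - Reagent tube
  - Food grade reagents
  unit_cost_usd:
  - 0.02
  - 0.05
  - 0.08
  - 0.01
  - 0.03
  - 0.02
generator:
  hbs_levels:
  - 0.0
  - 10.0
  - 20.0
  - 40.0
  - 80.0
  hematocrit_percent: 22.0
  image_size_px: 128.0
  stain_radius_px: 44.0
  center_radius_fraction: 0.35
  noise_sd: 2.0
  observer_slope: 40.0
  observer_cutpoints:
  - 1.1
  - 2.06
scheme:
  as_min: 10.0
  as_max: 40.0
  ss_binary_min: 80.0
alpha: 0.05
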