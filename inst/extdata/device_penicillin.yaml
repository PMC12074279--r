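# Penicillin biosensor: default stack with an adsorptively immobilized
# penicillinase layer, measured in 0.33 mM PBS at pH 7.4.
stack:
  d_sio2_nm: 30
  d_ta2o5_nm: 60
  area_mm2: 52
  doping_na_cm3: 2.0e+16
  temperature_k: 298.15
  flatband_v0: -1.0
chemistry:
  alpha: 1.0
  ph_pzc: 7.0
enzyme:
  present: true
  delta_ph_per_decade: 1.7
  s_onset_mm: 0.1
circuit:
  r_series_ohm: 14000
solution:
  ph: 7.4
  penicillin_mm: 0
rng_seed: 1
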