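# Default pH-sensitive EISCAP: Al/p-Si/SiO2/Ta2O5 stack, 52 mm^2 contact
# area, ideal Nernstian surface coupling, no enzyme layer, noise off.
stack:
  d_sio2_nm: 30
  d_ta2o5_nm: 60
  area_mm2: 52
  eps_sio2: 3.9
  eps_ta2o5: 27
  doping_na_cm3: 2.0e+16
  temperature_k: 298.15
  flatband_v0: -1.0
chemistry:
  alpha: 1.0
  ph_pzc: 7.0
enzyme:
  present: false
circuit:
  r_series_ohm: 14000
  noise_sd_c_f: 0
  drift_v_per_s: 0
solution:
  ph: 7.0
  penicillin_mm: 0
rng_seed: 1
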