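# eiscap — virtual instrument for capacitive field-effect biosensors

`eiscap` simulates an **EISCAP** (electrolyte–insulator–semiconductor
capacitor) — here an Al/p-Si/SiO₂/Ta₂O₅ structure used as a pH sensor and,
with an immobilized penicillinase layer, as a penicillin biosensor — and
drives it through the three measurement modes of a portable
impedance-analyzer readout station:

1. **impedance spectra** (series-RC equivalent circuit, resistive plateau at
   high frequency),
2. **high-frequency C−V sweeps** with automatic or manual working-point
   selection, and
3. **ConCap** (constant-capacitance) readout, where a PID feedback loop
   holds the capacitance at the working point so the gate voltage tracks
   surface-potential changes in real time.

It is aimed at developers of field-effect sensor instrumentation and
analysis pipelines who want a faithful, fully deterministic software stand-in
for the electrochemical cell: the simulator sits behind a small device
contract (`measure_impedance()`, `set_solution()`, `device_limits()`,
`elapse_time()`), so a real potentiostat driver can replace it without
touching the measurement modes or the analysis.

## The model

The total capacitance in series is the insulator stack and the semiconductor
space charge:

- insulator: C_ins = [Σᵢ dᵢ/(ε₀ εᵢ A)]⁻¹ over the SiO₂ and Ta₂O₅ layers
  (≈ 46.4 nF for 30 nm / 60 nm over 52 mm²);
- depletion (p-type, high-frequency, depletion approximation):
  C_sc = A √(q ε_Si ε₀ N_A / 2ψ_s), with the surface potential ψ_s solved from
  the charge balance V − V_fb = ψ_s + γ√ψ_s and clamped at strong-inversion
  onset ψ_s = 2φ_F;
- pH transduction: the effective flat-band voltage translates Nernstially,
  V_fb(pH) = V_fb⁰ + α·(RT ln10/F)·(pH_s − pH_pzc), with α ∈ (0,1] the
  site-binding sensitivity factor (59.16 mV/pH at α = 1, 298.15 K);
- enzyme layer: penicillinase hydrolysis acidifies the gate surface by
  ΔpH = δ·log₁₀(S/S₀) above an onset concentration S₀, an empirical
  log-linear law that reproduces the ~100 mV/dec penicillin response.

Calibration analysis extracts sensitivities as |slope| of an ordinary
least-squares line (settled ConCap potential vs pH, or vs log₁₀
concentration; C−V curve shifts vs pH), with the standard error of the
fitted slope, and aggregates several sensors as mean ± sample SD.

## Worked example

```r
library(eiscap)

dev <- eiscap_device()              # default pH-sensitive stack
cv  <- run_cv_sweep(dev)            # -2..+1 V, 100 mV steps, 120 Hz
wp  <- select_working_point(cv, 30e-9)
wp
#> Working point (manual): C_wp = 30.000 nF at V_wp = -0.7081 V

tr <- run_concap(eiscap_device(), wp, auto_pid_gains(cv, wp),
                 ph_ladder_schedule(duration_per_segment_s = 30))
tr <- offset_correct(tr)            # baseline pH 7 segment set to 0 mV
pts <- concap_calibration_points(tr, x_kind = "ph")
fit_calibration(pts$x, pts$potential_mv, x_kind = "ph")
#> Calibration fit (ph, n = 9): sensitivity 59.2 +/- 0.0 mV/pH
#>   signed slope 59.159, intercept -414.12 mV

aggregate_sensitivities(c(104, 101, 101))
#> Average sensitivity of 3 sensors: 102 +/- 2 mV/dec (mean 102.00, sd 1.73)
```

The ladder sensitivity of 59.159 mV/pH is the ideal Nernst slope at
298.15 K: the PID loop settles each pH segment onto the exact crossing of
the translated C−V curve with the 30 nF working point, and the nine settled
potentials (pH 7→6→5→6→7→8→9→8→7) fall on a perfect line.

`run_reference_scenarios("out/")` runs the full characterization suite
(spectrum, pH 5–9 C−V set, pH ladder, penicillin 0.2–2 mM run, wide pH 2–12
run) and writes all CSV products and fit reports.

A thin command-line interface with subcommands
`spectrum | cv | concap | calibrate | reproduce` lives at
`inst/cli/eiscap.R` (see its header for usage); device configurations are
YAML/JSON files with unit-bearing keys (`inst/extdata/device_default.yaml`).

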