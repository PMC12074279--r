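---
title: "Methods: the EISCAP simulator and its measurement modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EISCAP simulator and its measurement modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiscap)
```

## What the simulator models

An EISCAP is a chemically sensitive capacitor: reference electrode /
electrolyte / pH-sensitive oxide (Ta₂O₅) / SiO₂ / p-Si / Al back contact.
Its measurable total capacitance is the series combination of a fixed
insulator capacitance and the voltage-dependent semiconductor space-charge
capacitance. Surface protonation chemistry sets a pH-dependent surface
potential that rigidly translates the capacitance–voltage (C−V)
characteristic along the voltage axis; reading out that translation — from
C−V curve shifts or in real time with a constant-capacitance (ConCap)
feedback loop — is the sensing principle.

The package models this with four deliberately separable pieces:

1. **Insulator stack.** Parallel-plate capacitances in series,
   `insulator_capacitance()`. With the default 30 nm SiO₂ (ε = 3.9), 60 nm
   Ta₂O₅ (ε = 27) and 52 mm² contact area this gives 46.44 nF, the
   accumulation plateau of every simulated curve. The permittivities are
   standard literature values; everything is configurable, and all derived
   quantities are recomputed from whatever is configured.

2. **Semiconductor.** The p-type high-frequency C−V in the *depletion
   approximation*: the space-charge capacitance is
   \(C_{sc} = A\sqrt{q\varepsilon_{Si}\varepsilon_0 N_A/(2\psi_s)}\), with the
   surface potential solved from the charge balance
   \(V - V_{fb} = \psi_s + \gamma\sqrt{\psi_s}\),
   \(\gamma = \sqrt{2q\varepsilon_{Si}\varepsilon_0 N_A}\,/\,C''_{ins}\).
   That relation is quadratic in \(\sqrt{\psi_s}\), so it is solved in closed
   form — there is no iterative solver to mis-converge, and the model stays
   cheap enough to call tens of thousands of times per ConCap run. Beyond
   strong-inversion onset (\(\psi_s = 2\varphi_F\),
   \(\varphi_F = (kT/q)\ln(N_A/n_i)\), \(n_i = 10^{10}\,\mathrm{cm^{-3}}\))
   the capacitance is clamped at its high-frequency minimum. Accumulation is
   idealized as exactly \(C_{ins}\) for \(V \le V_{fb}\). The curve is
   therefore continuous, non-increasing, and bounded by \((0, C_{ins}]\).

3. **Surface chemistry.** A phenomenological site-binding factor
   \(\alpha \in (0,1]\) scales the Nernst slope:
   \(V_{fb}(\mathrm{pH}) = V_{fb}^0 + \alpha\,(RT\ln 10/F)\,
   (\mathrm{pH}_s - \mathrm{pH}_{pzc})\). At the defaults (α = 1,
   298.15 K) the slope is 59.159 mV/pH. A full site-binding/double-layer
   isotherm is intentionally **not** modelled; α subsumes it.

4. **Enzyme layer.** Penicillinase hydrolysis of penicillin releases
   protons near the gate. Without published kinetics we use an empirical
   log-linear local-pH drop,
   \(\mathrm{pH}_s = \mathrm{pH}_b - \delta \log_{10}(S/S_0)\) for
   \(S \ge S_0\), clamped to [0, 14]. Defaults δ = 1.7 pH/dec and
   S₀ = 0.1 mM were chosen once so the composed response,
   α·59.16·δ ≈ 100.6 mV/dec, lands in the ~100 mV/dec range typical of
   Ta₂O₅ penicillinase biosensors over 0.2–2 mM. This is a calibration-level
   description, not reaction–diffusion kinetics.

### Choice of doping density

The doping of the measured wafers is not public. We set
N_A = 2×10¹⁶ cm⁻³ because, together with the −1.0 V default flat-band
voltage at pH 7, it places the depletion window at roughly −1 V … +0.5 V and
strong-inversion onset near +0.53 V, the region structure visible in
published curves of this sensor type; a value of 5×10¹⁵ cm⁻³ would compress
the depletion flank into −1 V … +0.05 V and leave most of the sweep on the
inversion plateau. Both the doping and the flat-band voltage are
configuration fields, not constants.

## Measurement modes

**Impedance spectrum.** Log-spaced frequencies, series-RC model
\(Z = R_s + 1/(j2\pi f C)\). The plateau level is the configured
`r_series_ohm` (default 14 kΩ, an electrode/cable property that the
simulator only echoes).

**C−V sweep.** Single-pass staircase (no hysteresis modelling), default
−2 V to +1 V in 100 mV steps at 120 Hz with 20 mV AC. The AC amplitude is
recorded in metadata but does not enter the small-signal model (linearity
assumption). Capacitance is extracted per point as
\(C = -1/(2\pi f\,\mathrm{Im}\,Z)\), which is exact for the series-RC
backend for any series resistance.

**Working point.** Auto mode takes 60% of the maximum measured capacitance
(for this p-type device the maximum is the accumulation plateau); manual
mode accepts any capacitance strictly inside the measured span — the
30 nF depletion-flank inflection choice is the conventional manual setting
and the package default in the reference scenarios. V_wp is found by
scanning from the accumulation end (most negative voltage) and linearly
interpolating between the first pair of measured points bracketing C_wp.
The accumulation-side scan is also the tie-break for locally non-monotone
(noisy) curves: the working point belongs to the depletion flank adjacent
to accumulation. Interpolating the curve back at V_wp reproduces C_wp to
machine precision by construction.

**ConCap loop.** A discrete-time PID in incremental (velocity) form,

\[\Delta V_n = k_p(e_n - e_{n-1}) + k_i\,\Delta t\,e_n +
  k_d\,(e_n - 2e_{n-1} + e_{n-2})/\Delta t,\qquad e_n = C_n - C_{wp},\]

with the sign convention for p-type devices (dC/dV < 0 on the depletion
flank: a positive error drives V upward; a flag inverts it for hypothetical
n-type backends). The velocity form lets the output be clamped to the
hardware voltage range (−2.0 … +1.2 V) without integral wind-up. Gains are
not published for any real controller; `auto_pid_gains()` scales
proportional-dominant defaults by the local |dV/dC| of the measured curve
at the working point — \(k_p = 0.5/|g|\), \(k_i = 0.5/(|g|\Delta t)\),
\(k_d = 0\), Δt = 0.1 s — which for the linearized plant places the
closed-loop poles at magnitude ≈ 0.7 per step, i.e. settling well inside a
second. Because the integral term only vanishes at zero error, the
steady-state voltage converges to the exact crossing of the (translated)
C−V characteristic with C_wp; with integral action the steady-state error
is zero and each pH step of ΔpH changes the settled voltage by exactly
α·(RT ln10/F)·ΔpH. A segment whose final error exceeds `tolerance`
(default 0.01 nF) is flagged in the trace metadata, as is any sample where
the commanded voltage railed at a clamp. An optional dead time after each
solution exchange masks samples from the record, mimicking the gaps real
traces show during buffer exchange; the default is 0 s so simulated traces
are gap-free and deterministic.

**Offset correction and settled means.** The settled value of a segment is
the mean of its final 50% of samples (configurable fraction); offset
correction subtracts the baseline segment's settled mean so the baseline
reads 0 mV, and is idempotent.

## Calibration analysis

Curve shifts are extracted at a fixed reference capacitance with the same
accumulation-side interpolation rule as the working point; the default
reference, 30 nF, sits near the middle of the depletion flank where the
curve is steep and the piecewise-linear interpolation error of the 100 mV
grid is a few millivolts at most. Sensitivity fits are ordinary least
squares (`stats::lm`) of settled potential against pH or log₁₀
concentration, reporting the slope's standard error from residual variance;
in ladder schedules revisited pH values enter as individual points rather
than per-pH averages (the natural choice when drift between visits is
itself informative). Zero-analyte baseline segments are excluded from
concentration fits (their logarithm is undefined). Sensitivities are
quoted as |slope| — the penicillin response is a pH *decrease*, so its
signed slope is negative — and multi-sensor summaries are mean ± sample SD
(n−1), rounded half-away-from-zero to integer millivolts for reporting.

## Determinism, noise and drift

The simulator is noiseless and driftless by default, making every product
bit-reproducible for a given configuration. Optional Gaussian capacitance
noise (`noise_sd_c_f`) is drawn from a per-device private RNG stream seeded
at construction, so identical devices queried in the same order return
identical measurements without touching the session RNG; optional linear
baseline drift (`drift_v_per_s`) moves the effective flat-band with the
device clock, which the ConCap loop advances by Δt per sample.

## What the simulator does and does not emulate

It reproduces: the series capacitance structure and ≈46 nF accumulation
level implied by the stated stack, the accumulation/depletion/inversion
shape, rigid Nernstian curve translation with pH, the working-point rules,
ConCap tracking of solution steps, the ~59 mV/pH and ~100 mV/dec
sensitivities, and the impedance plateau at the configured series
resistance.

It does **not** model: sub-Nernstian curvature of real Ta₂O₅ over wide pH
ranges (α is constant, so the wide pH 2–12 scenario also reads the ideal
slope), enzyme saturation kinetics and substrate depletion, drift and
hysteresis of real oxides beyond a linear term, the small inversion-region
divergence between instruments, double-layer/Stern capacitance, and
temperature sweeps. Tests passing on the simulator therefore validate the
instrument logic and analysis chain, not the materials physics of a real
sensor.

## Problem sizes

The shipped tests and scenario runs use 31-point C−V sweeps, 25–40-point
spectra, and ConCap segments of 8–30 s at Δt = 0.1 s (≈ 700–2700 control
steps per run) — the same grid and step sizes as the bench procedure, with
segment durations an order of magnitude shorter than a wet experiment since
the noiseless loop settles in under a second.
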