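# EISCAP device simulator: high-frequency C-V of the p-type
# electrolyte-insulator-semiconductor capacitor plus its small-signal
# impedance, with Nernstian pH coupling and an optional enzyme layer.
# The simulator is the default backend behind the device contract
# (measure_impedance / set_solution / device_limits / elapse_time), so a
# real instrument driver can replace it without touching the modes.

#' Series insulator capacitance of the sensor stack
#'
#' Evaluates the two parallel-plate layer capacitances (SiO2, Ta2O5) and
#' returns their series combination, the accumulation-region maximum of the
#' high-frequency C-V curve.
#'
#' @param stack A [sensor_stack()].
#' @return Capacitance in farads.
#' @examples
#' insulator_capacitance(sensor_stack()) * 1e9  # ~46.4 nF
#' @export
insulator_capacitance <- function(stack) {
  stopifnot(inherits(stack, "sensor_stack"))
  a_m2 <- stack$area_mm2 * 1e-6
  c1 <- .eps0 * stack$eps_sio2 * a_m2 / (stack$d_sio2_nm * 1e-9)
  c2 <- .eps0 * stack$eps_ta2o5 * a_m2 / (stack$d_ta2o5_nm * 1e-9)
  1 / (1 / c1 + 1 / c2)
}

#' Local pH at the gate surface
#'
#' With no enzyme layer (or no substrate) the surface pH equals the bulk pH.
#' With penicillinase present and penicillin at or above the onset
#' concentration, enzymatic hydrolysis acidifies the surface by
#' `delta_ph_per_decade * log10(S / s_onset)` pH units; the result is clamped
#' to \[0, 14\].
#'
#' @param solution A [solution_state()].
#' @param enzyme An [enzyme_layer()].
#' @return Local surface pH (pH units).
#' @export
surface_ph <- function(solution, enzyme) {
  stopifnot(inherits(solution, "solution_state"), inherits(enzyme, "enzyme_layer"))
  ph <- solution$ph
  s <- solution$penicillin_mm
  if (enzyme$present && s >= enzyme$s_onset_mm) {
    ph <- ph - enzyme$delta_ph_per_decade * log10(s / enzyme$s_onset_mm)
  }
  min(max(ph, 0), 14)
}

#' Effective flat-band voltage at a given surface pH
#'
#' The pH-dependent surface potential rigidly translates the C-V curve along
#' the voltage axis: `V_fb(pH) = flatband_v0 + alpha * (RT ln10 / F) *
#' (pH_surface - ph_pzc)`. For this p-type device a pH increase moves the
#' curve toward more positive gate voltages.
#'
#' @param stack A [sensor_stack()] (supplies temperature and `flatband_v0`).
#' @param chem A [surface_chemistry()].
#' @param surface_ph_value Local pH at the gate surface.
#' @return Effective flat-band voltage, V.
#' @export
effective_flatband <- function(stack, chem, surface_ph_value) {
  stopifnot(inherits(stack, "sensor_stack"), inherits(chem, "surface_chemistry"))
  stack$flatband_v0 +
    chem$alpha * nernst_slope(stack$temperature_k) * (surface_ph_value - chem$ph_pzc)
}

#' Create a simulated EISCAP device
#'
#' Bundles the stack, surface chemistry, enzyme layer, circuit parameters and
#' initial solution into a mutable device object implementing the device
#' contract ([measure_impedance()], [set_solution()], [device_limits()],
#' [elapse_time()]). The object carries its own random-number stream (seeded
#' by `rng_seed`) for the optional capacitance noise, so two devices built
#' with the same seed and queried in the same order return bit-identical
#' measurements.
#'
#' @param stack,chem,enzyme,circuit,solution Component descriptions; see
#'   [sensor_stack()], [surface_chemistry()], [enzyme_layer()],
#'   [circuit_params()], [solution_state()].
#' @param rng_seed Integer seed for the device's private noise stream.
#' @return An environment of class `eiscap_device`.
#' @examples
#' dev <- eiscap_device()
#' hf_capacitance(dev, -2) * 1e9      # accumulation: ~46.4 nF
#' abs(measure_impedance(dev, -2, 120))
#' @export
eiscap_device <- function(stack = sensor_stack(), chem = surface_chemistry(),
                          enzyme = enzyme_layer(), circuit = circuit_params(),
                          solution = solution_state(), rng_seed = 1L) {
  stopifnot(inherits(stack, "sensor_stack"), inherits(chem, "surface_chemistry"),
            inherits(enzyme, "enzyme_layer"), inherits(circuit, "circuit_params"),
            inherits(solution, "solution_state"))
  if (stack$doping_na_cm3 <= .ni_cm3)
    stop("doping_na_cm3 must exceed the intrinsic density (1e10 cm^-3) ",
         "for the p-type depletion model", call. = FALSE)
  dev <- new.env(parent = emptyenv())
  dev$stack <- stack
  dev$chem <- chem
  dev$enzyme <- enzyme
  dev$circuit <- circuit
  dev$solution <- solution
  dev$rng_seed <- as.integer(rng_seed)
  dev$time_s <- 0
  dev$.rng_state <- NULL
  class(dev) <- "eiscap_device"
  dev
}

#' @export
print.eiscap_device <- function(x, ...) {
  cins <- insulator_capacitance(x$stack)
  cat("Simulated EISCAP device (Al/p-Si/SiO2/Ta2O5)\n")
  cat(sprintf("  stack: %g nm SiO2 / %g nm Ta2O5, area %g mm^2, N_A %.3g cm^-3\n",
              x$stack$d_sio2_nm, x$stack$d_ta2o5_nm, x$stack$area_mm2,
              x$stack$doping_na_cm3))
  cat(sprintf("  insulator capacitance: %.2f nF; flat-band V0: %.3f V at pH %g\n",
              cins * 1e9, x$stack$flatband_v0, x$chem$ph_pzc))
  cat(sprintf("  coupling: alpha = %g (%.2f mV/pH at %g K)\n", x$chem$alpha,
              x$chem$alpha * nernst_slope(x$stack$temperature_k) * 1e3,
              x$stack$temperature_k))
  if (x$enzyme$present)
    cat(sprintf("  enzyme layer: %.2f pH/dec above %g mM\n",
                x$enzyme$delta_ph_per_decade, x$enzyme$s_onset_mm))
  cat(sprintf("  solution: pH %g, penicillin %g mM; R_series %g ohm\n",
              x$solution$ph, x$solution$penicillin_mm, x$circuit$r_series_ohm))
  invisible(x)
}

# draw from the device's private noise stream without disturbing the
# caller's global RNG state
.device_rnorm <- function(dev, n) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(dev$.rng_state)) set.seed(dev$rng_seed)
  else assign(".Random.seed", dev$.rng_state, envir = globalenv())
  x <- stats::rnorm(n)
  dev$.rng_state <- get(".Random.seed", envir = globalenv())
  x
}

# closed-form depletion-approximation surface potential:
# V - V_fb = psi + gamma*sqrt(psi) is quadratic in sqrt(psi)
.surface_potential <- function(v_minus_vfb, gamma) {
  disc <- gamma^2 + 4 * v_minus_vfb
  if (any(disc < 0))
    stop("surface-potential solve failed: negative discriminant ",
         "(check stack parameters)", call. = FALSE)
  u <- (-gamma + sqrt(disc)) / 2
  u^2
}

#' High-frequency capacitance of the device at a gate voltage
#'
#' The p-type high-frequency C-V model in the depletion approximation.
#' At or below the effective flat-band voltage (accumulation) the capacitance
#' equals the insulator capacitance. In depletion the space-charge capacitance
#' \eqn{C_{sc} = A\sqrt{q\varepsilon_{Si}\varepsilon_0 N_A/(2\psi_s)}}
#' adds in series, with the surface potential \eqn{\psi_s} from the
#' charge-balance relation \eqn{V - V_{fb} = \psi_s + \gamma\sqrt{\psi_s}}.
#' Beyond strong-inversion onset (\eqn{\psi_s = 2\varphi_F}) the capacitance
#' is clamped at its high-frequency minimum. The result is noiseless,
#' non-increasing in voltage, and bounded by the insulator capacitance;
#' measurement noise enters only through [measure_impedance()].
#'
#' @param device An [eiscap_device()].
#' @param v_gate Gate voltage(s), V (vs the Ag/AgCl reference electrode).
#' @return Capacitance(s) in farads.
#' @export
hf_capacitance <- function(device, v_gate) {
  stopifnot(inherits(device, "eiscap_device"), is.numeric(v_gate),
            all(is.finite(v_gate)))
  st <- device$stack
  cins <- insulator_capacitance(st)
  a_m2 <- st$area_mm2 * 1e-6
  na_m3 <- st$doping_na_cm3 * 1e6
  phi_f <- (.kB * st$temperature_k / .q) * log(st$doping_na_cm3 / .ni_cm3)
  gamma <- sqrt(2 * .q * .eps_si * .eps0 * na_m3) / (cins / a_m2)
  vfb <- effective_flatband(st, device$chem,
                            surface_ph(device$solution, device$enzyme)) +
    device$circuit$drift_v_per_s * device$time_s
  vapply(v_gate, function(v) {
    if (v <= vfb) return(cins)
    psi <- min(.surface_potential(v - vfb, gamma), 2 * phi_f)
    csc <- a_m2 * sqrt(.q * .eps_si * .eps0 * na_m3 / (2 * psi))
    1 / (1 / cins + 1 / csc)
  }, numeric(1))
}

#' Small-signal impedance of the device
#'
#' Series-RC equivalent circuit: the reference-electrode/solution series
#' resistance plus the capacitive reactance of the stack,
#' \eqn{Z = R_s + 1/(j 2\pi f C)}. The magnitude tends to `r_series_ohm` at
#' high frequency (the resistive plateau) and the phase to -90 degrees at
#' low frequency.
#'
#' @param device An [eiscap_device()].
#' @param v_gate Gate voltage, V.
#' @param freq AC frequency, Hz (> 0).
#' @return A complex impedance in ohms.
#' @export
impedance <- function(device, v_gate, freq) {
  stopifnot(inherits(device, "eiscap_device"))
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0)
    stop("'freq' must be a positive number (Hz)", call. = FALSE)
  cc <- hf_capacitance(device, v_gate)
  complex(real = device$circuit$r_series_ohm, imaginary = -1 / (2 * pi * freq * cc))
}

# ---- device contract ------------------------------------------------------

#' Device contract: perform one impedance measurement
#'
#' The abstract instrument-facing surface: any backend (the simulator here, or
#' a real potentiostat driver) must measure the complex impedance at a gate
#' voltage and AC frequency, honour [set_solution()], report its hardware
#' limits via [device_limits()], and advance its internal clock via
#' [elapse_time()]. The simulator backend adds Gaussian capacitance noise
#' (`noise_sd_c_f`) from its private seeded stream before forming Z.
#'
#' @param device A backend object.
#' @param v_gate Gate voltage, V.
#' @param freq AC frequency, Hz.
#' @param ... Passed to methods.
#' @return Complex impedance, ohms.
#' @export
measure_impedance <- function(device, v_gate, freq, ...) {
  UseMethod("measure_impedance")
}

#' @export
measure_impedance.eiscap_device <- function(device, v_gate, freq, ...) {
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0)
    stop("'freq' must be a positive number (Hz)", call. = FALSE)
  cc <- hf_capacitance(device, v_gate)
  if (device$circuit$noise_sd_c_f > 0) {
    cc <- cc + device$circuit$noise_sd_c_f * .device_rnorm(device, 1L)
    cc <- max(cc, 1e-15)  # keep the measured reactance physical
  }
  complex(real = device$circuit$r_series_ohm, imaginary = -1 / (2 * pi * freq * cc))
}

#' Device contract: exchange the measurement solution
#'
#' @param device A backend object.
#' @param solution A [solution_state()].
#' @param ... Passed to methods.
#' @return The device, invisibly.
#' @export
set_solution <- function(device, solution, ...) UseMethod("set_solution")

#' @export
set_solution.eiscap_device <- function(device, solution, ...) {
  stopifnot(inherits(solution, "solution_state"))
  device$solution <- solution
  invisible(device)
}

#' Device contract: hardware operating limits
#'
#' @param device A backend object.
#' @return A list with `v_min`, `v_max` (V), `freq_min`, `freq_max` (Hz),
#'   `ac_min`, `ac_max` (V).
#' @export
device_limits <- function(device) UseMethod("device_limits")

#' @export
device_limits.eiscap_device <- function(device) {
  list(v_min = -2.0, v_max = 1.2,
       freq_min = 0.016, freq_max = 200e3,
       ac_min = 0.001, ac_max = 0.250)
}

#' Device contract: advance the device clock
#'
#' Used by time-resolved modes; the simulator applies its configured baseline
#' drift as a function of this clock.
#'
#' @param device A backend object.
#' @param seconds Time increment, s.
#' @return The device, invisibly.
#' @export
elapse_time <- function(device, seconds) UseMethod("elapse_time")

#' @export
elapse_time.eiscap_device <- function(device, seconds) {
  stopifnot(is.numeric(seconds), seconds >= 0)
  device$time_s <- device$time_s + seconds
  invisible(device)
}
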