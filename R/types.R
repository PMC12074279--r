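# Validated constructors for the device description types. Each returns a
# plain classed list; validation errors name the offending field.

.check_num <- function(x, field, lower = -Inf, upper = Inf,
                       strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", field), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g outside the valid range %s%g, %g%s", field, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  as.numeric(x)
}

#' Layered sensor stack geometry and semiconductor parameters
#'
#' Describes the Al/p-Si/SiO2/Ta2O5 capacitor under test: the two insulator
#' layers facing the solution, the contact area, the p-type doping, and the
#' flat-band voltage at the reference pH with no analyte. Defaults follow the
#' fabricated device: 30 nm SiO2 under a 60 nm Ta2O5 pH-sensitive film with a
#' 52 mm^2 solution contact area.
#'
#' @param d_sio2_nm SiO2 thickness, nm.
#' @param d_ta2o5_nm Ta2O5 thickness, nm.
#' @param area_mm2 Solution contact area, mm^2.
#' @param eps_sio2,eps_ta2o5 Relative permittivities (literature values 3.9
#'   and 27 by default).
#' @param doping_na_cm3 Acceptor density of the p-Si substrate, cm^-3.
#' @param temperature_k Temperature, K.
#' @param flatband_v0 Flat-band voltage (V) at the reference pH (`ph_pzc` of
#'   [surface_chemistry()]) with no analyte present.
#' @return An object of class `sensor_stack`.
#' @examples
#' st <- sensor_stack()
#' insulator_capacitance(st) * 1e9  # ~46.4 nF
#' @export
sensor_stack <- function(d_sio2_nm = 30, d_ta2o5_nm = 60, area_mm2 = 52,
                         eps_sio2 = 3.9, eps_ta2o5 = 27,
                         doping_na_cm3 = 2e16, temperature_k = 298.15,
                         flatband_v0 = -1.0) {
  out <- list(
    d_sio2_nm     = .check_num(d_sio2_nm, "d_sio2_nm", 0, strict_lower = TRUE),
    d_ta2o5_nm    = .check_num(d_ta2o5_nm, "d_ta2o5_nm", 0, strict_lower = TRUE),
    area_mm2      = .check_num(area_mm2, "area_mm2", 0, strict_lower = TRUE),
    eps_sio2      = .check_num(eps_sio2, "eps_sio2", 1),
    eps_ta2o5     = .check_num(eps_ta2o5, "eps_ta2o5", 1),
    doping_na_cm3 = .check_num(doping_na_cm3, "doping_na_cm3", 0, strict_lower = TRUE),
    temperature_k = .check_num(temperature_k, "temperature_k", 0, strict_lower = TRUE),
    flatband_v0   = .check_num(flatband_v0, "flatband_v0")
  )
  structure(out, class = "sensor_stack")
}

#' pH-to-surface-potential coupling of the gate surface
#'
#' Phenomenological site-binding response of the Ta2O5 surface: the surface
#' potential follows `alpha * nernst_slope(T) * (pH - ph_pzc)`. `alpha = 1`
#' is the ideal Nernstian limit; real oxide surfaces sit slightly below it.
#'
#' @param alpha Dimensionless sensitivity factor in (0, 1].
#' @param ph_pzc Reference pH (point of zero charge); the flat-band voltage of
#'   the stack is defined at this pH.
#' @return An object of class `surface_chemistry`.
#' @export
surface_chemistry <- function(alpha = 1, ph_pzc = 7) {
  structure(list(
    alpha  = .check_num(alpha, "alpha", 0, 1, strict_lower = TRUE),
    ph_pzc = .check_num(ph_pzc, "ph_pzc", 0, 14)
  ), class = "surface_chemistry")
}

#' Penicillinase enzyme layer
#'
#' Empirical model of the immobilized penicillinase film: hydrolysis of
#' penicillin releases protons and acidifies the gate surface, lowering the
#' local pH by `delta_ph_per_decade` for every tenfold increase of substrate
#' concentration above the onset `s_onset_mm`. Below the onset no measurable
#' local pH change occurs.
#'
#' @param present Logical; is an enzyme layer immobilized?
#' @param delta_ph_per_decade Local pH drop per decade of substrate (pH units),
#'   >= 0.
#' @param s_onset_mm Substrate concentration (mM) at which a local pH change
#'   becomes measurable, > 0.
#' @return An object of class `enzyme_layer`.
#' @export
enzyme_layer <- function(present = FALSE, delta_ph_per_decade = 1.7,
                         s_onset_mm = 0.1) {
  if (!is.logical(present) || length(present) != 1L || is.na(present))
    stop("'present' must be TRUE or FALSE", call. = FALSE)
  structure(list(
    present = present,
    delta_ph_per_decade = .check_num(delta_ph_per_decade, "delta_ph_per_decade", 0),
    s_onset_mm = .check_num(s_onset_mm, "s_onset_mm", 0, strict_lower = TRUE)
  ), class = "enzyme_layer")
}

#' Bulk solution state
#'
#' @param ph Bulk pH, in \[0, 14\].
#' @param penicillin_mm Penicillin concentration, mM, >= 0.
#' @return An object of class `solution_state`.
#' @export
solution_state <- function(ph = 7, penicillin_mm = 0) {
  structure(list(
    ph = .check_num(ph, "ph", 0, 14),
    penicillin_mm = .check_num(penicillin_mm, "penicillin_mm", 0)
  ), class = "solution_state")
}

#' External circuit and disturbance parameters
#'
#' @param r_series_ohm Series resistance of reference electrode plus solution,
#'   ohms (shows up as the high-frequency impedance plateau).
#' @param noise_sd_c_f Gaussian capacitance noise standard deviation, F
#'   (default 0: noiseless).
#' @param drift_v_per_s Linear baseline drift of the effective flat-band
#'   voltage, V/s (default 0).
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(r_series_ohm = 14e3, noise_sd_c_f = 0,
                           drift_v_per_s = 0) {
  structure(list(
    r_series_ohm = .check_num(r_series_ohm, "r_series_ohm", 0),
    noise_sd_c_f = .check_num(noise_sd_c_f, "noise_sd_c_f", 0),
    drift_v_per_s = .check_num(drift_v_per_s, "drift_v_per_s")
  ), class = "circuit_params")
}

#' PID controller settings for ConCap mode
#'
#' Gains act on the capacitance error `e = C_measured - C_wp` and are applied
#' in incremental (velocity) form, so the commanded voltage can be clamped to
#' the hardware limits without integral wind-up.
#'
#' @param kp Proportional gain, V/F.
#' @param ki Integral gain, V/(F s).
#' @param kd Derivative gain, V s/F.
#' @param dt Control interval, s (> 0).
#' @param tolerance Capacitance tolerance defining "settled", F (> 0).
#' @return An object of class `pid_gains`.
#' @seealso [auto_pid_gains()] to derive gains from a measured C-V curve.
#' @export
pid_gains <- function(kp, ki, kd = 0, dt = 0.1, tolerance = 1e-11) {
  structure(list(
    kp = .check_num(kp, "kp"),
    ki = .check_num(ki, "ki"),
    kd = .check_num(kd, "kd"),
    dt = .check_num(dt, "dt", 0, strict_lower = TRUE),
    tolerance = .check_num(tolerance, "tolerance", 0, strict_lower = TRUE)
  ), class = "pid_gains")
}

#' Timed sequence of solution exchanges
#'
#' Builds the schedule consumed by [run_concap()]: one row per measurement
#' segment, in order.
#'
#' @param label Character segment identifiers (unique).
#' @param ph Bulk pH per segment.
#' @param penicillin_mm Penicillin concentration per segment, mM.
#' @param duration_s Segment duration, s.
#' @return A `data.frame` of class `solution_schedule`.
#' @examples
#' ph_ladder_schedule()
#' @export
solution_schedule <- function(label, ph, penicillin_mm = 0, duration_s = 30) {
  n <- length(ph)
  label <- as.character(label)
  penicillin_mm <- rep_len(penicillin_mm, n)
  duration_s <- rep_len(duration_s, n)
  if (length(label) != n)
    stop("'label' and 'ph' must have the same length", call. = FALSE)
  if (anyDuplicated(label))
    stop("segment labels must be unique", call. = FALSE)
  for (i in seq_len(n)) {
    .check_num(ph[i], sprintf("ph[%d]", i), 0, 14)
    .check_num(penicillin_mm[i], sprintf("penicillin_mm[%d]", i), 0)
    .check_num(duration_s[i], sprintf("duration_s[%d]", i), 0, strict_lower = TRUE)
  }
  structure(
    data.frame(label = label, ph = as.numeric(ph),
               penicillin_mm = as.numeric(penicillin_mm),
               duration_s = as.numeric(duration_s),
               stringsAsFactors = FALSE),
    class = c("solution_schedule", "data.frame"))
}

#' @rdname solution_schedule
#' @param duration_per_segment_s Duration of each pH step, s.
#' @details `ph_ladder_schedule()` builds the standard nine-step pH ladder
#'   7-6-5-6-7-8-9-8-7 used for pH calibration.
#' @export
ph_ladder_schedule <- function(duration_per_segment_s = 30) {
  ph <- c(7, 6, 5, 6, 7, 8, 9, 8, 7)
  solution_schedule(label = sprintf("s%02d_pH%g", seq_along(ph), ph),
                    ph = ph, penicillin_mm = 0,
                    duration_s = duration_per_segment_s)
}

#' @rdname solution_schedule
#' @param conc_mm Penicillin concentrations (mM) measured after the
#'   penicillin-free baseline buffer.
#' @param buffer_ph Bulk pH of the measurement buffer.
#' @details `penicillin_schedule()` builds the baseline-plus-concentrations
#'   run used for penicillin calibration (buffer, then 0.2, 0.5, 1, 2 mM).
#' @export
penicillin_schedule <- function(conc_mm = c(0.2, 0.5, 1, 2), buffer_ph = 7.4,
                                duration_per_segment_s = 30) {
  solution_schedule(
    label = c("buffer", sprintf("pen_%gmM", conc_mm)),
    ph = rep(buffer_ph, length(conc_mm) + 1L),
    penicillin_mm = c(0, conc_mm),
    duration_s = duration_per_segment_s)
}
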