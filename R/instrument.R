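# Measurement modes run against the device contract: impedance spectrum,
# high-frequency C-V sweep with working-point selection, and the
# constant-capacitance (ConCap) PID feedback loop.

.check_v <- function(device, v, what = "gate voltage") {
  lim <- device_limits(device)
  if (any(v < lim$v_min) || any(v > lim$v_max))
    stop(sprintf("%s %g V outside the hardware limit [%g, %g] V",
                 what, v[which(v < lim$v_min | v > lim$v_max)[1]],
                 lim$v_min, lim$v_max), call. = FALSE)
  invisible(v)
}

.check_f <- function(device, f) {
  lim <- device_limits(device)
  if (any(f < lim$freq_min) || any(f > lim$freq_max))
    stop(sprintf("frequency %g Hz outside the hardware limit [%g, %g] Hz",
                 f[which(f < lim$freq_min | f > lim$freq_max)[1]],
                 lim$freq_min, lim$freq_max), call. = FALSE)
  invisible(f)
}

.check_ac <- function(device, ac) {
  lim <- device_limits(device)
  if (ac < lim$ac_min || ac > lim$ac_max)
    stop(sprintf("AC amplitude %g V outside the hardware limit [%g, %g] V",
                 ac, lim$ac_min, lim$ac_max), call. = FALSE)
  invisible(ac)
}

#' Record an impedance spectrum
#'
#' Measures the complex impedance at `n_points` logarithmically spaced
#' frequencies at a fixed gate voltage. For the series-RC device the
#' magnitude falls from the capacitive reactance at low frequency to the
#' series-resistance plateau at high frequency.
#'
#' @param device A device-contract backend, e.g. [eiscap_device()].
#' @param v_gate Gate voltage, V (default -2 V, deep accumulation).
#' @param f_lo,f_hi Frequency range, Hz (defaults 20 Hz to 5 kHz).
#' @param n_points Number of frequencies (>= 1; `n_points = 1` measures at
#'   `f_lo`).
#' @return An object of class `impedance_spectrum`: a data frame with columns
#'   `freq_hz`, `zmag_ohm`, `phase_deg`, carrying `v_gate` as an attribute.
#' @export
run_impedance_spectrum <- function(device, v_gate = -2, f_lo = 20, f_hi = 5e3,
                                   n_points = 30L) {
  stopifnot(n_points >= 1)
  if (f_lo >= f_hi) stop("'f_lo' must be below 'f_hi'", call. = FALSE)
  .check_v(device, v_gate)
  .check_f(device, c(f_lo, f_hi))
  freqs <- 10^seq(log10(f_lo), log10(f_hi), length.out = n_points)
  z <- vapply(freqs, function(f) measure_impedance(device, v_gate, f),
              complex(1))
  out <- data.frame(frequency_hz = freqs, zmag_ohm = Mod(z),
                    phase_deg = Arg(z) * 180 / pi)
  structure(out, class = c("impedance_spectrum", "data.frame"),
            v_gate = v_gate)
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d points, %.3g Hz - %.3g Hz at %g V\n",
              nrow(x), min(x$frequency_hz), max(x$frequency_hz), attr(x, "v_gate")))
  cat(sprintf("  |Z| %.3g -> %.3g ohm; phase %.1f -> %.1f deg\n",
              x$zmag_ohm[1], x$zmag_ohm[nrow(x)],
              x$phase_deg[1], x$phase_deg[nrow(x)]))
  invisible(x)
}

#' Extract capacitance from one impedance measurement
#'
#' Measures Z at the given voltage and frequency and returns
#' `C = -1 / (2 pi f Im(Z))`. The series resistance only enters the real
#' part, so for a series-RC backend the backend's true capacitance is
#' recovered exactly regardless of `r_series_ohm`.
#'
#' @inheritParams run_impedance_spectrum
#' @param freq AC frequency, Hz.
#' @return Capacitance, F.
#' @export
measure_capacitance <- function(device, v_gate, freq) {
  .check_v(device, v_gate)
  .check_f(device, freq)
  z <- measure_impedance(device, v_gate, freq)
  if (Im(z) >= 0)
    stop("non-capacitive response: Im(Z) >= 0 at ", v_gate, " V, ",
         freq, " Hz", call. = FALSE)
  -1 / (2 * pi * freq * Im(z))
}

#' Construct a C-V curve object
#'
#' Normally produced by [run_cv_sweep()]; the constructor is exported so
#' curves can be rebuilt from files or supplied by hand.
#'
#' @param voltage_v Strictly increasing gate voltages, V.
#' @param capacitance_f Positive capacitances, F (same length).
#' @param freq_hz Measurement frequency, Hz.
#' @param ac_amplitude_v Superimposed AC amplitude, V.
#' @param solution The [solution_state()] the curve was recorded in, or NULL.
#' @return An object of class `cv_curve`.
#' @export
cv_curve <- function(voltage_v, capacitance_f, freq_hz = 120,
                     ac_amplitude_v = 0.02, solution = NULL) {
  if (length(voltage_v) != length(capacitance_f))
    stop("voltage and capacitance vectors must have equal length", call. = FALSE)
  if (is.unsorted(voltage_v, strictly = TRUE))
    stop("voltages must be strictly increasing", call. = FALSE)
  if (any(capacitance_f <= 0))
    stop("capacitances must be positive", call. = FALSE)
  structure(data.frame(voltage_v = as.numeric(voltage_v),
                       capacitance_f = as.numeric(capacitance_f)),
            class = c("cv_curve", "data.frame"),
            freq_hz = freq_hz, ac_amplitude_v = ac_amplitude_v,
            solution = solution)
}

#' Run a capacitance-voltage sweep
#'
#' Single-pass staircase sweep from `v_start` to `v_end` measuring the
#' capacitance at every grid voltage via [measure_capacitance()]. Defaults
#' follow the standard characterization conditions: -2 V to +1 V in 100 mV
#' steps with a 20 mV AC excitation at 120 Hz (31 points).
#'
#' @inheritParams run_impedance_spectrum
#' @param v_start,v_end Sweep limits, V (`v_start < v_end`).
#' @param step Voltage step, V (> 0).
#' @param freq AC frequency, Hz.
#' @param ac_amplitude AC amplitude, V (recorded; the small-signal model is
#'   amplitude-independent).
#' @return A [cv_curve()].
#' @examples
#' cv <- run_cv_sweep(eiscap_device())
#' nrow(cv)  # 31
#' @export
run_cv_sweep <- function(device, v_start = -2, v_end = 1, step = 0.1,
                         freq = 120, ac_amplitude = 0.02) {
  if (!(v_start < v_end)) stop("'v_start' must be below 'v_end'", call. = FALSE)
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  .check_v(device, c(v_start, v_end))
  .check_f(device, freq)
  .check_ac(device, ac_amplitude)
  n <- floor((v_end - v_start) / step + 1e-9) + 1L
  grid <- v_start + step * (seq_len(n) - 1L)
  caps <- vapply(grid, function(v) measure_capacitance(device, v, freq),
                 numeric(1))
  cv_curve(grid, caps, freq_hz = freq, ac_amplitude_v = ac_amplitude,
           solution = device$solution)
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("C-V curve: %d points, %g V to %g V at %g Hz\n",
              nrow(x), x$voltage_v[1], x$voltage_v[nrow(x)],
              attr(x, "freq_hz")))
  cat(sprintf("  C: %.2f nF (max) -> %.2f nF (min)\n",
              max(x$capacitance_f) * 1e9, min(x$capacitance_f) * 1e9))
  invisible(x)
}

# voltage at which the curve crosses capacitance cref, scanning from the
# accumulation end (most negative voltage) and linearly interpolating between
# the first bracketing pair -- the rule used for V_wp and shift extraction
.v_at_c <- function(voltage, capacitance, cref) {
  n <- length(voltage)
  for (i in seq_len(n - 1L)) {
    ci <- capacitance[i]; cj <- capacitance[i + 1L]
    if ((ci - cref) * (cj - cref) <= 0) {
      if (ci == cj) return(voltage[i])
      return(voltage[i] + (cref - ci) * (voltage[i + 1L] - voltage[i]) / (cj - ci))
    }
  }
  stop(sprintf("capacitance %.4g F outside the measured span [%.4g, %.4g] F",
               cref, min(capacitance), max(capacitance)), call. = FALSE)
}

#' Interpolate a C-V curve at a gate voltage
#'
#' Piecewise-linear interpolation of the measured curve; the inverse of the
#' crossing rule used by [select_working_point()].
#'
#' @param cv A [cv_curve()].
#' @param v Gate voltage(s) within the curve's range.
#' @return Capacitance(s), F.
#' @export
interpolate_capacitance <- function(cv, v) {
  stopifnot(inherits(cv, "cv_curve"))
  stats::approx(cv$voltage_v, cv$capacitance_f, xout = v, rule = 1)$y
}

#' Select the ConCap working point from a C-V curve
#'
#' In automatic mode the working-point capacitance is 60% of the maximum
#' measured capacitance (the accumulation plateau); in manual mode it is
#' supplied by the user. The working-point voltage is found by scanning the
#' curve from the accumulation end (most negative voltage) and linearly
#' interpolating between the first pair of measured points whose capacitances
#' bracket the target, so the returned `v_wp` lies on the depletion flank
#' adjacent to accumulation.
#'
#' @param cv A [cv_curve()] with at least two points.
#' @param manual_c_wp Manual working-point capacitance, F, strictly between
#'   the curve's minimum and maximum; omit (NULL) for the automatic 60% rule.
#' @return An object of class `working_point`: list with `c_wp` (F), `v_wp`
#'   (V) and `mode` ("auto" or "manual").
#' @examples
#' cv <- run_cv_sweep(eiscap_device())
#' select_working_point(cv)            # auto: 60% of maximum
#' select_working_point(cv, 30e-9)     # the 30 nF inflection-point choice
#' @export
select_working_point <- function(cv, manual_c_wp = NULL) {
  stopifnot(inherits(cv, "cv_curve"), nrow(cv) >= 2)
  cmax <- max(cv$capacitance_f); cmin <- min(cv$capacitance_f)
  if (is.null(manual_c_wp)) {
    c_wp <- 0.6 * cmax
    mode <- "auto"
    if (c_wp <= cmin)
      stop("60% of the maximum capacitance lies below the measured span; ",
           "sweep further into inversion or set the working point manually",
           call. = FALSE)
  } else {
    c_wp <- .check_num(manual_c_wp, "manual_c_wp")
    mode <- "manual"
    if (c_wp <= cmin || c_wp >= cmax)
      stop(sprintf(
        "manual_c_wp = %.4g F must lie strictly between the measured %.4g F and %.4g F",
        c_wp, cmin, cmax), call. = FALSE)
  }
  v_wp <- .v_at_c(cv$voltage_v, cv$capacitance_f, c_wp)
  structure(list(c_wp = c_wp, v_wp = v_wp, mode = mode),
            class = "working_point")
}

#' @export
print.working_point <- function(x, ...) {
  cat(sprintf("Working point (%s): C_wp = %.3f nF at V_wp = %.4f V\n",
              x$mode, x$c_wp * 1e9, x$v_wp))
  invisible(x)
}

#' Derive PID gains from the C-V curve at the working point
#'
#' Proportional-dominant gains scaled by the inverse local slope of the C-V
#' curve at the working point, `|dV/dC|`, giving a settling time of a few
#' control intervals for pH steps within the quasi-linear depletion flank.
#'
#' @param cv The [cv_curve()] the working point was selected on.
#' @param wp A [working_point()].
#' @param dt Control interval, s.
#' @param tolerance Settled-capacitance tolerance, F.
#' @return A [pid_gains()] object.
#' @export
auto_pid_gains <- function(cv, wp, dt = 0.1, tolerance = 1e-11) {
  stopifnot(inherits(cv, "cv_curve"), inherits(wp, "working_point"))
  # slope of the bracketing segment actually used for V_wp
  i <- max(findInterval(wp$v_wp, cv$voltage_v), 1L)
  i <- min(i, nrow(cv) - 1L)
  g <- (cv$capacitance_f[i + 1L] - cv$capacitance_f[i]) /
    (cv$voltage_v[i + 1L] - cv$voltage_v[i])
  if (g == 0) stop("C-V curve is flat at the working point; cannot scale gains",
                   call. = FALSE)
  pid_gains(kp = 0.5 / abs(g), ki = 0.5 / (abs(g) * dt), kd = 0,
            dt = dt, tolerance = tolerance)
}

#' Run a constant-capacitance (ConCap) measurement
#'
#' Time-resolved readout: a discrete-time PID loop adjusts the gate voltage
#' every `gains$dt` seconds to hold the measured capacitance at the working
#' point while the solution steps through `schedule`. Because the C-V curve
#' translates rigidly with surface potential, the controller output tracks
#' the pH- (or analyte-) induced potential shifts in real time. The PID runs
#' in incremental form with the sign convention for p-type devices
#' (dC/dV < 0 on the depletion flank): a positive capacitance error drives
#' the voltage upward. Commanded voltages are clamped to the hardware limits.
#'
#' @param device A device-contract backend.
#' @param wp A [working_point()].
#' @param gains A [pid_gains()] (see [auto_pid_gains()]).
#' @param schedule A [solution_schedule()].
#' @param freq AC measurement frequency, Hz.
#' @param dead_time_s Buffer-exchange dead time, s: samples within this window
#'   after each solution change are not recorded (default 0).
#' @param v_init Initial gate voltage, V (defaults to `wp$v_wp`).
#' @param control_sign `+1` for p-type devices (default); `-1` inverts the
#'   loop for backends with dC/dV > 0 at the working point.
#' @return An object of class `concap_trace`: data frame with columns
#'   `time_s`, `voltage_v`, `capacitance_f`, `segment`, plus attributes
#'   `c_wp`, `gains`, `schedule` and a character vector `warnings`
#'   (convergence/rail diagnostics; empty if clean).
#' @examples
#' dev <- eiscap_device()
#' cv <- run_cv_sweep(dev)
#' wp <- select_working_point(cv, 30e-9)
#' tr <- run_concap(dev, wp, auto_pid_gains(cv, wp),
#'                  ph_ladder_schedule(duration_per_segment_s = 10))
#' @export
run_concap <- function(device, wp, gains, schedule, freq = 120,
                       dead_time_s = 0, v_init = wp$v_wp, control_sign = 1) {
  stopifnot(inherits(wp, "working_point"), inherits(gains, "pid_gains"),
            inherits(schedule, "solution_schedule"), nrow(schedule) >= 1,
            control_sign %in% c(-1, 1))
  .check_f(device, freq)
  lim <- device_limits(device)
  v <- .check_v(device, v_init, "initial voltage")
  dt <- gains$dt
  c_wp <- wp$c_wp
  warns <- character(0)

  n_total <- sum(vapply(schedule$duration_s, function(d) max(round(d / dt), 1L),
                        numeric(1)))
  times <- numeric(n_total); volts <- numeric(n_total)
  caps <- numeric(n_total); segs <- character(n_total)
  keep <- logical(n_total)

  t <- 0; k <- 0L
  e_prev <- NA_real_; e_prev2 <- NA_real_
  for (s in seq_len(nrow(schedule))) {
    set_solution(device, solution_state(ph = schedule$ph[s],
                                        penicillin_mm = schedule$penicillin_mm[s]))
    seg_t0 <- t
    n_steps <- max(round(schedule$duration_s[s] / dt), 1L)
    railed <- FALSE
    e <- NA_real_
    for (j in seq_len(n_steps)) {
      elapse_time(device, dt)
      t <- t + dt
      cm <- measure_capacitance(device, v, freq)
      e <- cm - c_wp
      k <- k + 1L
      times[k] <- t; volts[k] <- v; caps[k] <- cm
      segs[k] <- schedule$label[s]
      keep[k] <- (t - seg_t0) > dead_time_s || dead_time_s <= 0
      if (is.na(e_prev)) { e_prev <- e; e_prev2 <- e }
      dv <- control_sign * (gains$kp * (e - e_prev) + gains$ki * dt * e +
                              gains$kd * (e - 2 * e_prev + e_prev2) / dt)
      v_new <- v + dv
      if (v_new < lim$v_min || v_new > lim$v_max) {
        v_new <- min(max(v_new, lim$v_min), lim$v_max)
        railed <- TRUE
      }
      e_prev2 <- e_prev; e_prev <- e
      v <- v_new
    }
    if (railed)
      warns <- c(warns, sprintf("segment '%s': commanded voltage railed at a hardware limit",
                                schedule$label[s]))
    if (abs(e) >= gains$tolerance)
      warns <- c(warns, sprintf("segment '%s': not settled (|e| = %.3g F >= tolerance %.3g F)",
                                schedule$label[s], abs(e), gains$tolerance))
  }
  out <- data.frame(time_s = times[keep], voltage_v = volts[keep],
                    capacitance_f = caps[keep], segment = segs[keep],
                    stringsAsFactors = FALSE)
  structure(out, class = c("concap_trace", "data.frame"),
            c_wp = c_wp, gains = gains, schedule = schedule,
            warnings = warns)
}

#' @export
print.concap_trace <- function(x, ...) {
  segs <- unique(x$segment)
  cat(sprintf("ConCap trace: %d samples, %.1f s, %d segments (C_wp = %.2f nF)\n",
              nrow(x), max(x$time_s), length(segs), attr(x, "c_wp") * 1e9))
  w <- attr(x, "warnings")
  if (length(w)) cat("  warnings:\n", paste0("   - ", w, "\n"), sep = "")
  invisible(x)
}

# mean controller voltage over the settled (final) fraction of one segment
.settled_mean <- function(trace, label, settle_frac = 0.5) {
  idx <- which(trace$segment == label)
  if (!length(idx))
    stop(sprintf("segment '%s' not found in trace", label), call. = FALSE)
  n <- length(idx)
  tail_idx <- idx[(n - ceiling(n * settle_frac) + 1L):n]
  mean(trace$voltage_v[tail_idx])
}

#' Offset-correct a ConCap trace to its baseline segment
#'
#' Subtracts the settled mean voltage of the baseline segment from the whole
#' trace, so the baseline reads 0 mV (the standard presentation of ConCap
#' responses). Applying the correction twice is a no-op.
#'
#' @param trace A [run_concap()] trace.
#' @param baseline_segment Label of the baseline segment (default: the first
#'   segment of the schedule).
#' @param settle_frac Fraction of each segment's final samples regarded as
#'   settled (default 0.5).
#' @return The corrected `concap_trace`; the subtracted offset is stored in
#'   attribute `offset_v`.
#' @export
offset_correct <- function(trace, baseline_segment = NULL, settle_frac = 0.5) {
  stopifnot(inherits(trace, "concap_trace"))
  if (is.null(baseline_segment)) baseline_segment <- trace$segment[1]
  off <- .settled_mean(trace, baseline_segment, settle_frac)
  trace$voltage_v <- trace$voltage_v - off
  attr(trace, "offset_v") <- off + (attr(trace, "offset_v") %||% 0)
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a
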