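# End-to-end reference scenarios: the standard characterization experiments
# run in simulation with the default device, producing the CSV products and
# calibration reports.

.write_fit_report <- function(fit, path, title) {
  lines <- c(sprintf("# %s", title),
             sprintf("x_kind: %s", fit$x_kind),
             sprintf("n_points: %d", fit$n),
             sprintf("slope_mv_per_unit: %.6f", fit$slope),
             sprintf("slope_se_mv_per_unit: %.6f", fit$slope_se),
             sprintf("intercept_mv: %.6f", fit$intercept),
             sprintf("sensitivity: %.1f +/- %.1f %s", abs(fit$slope),
                     fit$slope_se, .unit_of(fit$x_kind)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the reference characterization scenarios in simulation
#'
#' Reproduces the standard bench experiments end-to-end on the default
#' simulated device and writes all products and fit reports to
#' `output_dir`:
#' \enumerate{
#'   \item impedance spectrum at -2 V, 20 Hz to 5 kHz, pH 7;
#'   \item C-V sweeps at pH 5-9 with shift extraction at 30 nF and a
#'     shift-vs-pH sensitivity fit;
#'   \item ConCap pH ladder 7-6-5-6-7-8-9-8-7 with offset correction and a
#'     settled-mean calibration fit (near-Nernstian, ~59 mV/pH);
#'   \item penicillin biosensor run (buffer + 0.2/0.5/1/2 mM) with a
#'     log10-concentration calibration fit (~100 mV/dec by default);
#'   \item wide-range ConCap ladder from pH 2 to pH 12.
#' }
#'
#' @param output_dir Directory for products and reports (created if needed).
#' @param seed Seed for the devices' noise streams (noise is off by default,
#'   so results are deterministic; the seed is still recorded).
#' @param segment_duration_s ConCap segment duration, s.
#' @param dt PID control interval, s.
#' @param c_wp_f Manual working-point capacitance, F (default the 30 nF
#'   depletion-flank inflection choice).
#' @return Invisibly, a list with the products and `calibration_fit` objects
#'   per scenario.
#' @export
run_reference_scenarios <- function(output_dir, seed = 1L,
                                    segment_duration_s = 30, dt = 0.1,
                                    c_wp_f = 30e-9) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  # 1: impedance spectrum in accumulation
  dev <- eiscap_device(rng_seed = seed)
  spec <- run_impedance_spectrum(dev, v_gate = -2, f_lo = 20, f_hi = 5e3,
                                 n_points = 40L)
  write_product(spec, file.path(output_dir, "spectrum_ph7.csv"), device = dev)
  out$spectrum <- spec

  # 2: C-V set at pH 5..9 and shift-vs-pH sensitivity
  cvs <- lapply(5:9, function(ph) {
    set_solution(dev, solution_state(ph = ph))
    cv <- run_cv_sweep(dev)
    write_product(cv, file.path(output_dir, sprintf("cv_ph%d.csv", ph)),
                  device = dev)
    cv
  })
  names(cvs) <- sprintf("ph%d", 5:9)
  shifts <- vapply(cvs, function(cv) extract_cv_shift(cvs$ph7, cv, c_wp_f),
                   numeric(1))
  fit_cv <- fit_calibration(5:9, shifts, x_kind = "ph")
  .write_fit_report(fit_cv, file.path(output_dir, "fit_cv_shift_ph.txt"),
                    "C-V shift vs pH sensitivity")
  out$cv_set <- cvs; out$fit_cv_shift <- fit_cv

  # 3: ConCap pH ladder with calibration
  dev3 <- eiscap_device(rng_seed = seed)
  cv7 <- run_cv_sweep(dev3)
  wp <- select_working_point(cv7, c_wp_f)
  gains <- auto_pid_gains(cv7, wp, dt = dt)
  tr <- run_concap(dev3, wp, gains,
                   ph_ladder_schedule(duration_per_segment_s = segment_duration_s))
  tr <- offset_correct(tr)
  write_product(tr, file.path(output_dir, "concap_ph_ladder.csv"), device = dev3)
  pts <- concap_calibration_points(tr, x_kind = "ph")
  fit_ladder <- fit_calibration(pts$x, pts$potential_mv, x_kind = "ph")
  .write_fit_report(fit_ladder, file.path(output_dir, "fit_concap_ph.txt"),
                    "ConCap pH ladder sensitivity")
  out$concap_ladder <- tr; out$fit_concap_ph <- fit_ladder

  # 4: penicillin biosensor (enzyme layer on, pH 7.4 buffer)
  dev4 <- eiscap_device(enzyme = enzyme_layer(present = TRUE),
                        solution = solution_state(ph = 7.4),
                        rng_seed = seed)
  cvb <- run_cv_sweep(dev4)
  wp4 <- select_working_point(cvb, c_wp_f)
  gains4 <- auto_pid_gains(cvb, wp4, dt = dt)
  sched4 <- penicillin_schedule(duration_per_segment_s = segment_duration_s)
  tr4 <- offset_correct(run_concap(dev4, wp4, gains4, sched4))
  write_product(tr4, file.path(output_dir, "concap_penicillin.csv"),
                device = dev4)
  pts4 <- concap_calibration_points(tr4, x_kind = "log10_concentration")
  fit_pen <- fit_calibration(pts4$x, pts4$potential_mv,
                             x_kind = "log10_concentration")
  .write_fit_report(fit_pen, file.path(output_dir, "fit_concap_penicillin.txt"),
                    "ConCap penicillin sensitivity")
  out$concap_penicillin <- tr4; out$fit_penicillin <- fit_pen

  # 5: wide-range pH ladder 2..12
  dev5 <- eiscap_device(rng_seed = seed)
  cv5 <- run_cv_sweep(dev5)
  wp5 <- select_working_point(cv5, c_wp_f)
  gains5 <- auto_pid_gains(cv5, wp5, dt = dt)
  ph_wide <- c(7, 2, 4, 6, 8, 10, 12, 7)
  sched5 <- solution_schedule(sprintf("w%02d_pH%g", seq_along(ph_wide), ph_wide),
                              ph_wide, duration_s = segment_duration_s)
  tr5 <- offset_correct(run_concap(dev5, wp5, gains5, sched5))
  write_product(tr5, file.path(output_dir, "concap_ph_wide.csv"), device = dev5)
  pts5 <- concap_calibration_points(tr5, x_kind = "ph")
  fit_wide <- fit_calibration(pts5$x, pts5$potential_mv, x_kind = "ph")
  .write_fit_report(fit_wide, file.path(output_dir, "fit_concap_ph_wide.txt"),
                    "Wide-range (pH 2-12) ConCap sensitivity")
  out$concap_wide <- tr5; out$fit_wide <- fit_wide

  invisible(out)
}
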