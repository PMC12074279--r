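# Property-style checks of the model invariants over generated cases.

test_that("hf capacitance never exceeds the insulator capacitance", {
  set.seed(7)
  for (i in 1:10) {
    st <- sensor_stack(d_sio2_nm = runif(1, 10, 60),
                       d_ta2o5_nm = runif(1, 20, 120),
                       area_mm2 = runif(1, 10, 100),
                       doping_na_cm3 = 10^runif(1, 15, 17),
                       flatband_v0 = runif(1, -1.5, -0.5))
    dev <- eiscap_device(stack = st,
                         solution = solution_state(ph = runif(1, 2, 12)))
    cins <- insulator_capacitance(st)
    v <- seq(-2, 1.2, length.out = 40)
    cc <- hf_capacitance(dev, v)
    expect_true(all(cc <= cins + 1e-18))
    expect_true(all(diff(cc) <= 1e-18))
  }
})

test_that("pH changes translate the C-V curve by exactly alpha * Nernst per pH", {
  s <- oracle_nernst(298.15)
  for (alpha in c(1, 0.8, 0.55)) {
    dev <- eiscap_device(chem = surface_chemistry(alpha = alpha))
    dph <- 1.5
    set_solution(dev, solution_state(ph = 7))
    c_a <- function(v) hf_capacitance(dev, v)
    v_probe <- seq(-1.3, 0.3, by = 0.05)
    ca <- c_a(v_probe)
    set_solution(dev, solution_state(ph = 7 + dph))
    # cross-interpolation: the pH-stepped curve at v + alpha*S*dph must
    # reproduce the original curve at v, point by point
    cb <- hf_capacitance(dev, v_probe + alpha * s * dph)
    expect_equal(cb, ca, tolerance = 1e-12)
  }
})

test_that("ConCap steady state equals the C-V crossing voltage after each step", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)
  sch <- solution_schedule(c("pH7", "pH5.5", "pH8.2"), c(7, 5.5, 8.2),
                           duration_s = 12)
  tr <- run_concap(default_device(), wp, gains, sch)
  probe <- default_device()
  for (i in seq_len(nrow(sch))) {
    set_solution(probe, solution_state(ph = sch$ph[i]))
    v_star <- oracle_crossing(probe, wp$c_wp)
    v_end <- tail(tr$voltage_v[tr$segment == sch$label[i]], 1)
    expect_lt(abs(v_end - v_star), 1e-6)
  }
  # and the ConCap shifts agree with the C-V shift extracted at c_wp
  dev_b <- default_device()
  set_solution(dev_b, solution_state(ph = 5.5))
  cv55 <- run_cv_sweep(dev_b)
  shift_cv <- extract_cv_shift(cv, cv55, wp$c_wp)
  dv <- (settled_mean_of(tr, "pH5.5") - settled_mean_of(tr, "pH7")) * 1e3
  expect_equal(dv, shift_cv, tolerance = 0.05)
})

test_that("enzyme response is log-linear in substrate above onset", {
  s <- oracle_nernst(298.15)
  enz <- enzyme_layer(present = TRUE, delta_ph_per_decade = 1.7,
                      s_onset_mm = 0.1)
  dev <- eiscap_device(enzyme = enz, solution = solution_state(ph = 7.4))
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)
  conc <- c(0.2, 0.5, 1, 2, 5)
  sch <- solution_schedule(sprintf("c%g", conc), rep(7.4, 5),
                           penicillin_mm = conc, duration_s = 10)
  tr <- run_concap(eiscap_device(enzyme = enz,
                                 solution = solution_state(ph = 7.4)),
                   wp, gains, sch)
  pts <- concap_calibration_points(tr, x_kind = "log10_concentration")
  fit <- fit_calibration(pts$x, pts$potential_mv, "log10_concentration")
  expect_equal(fit$slope, -1 * s * 1e3 * 1.7, tolerance = 1e-6)
  expect_lt(fit$slope_se, 1e-6)
})

test_that("noisy measurements are bit-identical across devices with equal seeds", {
  mk <- function(seed) eiscap_device(
    circuit = circuit_params(noise_sd_c_f = 0.5e-9), rng_seed = seed)
  d1 <- mk(11); d2 <- mk(11); d3 <- mk(12)
  q1 <- vapply(seq(-2, 1, by = 0.25),
               function(v) measure_capacitance(d1, v, 120), numeric(1))
  q2 <- vapply(seq(-2, 1, by = 0.25),
               function(v) measure_capacitance(d2, v, 120), numeric(1))
  q3 <- vapply(seq(-2, 1, by = 0.25),
               function(v) measure_capacitance(d3, v, 120), numeric(1))
  expect_identical(q1, q2)
  expect_false(identical(q1, q3))
  # the device stream does not disturb the session RNG
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(measure_capacitance(mk(5), -1, 120))
  expect_identical(rnorm(3), before)

  # whole ConCap traces are reproducible, including under noise
  cv <- run_cv_sweep(default_device())
  wp <- select_working_point(cv, 30e-9)
  g <- auto_pid_gains(cv, wp)
  g$tolerance <- 1e-9   # allow for the injected noise floor
  t1 <- run_concap(mk(4), wp, g, solution_schedule("a", 7, duration_s = 3))
  t2 <- run_concap(mk(4), wp, g, solution_schedule("a", 7, duration_s = 3))
  expect_identical(t1$voltage_v, t2$voltage_v)
  expect_identical(t1$capacitance_f, t2$capacitance_f)
})

test_that("baseline drift moves the ConCap output at the configured rate", {
  drift <- 2e-4  # V/s
  dev <- eiscap_device(circuit = circuit_params(drift_v_per_s = drift))
  cv <- run_cv_sweep(default_device())
  wp <- select_working_point(cv, 30e-9)
  g <- auto_pid_gains(cv, wp)
  g$tolerance <- 1e-10
  tr <- run_concap(dev, wp, g, solution_schedule("a", 7, duration_s = 20))
  late <- tr[tr$time_s > 10, ]
  rate <- coef(lm(voltage_v ~ time_s, late))[2]
  expect_equal(unname(rate), drift, tolerance = 0.02)
})
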