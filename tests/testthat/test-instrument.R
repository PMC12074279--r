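# Measurement modes: spectrum, capacitance extraction, C-V sweep,
# working-point selection, ConCap PID loop, offset correction.

test_that("impedance spectrum shows the capacitive-to-resistive transition", {
  dev <- default_device()
  sp <- run_impedance_spectrum(dev, v_gate = -2, f_lo = 20, f_hi = 5e3,
                               n_points = 25L)
  expect_s3_class(sp, "impedance_spectrum")
  expect_equal(nrow(sp), 25L)
  expect_true(!is.unsorted(sp$frequency_hz, strictly = TRUE))
  # |Z| monotone non-increasing for the series-RC backend
  expect_true(all(diff(sp$zmag_ohm) <= 0))
  # plateau at the configured series resistance at the high-frequency end
  expect_lt(abs(sp$zmag_ohm[25] - 14e3) / 14e3, 0.03)
  # phase more negative at the lowest frequency than the highest
  expect_lt(sp$phase_deg[1], sp$phase_deg[25])
  # degenerate single-point sweep measures at f_lo
  sp1 <- run_impedance_spectrum(dev, n_points = 1L)
  expect_equal(nrow(sp1), 1L)
  expect_equal(sp1$frequency_hz, 20)
  # hardware limit violations name the bound
  expect_error(run_impedance_spectrum(dev, v_gate = -3), "-2")
  expect_error(run_impedance_spectrum(dev, f_hi = 3e5), "200000|2e\\+05")
})

test_that("measure_capacitance recovers the backend capacitance for any r_series", {
  for (rs in c(0, 14e3, 1e6)) {
    dev <- eiscap_device(circuit = circuit_params(r_series_ohm = rs))
    truth <- hf_capacitance(dev, -2)
    expect_equal(measure_capacitance(dev, -2, 120), truth, tolerance = 1e-14)
  }
  # purely resistive backend raises a non-capacitive-response error
  fake <- structure(new.env(), class = "fake_resistor")
  registerS3method("measure_impedance", "fake_resistor",
                   function(device, v_gate, freq, ...)
                     complex(real = 100, imaginary = 0),
                   envir = asNamespace("eiscap"))
  registerS3method("device_limits", "fake_resistor",
                   function(device)
                     list(v_min = -2, v_max = 1.2, freq_min = 0.016,
                          freq_max = 2e5, ac_min = 1e-3, ac_max = 0.25),
                   envir = asNamespace("eiscap"))
  expect_error(measure_capacitance(fake, 0, 120), "non-capacitive")
})

test_that("C-V sweep produces the default 31-point non-increasing curve", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  expect_s3_class(cv, "cv_curve")
  expect_equal(nrow(cv), 31L)
  expect_equal(cv$voltage_v, seq(-2, 1, by = 0.1), tolerance = 1e-12)
  expect_equal(cv$capacitance_f[1], oracle_cins(), tolerance = 1e-9)
  expect_true(all(diff(cv$capacitance_f) <= 1e-18))
  expect_equal(attr(cv, "freq_hz"), 120)
  # two-point degenerate sweep
  cv2 <- run_cv_sweep(dev, v_start = -2, v_end = -1.9, step = 0.1)
  expect_equal(nrow(cv2), 2L)
  expect_error(run_cv_sweep(dev, v_start = 1, v_end = -2), "v_start")
  expect_error(run_cv_sweep(dev, step = -0.1), "step")
})

test_that("working-point selection interpolates from the accumulation side", {
  # midpoint of a linear segment
  cv <- cv_curve(c(0, 0.1), c(40e-9, 20e-9))
  wp <- select_working_point(cv, 30e-9)
  expect_equal(wp$v_wp, 0.05, tolerance = 1e-12)
  expect_identical(wp$mode, "manual")

  # auto rule: 60% of the curve maximum
  dev <- default_device()
  cvd <- run_cv_sweep(dev)
  wpa <- select_working_point(cvd)
  expect_identical(wpa$mode, "auto")
  expect_equal(wpa$c_wp, 0.6 * max(cvd$capacitance_f), tolerance = 1e-15)

  # the 30 nF manual choice lands on the depletion flank (-1 V .. +0.5 V)
  wp30 <- select_working_point(cvd, 30e-9)
  expect_gt(wp30$v_wp, -1)
  expect_lt(wp30$v_wp, 0.5)

  # round trip: interpolating the curve at v_wp returns c_wp
  expect_equal(interpolate_capacitance(cvd, wp30$v_wp), 30e-9,
               tolerance = 1e-12)
  expect_equal(interpolate_capacitance(cvd, wpa$v_wp), wpa$c_wp,
               tolerance = 1e-12)

  # non-monotone curve: first bracketing pair from the accumulation end wins
  wig <- cv_curve(c(0, 0.1, 0.2, 0.3), c(40e-9, 30e-9, 35e-9, 20e-9))
  wpw <- select_working_point(wig, 32e-9)
  expect_equal(wpw$v_wp, 0.08, tolerance = 1e-12)

  # manual target outside the measured span is rejected
  expect_error(select_working_point(cvd, 50e-9), "between")
  expect_error(select_working_point(cvd, 1e-9), "between")
})

test_that("ConCap holds the working point and tracks Nernstian pH steps", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)

  # equilibrium initialization: constant solution, start at the true crossing
  dev_eq <- default_device()
  v_star <- oracle_crossing(dev_eq, wp$c_wp)
  wp_eq <- structure(list(c_wp = wp$c_wp, v_wp = v_star, mode = "manual"),
                     class = "working_point")
  tr_eq <- run_concap(dev_eq, wp_eq, gains,
                      solution_schedule("hold", 7, duration_s = 5))
  expect_true(all(abs(tr_eq$voltage_v - v_star) < 1e-12))
  expect_length(attr(tr_eq, "warnings"), 0)

  # single pH step 7 -> 6: steady-state shift is one Nernst slope downward
  dev_st <- default_device()
  tr <- run_concap(dev_st, wp, gains,
                   solution_schedule(c("pH7", "pH6"), c(7, 6),
                                     duration_s = 15))
  v7 <- mean(tail(tr$voltage_v[tr$segment == "pH7"], 50))
  v6 <- mean(tail(tr$voltage_v[tr$segment == "pH6"], 50))
  expect_equal((v6 - v7) * 1e3, -oracle_nernst(298.15) * 1e3,
               tolerance = 1e-6)
  expect_length(attr(tr, "warnings"), 0)

  # ladder: steady-state potentials symmetric about pH 7 and monotone in pH
  dev_l <- default_device()
  trl <- run_concap(dev_l, wp, gains, ph_ladder_schedule(10))
  sm <- vapply(unique(trl$segment), function(s)
    mean(tail(trl$voltage_v[trl$segment == s], 30)), numeric(1))
  ph <- c(7, 6, 5, 6, 7, 8, 9, 8, 7)
  sm <- unname(sm)
  expect_equal(sm[2] - sm[1], -(sm[6] - sm[5]), tolerance = 1e-9)  # 6 vs 8
  expect_equal(sm[3] - sm[1], -(sm[7] - sm[5]), tolerance = 1e-9)  # 5 vs 9
  expect_true(all(diff(sm[order(ph)][!duplicated(sort(ph))]) > 0))
  # revisited pH values reproduce (no noise, no drift)
  expect_equal(sm[2], sm[4], tolerance = 1e-9)
  expect_equal(unname(sm[1]), mean(tail(trl$voltage_v[trl$segment == unique(trl$segment)[9]], 30)),
               tolerance = 1e-9)
})

test_that("ConCap clamps commanded voltages and reports rails and non-settling", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)
  lim <- device_limits(dev)
  # an extreme pH step drives the controller toward the negative rail
  tr <- run_concap(default_device(), wp,
                   pid_gains(kp = gains$kp * 50, ki = gains$ki * 50,
                             dt = gains$dt, tolerance = gains$tolerance),
                   solution_schedule(c("a", "b"), c(7, 1), duration_s = 3))
  expect_true(all(tr$voltage_v >= lim$v_min & tr$voltage_v <= lim$v_max))

  # hopeless tolerance is reported as a convergence warning in the metadata
  tight <- pid_gains(kp = gains$kp, ki = gains$ki, dt = gains$dt,
                     tolerance = 1e-30)
  trt <- run_concap(default_device(), wp, tight,
                    solution_schedule("x", 6, duration_s = 2))
  expect_match(attr(trt, "warnings"), "not settled", all = FALSE)
})

test_that("buffer-exchange dead time masks samples after each solution change", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)
  tr <- run_concap(default_device(), wp, gains,
                   solution_schedule(c("a", "b"), c(7, 8), duration_s = 5),
                   dead_time_s = 1)
  ta <- tr$time_s[tr$segment == "a"]
  tb <- tr$time_s[tr$segment == "b"]
  expect_gt(min(ta), 1)            # masked at the start of the run
  expect_gt(min(tb) - 5, 1 - 1e-9) # masked after the exchange at t = 5 s
  expect_equal(nrow(tr), 2 * (5 - 1) / gains$dt)
})

test_that("offset correction zeroes the baseline and is idempotent", {
  dev <- default_device()
  cv <- run_cv_sweep(dev)
  wp <- select_working_point(cv, 30e-9)
  gains <- auto_pid_gains(cv, wp)
  tr <- run_concap(default_device(), wp, gains, ph_ladder_schedule(10))
  cor1 <- offset_correct(tr)
  base <- unique(cor1$segment)[1]
  expect_equal(settled_mean_of(cor1, base), 0, tolerance = 1e-15)
  cor2 <- offset_correct(cor1)
  expect_equal(cor1$voltage_v, cor2$voltage_v, tolerance = 1e-15)
  # pH 5 segment reads two Nernst steps below baseline: -118.3 mV
  ph5 <- unique(cor1$segment)[3]
  expect_equal(settled_mean_of(cor1, ph5) * 1e3, -118.3,
               tolerance = 1e-3)
  expect_error(offset_correct(tr, "nonexistent"), "not found")
})
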