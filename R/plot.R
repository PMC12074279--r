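# Base-graphics plot methods for the measurement products.

#' @export
plot.cv_curve <- function(x, ..., add = FALSE, col = "steelblue") {
  if (add) {
    graphics::lines(x$voltage_v, x$capacitance_f * 1e9, col = col, ...)
    graphics::points(x$voltage_v, x$capacitance_f * 1e9, col = col, pch = 16,
                     cex = 0.6)
  } else {
    plot(x$voltage_v, x$capacitance_f * 1e9, type = "o", pch = 16, cex = 0.6,
         col = col, xlab = "Gate voltage (V)", ylab = "Capacitance (nF)",
         main = "High-frequency C-V", ...)
  }
  invisible(x)
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$frequency_hz, x$zmag_ohm, log = "xy", type = "o", pch = 16,
       cex = 0.6, xlab = "Frequency (Hz)", ylab = "|Z| (ohm)",
       main = "Impedance spectrum", ...)
  plot(x$frequency_hz, x$phase_deg, log = "x", type = "o", pch = 16,
       cex = 0.6, xlab = "Frequency (Hz)", ylab = "Phase (deg)")
  invisible(x)
}

#' @export
plot.concap_trace <- function(x, ...) {
  plot(x$time_s, x$voltage_v * 1e3, type = "l", col = "steelblue",
       xlab = "Time (s)", ylab = "Gate voltage (mV)",
       main = "ConCap response", ...)
  bounds <- which(x$segment[-1] != x$segment[-nrow(x)])
  graphics::abline(v = x$time_s[bounds], col = "grey80", lty = 3)
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ...) {
  plot(x$x, x$y, pch = 16,
       xlab = if (x$x_kind == "ph") "pH" else "log10(concentration / mM)",
       ylab = "Settled potential (mV)",
       main = sprintf("Calibration: %.1f +/- %.1f %s", abs(x$slope),
                      x$slope_se, .unit_of(x$x_kind)), ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}
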