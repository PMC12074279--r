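# Sensitivity extraction: C-V shift measurement, linear calibration fits
# with slope standard errors, settled-mean ConCap calibration points, and
# multi-sensor aggregation.

#' Horizontal shift between two C-V curves
#'
#' Measures the voltage displacement of curve `cv_b` relative to `cv_a` at a
#' fixed reference capacitance on the depletion flank, using the same
#' accumulation-side bracketing/interpolation rule as
#' [select_working_point()]. Positive when `cv_b` lies at more positive
#' voltages (e.g. a pH increase on a p-type device).
#'
#' @param cv_a,cv_b [cv_curve()] objects sharing the reference capacitance in
#'   their measured spans.
#' @param c_ref Reference capacitance, F.
#' @return Shift in millivolts.
#' @export
extract_cv_shift <- function(cv_a, cv_b, c_ref) {
  stopifnot(inherits(cv_a, "cv_curve"), inherits(cv_b, "cv_curve"))
  va <- .v_at_c(cv_a$voltage_v, cv_a$capacitance_f, c_ref)
  vb <- .v_at_c(cv_b$voltage_v, cv_b$capacitance_f, c_ref)
  (vb - va) * 1e3
}

#' Fit a linear sensor calibration
#'
#' Ordinary least-squares line through calibration points: settled sensor
#' potential (mV) against pH, or against log10 of analyte concentration.
#' All points enter individually (revisited pH values in a ladder are not
#' averaged). The slope standard error comes from the residual variance of
#' the fit in the usual way.
#'
#' @param x Predictor: pH values, or log10 of concentrations in mM.
#' @param y Settled potentials, mV.
#' @param x_kind Either `"ph"` or `"log10_concentration"`; determines the
#'   sensitivity unit (mV/pH or mV/dec) used in reporting.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `slope_se` (all mV-based), `n`, `x_kind` and the underlying
#'   `lm` fit. `coef()`, `predict()`, `summary()`, `print()` and `plot()`
#'   methods are available; the reported sensitivity is `abs(slope)`.
#' @examples
#' fit_calibration(c(1, 2, 3), c(1, 2, 4))  # slope 1.5 +/- 0.289
#' @export
fit_calibration <- function(x, y, x_kind = c("ph", "log10_concentration")) {
  x_kind <- match.arg(x_kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 calibration points", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate calibration: all x values equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # a perfect fit is a legitimate outcome here (noiseless simulation);
  # summary.lm's zero-residual warning is not informative
  sm <- suppressWarnings(summary(fit)$coefficients)
  slope_se <- if (length(x) > 2) sm["x", "Std. Error"] else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = slope_se, n = length(x), x_kind = x_kind,
                 lm = fit, x = x, y = y),
            class = "calibration_fit")
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
residuals.calibration_fit <- function(object, ...) {
  object$y - predict(object)
}

.unit_of <- function(x_kind) if (x_kind == "ph") "mV/pH" else "mV/dec"

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s, n = %d): sensitivity %.1f +/- %.1f %s\n",
              x$x_kind, x$n, abs(x$slope), x$slope_se, .unit_of(x$x_kind)))
  cat(sprintf("  signed slope %.3f, intercept %.2f mV\n", x$slope, x$intercept))
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  cat(sprintf("Linear calibration, x = %s, n = %d points\n",
              object$x_kind, object$n))
  cat(sprintf("  slope      %10.3f mV per unit (SE %.3f)\n",
              object$slope, object$slope_se))
  cat(sprintf("  intercept  %10.3f mV\n", object$intercept))
  cat(sprintf("  sensitivity %9.1f %s (reported as magnitude)\n",
              abs(object$slope), .unit_of(object$x_kind)))
  invisible(object)
}

# round half away from zero (1.73 -> 2, 3.06 -> 3, -2.5 -> -3), the
# convention used when quoting integer-mV sensitivities
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate sensitivities over several sensors
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-sensor
#' sensitivity magnitudes; the print method quotes integer millivolts,
#' rounding half away from zero.
#'
#' @param values Sensitivities (mV per pH or mV per decade), length >= 2.
#' @param unit Unit string used for printing.
#' @return An object of class `sensitivity_summary`: list with `mean`, `sd`,
#'   `n`, `unit`, and integer-rounded `mean_mv`, `sd_mv`.
#' @examples
#' aggregate_sensitivities(c(104, 101, 101))  # 102 +/- 2 mV/dec
#' @export
aggregate_sensitivities <- function(values, unit = "mV/dec") {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need at least 2 sensors to aggregate", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  structure(list(mean = m, sd = s, n = length(values), unit = unit,
                 mean_mv = round_half_away(m), sd_mv = round_half_away(s)),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("Average sensitivity of %d sensors: %d +/- %d %s (mean %.2f, sd %.2f)\n",
              x$n, x$mean_mv, x$sd_mv, x$unit, x$mean, x$sd))
  invisible(x)
}

#' Calibration points from a ConCap trace
#'
#' Reduces each schedule segment to one calibration point: the settled mean
#' of the controller voltage (converted to mV) against the segment's pH or
#' log10 analyte concentration. For concentration calibrations the
#' zero-analyte baseline segments are excluded (their logarithm is
#' undefined). Segments whose final capacitance error exceeds the controller
#' tolerance are flagged and excluded with a warning.
#'
#' @param trace A [run_concap()] trace.
#' @param schedule The [solution_schedule()] the trace was recorded under
#'   (defaults to the schedule stored in the trace).
#' @param x_kind `"ph"` or `"log10_concentration"`.
#' @param settle_frac Fraction of each segment's final samples averaged.
#' @return A data frame with columns `label`, `x`, `potential_mv`.
#' @export
concap_calibration_points <- function(trace, schedule = attr(trace, "schedule"),
                                      x_kind = c("ph", "log10_concentration"),
                                      settle_frac = 0.5) {
  stopifnot(inherits(trace, "concap_trace"), inherits(schedule, "solution_schedule"))
  x_kind <- match.arg(x_kind)
  unsettled <- attr(trace, "warnings")
  rows <- lapply(seq_len(nrow(schedule)), function(s) {
    lab <- schedule$label[s]
    if (any(grepl(sprintf("segment '%s': not settled", lab), unsettled, fixed = TRUE))) {
      warning(sprintf("segment '%s' did not settle; excluded from calibration", lab),
              call. = FALSE)
      return(NULL)
    }
    if (x_kind == "log10_concentration") {
      if (schedule$penicillin_mm[s] <= 0) return(NULL)  # baseline buffer
      x <- log10(schedule$penicillin_mm[s])
    } else {
      x <- schedule$ph[s]
    }
    data.frame(label = lab, x = x,
               potential_mv = .settled_mean(trace, lab, settle_frac) * 1e3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no usable calibration segments in trace", call. = FALSE)
  rownames(out) <- NULL
  out
}
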