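# Independent hand evaluations of the closed-form physics, kept separate
# from the package implementation so they can serve as oracles.

EPS0 <- 8.8541878128e-12
QE <- 1.602176634e-19
KB <- 1.380649e-23

# Nernst slope from the gas and Faraday constants directly (V per pH)
oracle_nernst <- function(temp_k) 8.31446261815324 * temp_k * log(10) / 96485.33212

# series plate-capacitor evaluation of the two-layer stack (F)
oracle_cins <- function(d1_nm = 30, d2_nm = 60, area_mm2 = 52,
                        e1 = 3.9, e2 = 27) {
  a <- area_mm2 * 1e-6
  c1 <- EPS0 * e1 * a / (d1_nm * 1e-9)
  c2 <- EPS0 * e2 * a / (d2_nm * 1e-9)
  1 / (1 / c1 + 1 / c2)
}

# strong-inversion high-frequency plateau: series of the insulator
# capacitance and the space-charge capacitance at psi_s = 2 phi_F
oracle_hf_min <- function(na_cm3 = 2e16, temp_k = 298.15, area_mm2 = 52,
                          cins = oracle_cins()) {
  a <- area_mm2 * 1e-6
  na_m3 <- na_cm3 * 1e6
  phi_f <- (KB * temp_k / QE) * log(na_cm3 / 1e10)
  csc <- a * sqrt(QE * 11.7 * EPS0 * na_m3 / (2 * 2 * phi_f))
  1 / (1 / cins + 1 / csc)
}

# slope and slope standard error by explicit normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else 0
  list(slope = slope, intercept = intercept, se = se)
}

# default simulated device used across tests
default_device <- function(...) eiscap_device(...)

# integer rounding, half away from zero
round_half_away_test <- function(x) sign(x) * floor(abs(x) + 0.5)

# settled mean of a trace segment, recomputed independently of the package
settled_mean_of <- function(trace, label, frac = 0.5) {
  v <- trace$voltage_v[trace$segment == label]
  n <- length(v)
  mean(v[(n - ceiling(n * frac) + 1L):n])
}

# true working-point crossing voltage of the continuous device model
oracle_crossing <- function(device, c_wp, lower = -2, upper = 1.2) {
  stats::uniroot(function(v) hf_capacitance(device, v) - c_wp,
                 lower = lower, upper = upper, tol = 1e-12)$root
}
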