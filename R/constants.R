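# CODATA 2018 exact/recommended values (SI)
.eps0 <- 8.8541878128e-12   # vacuum permittivity, F/m
.q    <- 1.602176634e-19    # elementary charge, C
.kB   <- 1.380649e-23       # Boltzmann constant, J/K
.Rgas <- 8.31446261815324   # molar gas constant, J/(mol K)
.Fc   <- 96485.33212        # Faraday constant, C/mol

.eps_si <- 11.7             # relative permittivity of silicon
.ni_cm3 <- 1e10             # Si intrinsic carrier density at room temp, cm^-3

#' Nernst slope at a given temperature
#'
#' The ideal sensitivity limit of a pH-responsive surface,
#' \eqn{RT\,\ln 10 / F}: 59.16 mV per pH unit at 298.15 K.
#'
#' @param temperature_k Absolute temperature in kelvin.
#' @return Slope in volts per pH unit.
#' @examples
#' nernst_slope(298.15) * 1000  # 59.16 mV/pH
#' @export
nernst_slope <- function(temperature_k) {
  stopifnot(is.numeric(temperature_k), temperature_k > 0)
  .Rgas * temperature_k * log(10) / .Fc
}
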