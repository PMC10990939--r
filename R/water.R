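#' Thermophysical properties of liquid water
#'
#' Returns density, dynamic viscosity and the isobaric volume-expansion
#' coefficient of liquid water at atmospheric pressure, evaluated at a given
#' temperature. Density follows the Kell (1975) rational polynomial fit to the
#' 1-atm liquid range (0-150 degC, accurate to a few ppm below 100 degC); the
#' expansion coefficient is its exact analytic derivative, beta = -(1/rho)
#' drho/dT, so it vanishes at the density maximum near 4 degC. Viscosity uses
#' the Vogel-type correlation eta = 2.414e-5 * 10^(247.8 / (T_K - 140)) Pa s,
#' good to about 2.5 % over 0-100 degC.
#'
#' All downstream chamber physics evaluates these properties once at the film
#' (mean) temperature of the chamber cross-section.
#'
#' @param temperature temperature in degC; must lie in \[5, 95\].
#' @return an object of class `water_properties`: a list with fields
#'   `temperature` (degC), `density` (kg m^-3), `dynamic_viscosity` (Pa s),
#'   `volume_expansion` (K^-1) and `gravitational_acceleration` (9.81 m s^-2).
#' @examples
#' w <- water_properties(25)
#' w$density           # ~997.0 kg m^-3
#' w$dynamic_viscosity # ~8.9e-4 Pa s
#' @export
water_properties <- function(temperature) {
  assert_number(temperature, "temperature", 5, 95)
  t <- temperature
  # Kell (1975) density fit, kg m^-3
  a <- c(999.83952, 16.945176, -7.9870401e-3, -46.170461e-6,
         105.56302e-9, -280.54253e-12)
  bden <- 16.879850e-3
  num  <- a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3 + a[5] * t^4 + a[6] * t^5
  dnum <- a[2] + 2 * a[3] * t + 3 * a[4] * t^2 + 4 * a[5] * t^3 + 5 * a[6] * t^4
  den  <- 1 + bden * t
  rho  <- num / den
  drho <- (dnum * den - num * bden) / den^2
  beta <- -drho / rho
  eta  <- 2.414e-5 * 10^(247.8 / (t + 273.15 - 140))
  structure(
    list(temperature = t,
         density = rho,
         dynamic_viscosity = eta,
         volume_expansion = beta,
         gravitational_acceleration = 9.81),
    class = "water_properties")
}

#' @export
print.water_properties <- function(x, ...) {
  cat(sprintf("water at %.2f degC: rho = %.2f kg/m^3, eta = %.3e Pa s, beta = %.3e 1/K\n",
              x$temperature, x$density, x$dynamic_viscosity, x$volume_expansion))
  invisible(x)
}
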