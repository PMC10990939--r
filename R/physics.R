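#' Thermogravitational accumulation exponent q
#'
#' The dimensionless group controlling thermogravitational accumulation in a
#' differentially heated thin vertical gap,
#' \deqn{q = \Delta T \beta g \rho \alpha^3 / (6 \eta D),}
#' where \eqn{\alpha} is the gap thickness and \eqn{\beta, \rho, \eta} are the
#' volume expansion coefficient, density and viscosity of water at the film
#' temperature. Accumulation (at fixed `S_T * delta_T`) is strongest near
#' `q = sqrt(10080) ~ 100.4`.
#'
#' @param geometry a [chamber_geometry()].
#' @param thermal a [thermal_conditions()].
#' @param D solute diffusion coefficient (m^2 s^-1).
#' @return dimensionless q (>= 0).
#' @export
soret_exponent_q <- function(geometry, thermal, D) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(thermal, "thermal_conditions"))
  assert_number(D, "D", 0, Inf, strict = TRUE)
  w <- water_properties(thermal$T_film)
  thermal$delta_T * w$volume_expansion * w$gravitational_acceleration *
    w$density * geometry$thickness^3 / (6 * w$dynamic_viscosity * D)
}

# decay rate (1/m) of the closed-form steady vertical profile, positive for
# bottom accumulation (S_T > 0)
steady_profile_rate <- function(solute, geometry, thermal) {
  q <- soret_exponent_q(geometry, thermal, solute$D)
  (q / 120) / (1 + q^2 / 10080) * solute$S_T * thermal$delta_T /
    geometry$thickness
}

#' Closed-form steady vertical concentration profile
#'
#' The classical series solution for a closed thermogravitational column
#' predicts an exponential steady-state profile
#' \deqn{c(y) \propto \exp\left(-\frac{q/120}{1 + q^2/10080}\, S_T \Delta T\,
#'   \frac{y}{\alpha}\right)}
#' with `y` measured upward from the chamber bottom. The returned profile is
#' renormalized so its mean over the chamber height is 1, matching the
#' normalization used for measured fraction tables. For `S_T > 0` and
#' `delta_T > 0` the bottom is enriched.
#'
#' This closed form is the analytic oracle against which the numerical
#' chamber solver is validated; it assumes a closed chamber (no throughflow).
#'
#' @param solute a [solute()].
#' @param geometry a [chamber_geometry()].
#' @param thermal a [thermal_conditions()].
#' @param y positions in m from the chamber bottom (0 to `geometry$height`).
#' @return numeric vector of dimensionless concentrations (chamber mean 1).
#' @export
steady_profile <- function(solute, geometry, thermal, y) {
  stopifnot(inherits(solute, "solute"))
  if (any(y < -1e-12 | y > geometry$height + 1e-12)) {
    stop("y positions outside chamber height")
  }
  lam <- steady_profile_rate(solute, geometry, thermal)
  H <- geometry$height
  if (abs(lam * H) < 1e-12) return(rep(1, length(y)))
  # mean of exp(-lam y) over [0, H] = (1 - exp(-lam H)) / (lam H)
  m <- (1 - exp(-lam * H)) / (lam * H)
  exp(-lam * y) / m
}

# analytic fraction means of the steady profile (top-first), chamber mean 1
steady_fraction_means <- function(solute, geometry, thermal) {
  lam <- steady_profile_rate(solute, geometry, thermal)
  H <- geometry$height
  nfr <- geometry$n_fractions
  h <- H / nfr
  if (abs(lam * H) < 1e-12) return(rep(1, nfr))
  j <- seq_len(nfr)            # 1 = top
  ya <- (nfr - j) * h          # slab bottoms
  nfr * (exp(-lam * ya) - exp(-lam * (ya + h))) / (1 - exp(-lam * H))
}
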