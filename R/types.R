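#' Heat-flow chamber geometry
#'
#' Describes the thin vertical slab in which thermogravitational accumulation
#' takes place: a tall, narrow, very thin water-filled gap between a hot and a
#' cold wall. The thin-gap flow model used throughout the package requires a
#' large height-to-thickness aspect ratio.
#'
#' Coordinates: `y = 0` at the chamber bottom, increasing upward. Fractions are
#' numbered top-first, so fraction 1 is the top slab and fraction
#' `n_fractions` the bottom slab.
#'
#' @param height chamber height in m (0.05 for the single measurement chamber,
#'   0.2 for a network chamber).
#' @param width chamber width in m; enters only through the conversion between
#'   volumetric flow rates and 2-D fluxes.
#' @param thickness gap between hot and cold wall (m).
#' @param n_fractions number of equal-height analysis slabs (4 matches the
#'   frozen-and-cut readout).
#' @param bottom_probe_height height of the bottom sampling region (m); the
#'   bottommost 1.5 mm is where network chambers report their "bottom"
#'   concentration.
#' @return an object of class `chamber_geometry`.
#' @seealso [single_chamber_geometry()], [network_chamber_geometry()]
#' @export
chamber_geometry <- function(height = 0.05, width = 0.06, thickness = 1.7e-4,
                             n_fractions = 4L, bottom_probe_height = 1.5e-3) {
  assert_number(height, "height", 0, Inf, strict = TRUE)
  assert_number(width, "width", 0, Inf, strict = TRUE)
  assert_number(thickness, "thickness", 0, Inf, strict = TRUE)
  assert_number(bottom_probe_height, "bottom_probe_height", 0, height)
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  aspect <- height / thickness
  if (aspect <= 50) {
    stop(sprintf(
      "aspect ratio height/thickness = %.1f <= 50: thin-gap flow model invalid",
      aspect))
  }
  structure(
    list(height = height, width = width, thickness = thickness,
         n_fractions = as.integer(n_fractions),
         bottom_probe_height = bottom_probe_height),
    class = "chamber_geometry")
}

#' @rdname chamber_geometry
#' @export
single_chamber_geometry <- function() chamber_geometry(height = 0.05)

#' @rdname chamber_geometry
#' @export
network_chamber_geometry <- function() chamber_geometry(height = 0.2)

#' Thermal boundary conditions of a chamber
#'
#' The two walls of the gap are held at fixed temperatures; the temperature
#' profile across the thin gap is linear, and all water properties are
#' evaluated at the film (mean) temperature.
#'
#' @param T_cold cold-wall temperature (degC).
#' @param T_hot hot-wall temperature (degC); must be >= `T_cold`.
#' @return an object of class `thermal_conditions` with fields `T_cold`,
#'   `T_hot`, `delta_T` (K) and `T_film` (degC).
#' @export
thermal_conditions <- function(T_cold, T_hot) {
  assert_number(T_cold, "T_cold")
  assert_number(T_hot, "T_hot")
  if (T_hot < T_cold) stop("T_hot must be >= T_cold")
  structure(
    list(T_cold = T_cold, T_hot = T_hot,
         delta_T = T_hot - T_cold, T_film = (T_hot + T_cold) / 2),
    class = "thermal_conditions")
}

#' Thermal conditions from a temperature difference and film temperature
#'
#' Convenience constructor placing the walls symmetrically around the film
#' temperature: `T_cold = T_film - delta_T/2`, `T_hot = T_film + delta_T/2`.
#' Useful when sweeping `delta_T` at a fixed film temperature, e.g. for
#' transfer-table axes.
#'
#' @param delta_T temperature difference (K), >= 0.
#' @param T_film film (mean) temperature (degC).
#' @return a [thermal_conditions()] object.
#' @export
thermal_from_film <- function(delta_T, T_film) {
  thermal_conditions(T_film - delta_T / 2, T_film + delta_T / 2)
}

#' A dissolved species and its transport coefficients
#'
#' @param name species label.
#' @param D diffusion coefficient (m^2 s^-1), > 0.
#' @param S_T Soret coefficient (K^-1); positive values drift toward the cold
#'   wall. The thermophoretic drift velocity is `v_T = -grad(T) * S_T * D`.
#' @param sigma_random random error of `S_T` (K^-1), >= 0; used for Gaussian
#'   resampling in ensemble error propagation.
#' @param sigma_systematic systematic (multiplicative) error of `S_T`, as a
#'   fraction, >= 0.
#' @return an object of class `solute`.
#' @export
solute <- function(name, D, S_T, sigma_random = 0, sigma_systematic = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_number(D, "D", 0, Inf, strict = TRUE)
  assert_number(S_T, "S_T")
  assert_number(sigma_random, "sigma_random", 0, Inf)
  assert_number(sigma_systematic, "sigma_systematic", 0, Inf)
  structure(
    list(name = name, D = D, S_T = S_T,
         sigma_random = sigma_random, sigma_systematic = sigma_systematic),
    class = "solute")
}

# coerce a data frame row / list to a solute
as_solute <- function(x) {
  if (inherits(x, "solute")) return(x)
  solute(as.character(x$name), x$D, x$S_T,
         x$sigma_random %||% 0, x$sigma_systematic %||% 0)
}

#' Numerical settings for the chamber solver
#'
#' @param nx number of finite-volume cells across the gap (>= 8).
#' @param ny number of cells along the chamber height (>= 40).
#' @param n_steps number of implicit time steps for a transient solve.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(nx = 40L, ny = 200L, n_steps = 120L) {
  if (nx < 8 || ny < 40) stop("grid too coarse: need nx >= 8, ny >= 40")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 n_steps = as.integer(n_steps)),
            class = "solver_settings")
}
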