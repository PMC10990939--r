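#' Laminar flow field in a thin differentially heated chamber
#'
#' Builds the steady, divergence-free velocity field used by the transport
#' solver. Because the chamber is hundreds of times taller than it is thick,
#' the solver replaces a full Navier-Stokes solve with the analytic thin-gap
#' (lubrication / Boussinesq) limit:
#'
#' * a cubic, antisymmetric thermal-convection profile across the gap,
#'   `u_y(s) = K (s/4 - s^3)` with `s = x/alpha - 1/2` and
#'   `K = rho g beta delta_T alpha^2 / (6 eta)`, which rises at the hot wall
#'   and sinks at the cold wall and carries zero net vertical flux; and
#' * a parabolic (Poiseuille) throughflow profile carrying the part of the
#'   inflow that leaves through the bottom outlet.
#'
#' The inflow enters through the top boundary, one outflow leaves through the
#' top boundary and one through the bottom boundary; each open segment spans
#' the gap, and in-plane fluxes in the top and bottom cell rows are
#' reconstructed from continuity so the discrete field is exactly
#' divergence-free (the convection roll closes within the end rows, mimicking
#' the physical turning regions whose height is comparable to the gap).
#'
#' @param geometry a [chamber_geometry()]; must satisfy the thin-gap aspect
#'   requirement (enforced by the constructor).
#' @param thermal a [thermal_conditions()].
#' @param Q_in volumetric inflow rate (m^3 s^-1), >= 0.
#' @param bottom_outflow_fraction fraction of `Q_in` leaving through the
#'   bottom outlet, in \[0, 1\].
#' @param settings a [solver_settings()].
#' @return an object of class `flow_field` holding the grid, the per-column
#'   vertical face fluxes, the reconstructed horizontal face fluxes and the
#'   boundary fluxes.
#' @export
convective_flow_field <- function(geometry, thermal, Q_in = 0,
                                  bottom_outflow_fraction = 0,
                                  settings = solver_settings()) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(thermal, "thermal_conditions"),
            inherits(settings, "solver_settings"))
  assert_number(Q_in, "Q_in", 0, Inf)
  assert_number(bottom_outflow_fraction, "bottom_outflow_fraction", 0, 1)

  nx <- settings$nx; ny <- settings$ny
  alpha <- geometry$thickness; H <- geometry$height; W <- geometry$width
  dx <- alpha / nx; dy <- H / ny
  xc <- (seq_len(nx) - 0.5) * dx
  s  <- xc / alpha - 0.5                      # hot wall at x = alpha

  w  <- water_properties(thermal$T_film)
  K  <- w$density * w$gravitational_acceleration * w$volume_expansion *
        thermal$delta_T * alpha^2 / (6 * w$dynamic_viscosity)
  u_conv <- K * (s / 4 - s^3)                 # zero discrete net flux (odd in s)

  # 2-D fluxes per unit width
  qin2  <- Q_in / W
  qbot2 <- qin2 * bottom_outflow_fraction
  qtop2 <- qin2 - qbot2
  # downward parabola, normalized so its *discrete* integral is exactly qbot2
  wgt <- (xc / alpha) * (1 - xc / alpha)
  u_thr <- if (qbot2 > 0) -qbot2 * wgt / (sum(wgt) * dx) else rep(0, nx)

  Vface <- (u_conv + u_thr) * dx              # vertical flux per column (m^2/s)

  # net boundary influx per cell: inlet and top outlet distributed uniformly
  # over the top boundary, bottom outlet over the bottom boundary
  src <- matrix(0, nx, ny)
  src[, ny] <- (qin2 - qtop2) / nx
  src[, 1]  <- src[, 1] - qbot2 / nx

  # horizontal face fluxes from row-wise continuity; interior rows are zero
  # because the vertical profile is y-independent
  Uface <- matrix(0, nx + 1, ny)
  for (jy in seq_len(ny)) {
    Vb <- if (jy == 1) rep(0, nx) else Vface
    Va <- if (jy == ny) rep(0, nx) else Vface
    Uface[-1, jy] <- cumsum(Vb - Va + src[, jy])
  }
  resid <- max(abs(Uface[nx + 1, ]))
  if (resid > 1e-12 * max(abs(Vface), qin2, 1e-300)) {
    stop("internal error: flow field not divergence-free")
  }
  Uface[nx + 1, ] <- 0

  structure(
    list(geometry = geometry, thermal = thermal,
         Q_in = Q_in, bottom_outflow_fraction = bottom_outflow_fraction,
         Q_out_top = Q_in * (1 - bottom_outflow_fraction),
         Q_out_bot = Q_in * bottom_outflow_fraction,
         nx = nx, ny = ny, dx = dx, dy = dy, xc = xc,
         yc = (seq_len(ny) - 0.5) * dy,
         u_conv = u_conv, u_throughflow = u_thr,
         Vface = Vface, Uface = Uface,
         qin2 = qin2, qtop2 = qtop2, qbot2 = qbot2,
         settings = settings),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "thin-gap flow field: %d x %d cells, delta_T = %g K, Q_in = %g nl/s, f_bot = %g\n",
    x$nx, x$ny, x$thermal$delta_T, x$Q_in * 1e12, x$bottom_outflow_fraction))
  cat(sprintf("  max convective speed %.3g m/s\n", max(abs(x$u_conv))))
  invisible(x)
}
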