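# Finite-volume drift-diffusion operator and solvers.
#
# Discretization: uniform rectangular cells, flux form. Vertical advection
# (the axial direction of the accumulation profile) is discretized with
# central face averages: upwinding there would add an artificial axial
# dispersion u*dy/2 comparable to the molecular term that sets the "1" in the
# 1 + q^2/10080 denominator of the closed-form profile, and would flatten the
# exponential. Horizontal advection (thermophoretic drift plus the
# continuity-closure flow confined to the end rows) is upwinded; its cell
# Peclet number is tiny for the drift and the end rows are turning regions
# where a first-order scheme is harmless. Diffusion is central. The operator
# is linear and mass conservation is exact by flux antisymmetry.

# assemble sparse operator A and inflow vector b such that
#   vol * dc/dt = A c + b * c_in
assemble_operator <- function(flow, solute) {
  nx <- flow$nx; ny <- flow$ny; ns <- nx * ny
  dx <- flow$dx; dy <- flow$dy
  D <- solute$D
  vdrift <- -solute$S_T * D * flow$thermal$delta_T / flow$geometry$thickness

  # vertical interior faces: cells (ix, jy) and (ix, jy+1)
  Lv <- rep(seq_len(nx), ny - 1) + rep((0:(ny - 2)) * nx, each = nx)
  Uv <- Lv + nx
  Fv <- rep(flow$Vface, ny - 1)                  # flux > 0 upward
  aL <- Fv / 2; aU <- Fv / 2                     # central
  Ddv <- D * dx / dy
  iv <- c(Lv, Lv, Uv, Uv)
  jv <- c(Lv, Uv, Lv, Uv)
  xv <- c(-(aL + Ddv), -(aU - Ddv), (aL + Ddv), (aU - Ddv))

  # horizontal interior faces: cells (ix, jy) and (ix+1, jy)
  Lh <- rep(seq_len(nx - 1), ny) + rep((0:(ny - 1)) * nx, each = nx - 1)
  Rh <- Lh + 1
  Fh <- as.vector(flow$Uface[2:nx, , drop = FALSE]) + vdrift * dy
  aLh <- pmax(Fh, 0); aRh <- pmin(Fh, 0)         # upwind
  Ddh <- D * dy / dx
  ih <- c(Lh, Lh, Rh, Rh)
  jh <- c(Lh, Rh, Lh, Rh)
  xh <- c(-(aLh + Ddh), -(aRh - Ddh), (aLh + Ddh), (aRh - Ddh))

  b <- numeric(ns)
  ib <- integer(0); xb <- numeric(0)
  if (flow$Q_in > 0) {
    topcells <- (ny - 1) * nx + seq_len(nx)
    botcells <- seq_len(nx)
    b[topcells] <- flow$qin2 / nx                # inflow carries c_in
    ib <- c(topcells, botcells)
    xb <- c(rep(-flow$qtop2 / nx, nx), rep(-flow$qbot2 / nx, nx))
  }

  A <- Matrix::sparseMatrix(i = c(iv, ih, ib), j = c(jv, jh, ib),
                            x = c(xv, xh, xb), dims = c(ns, ns))
  list(A = A, b = b, vol = dx * dy, ns = ns)
}

new_concentration_field <- function(values, flow, solute, time) {
  structure(
    list(values = values, nx = flow$nx, ny = flow$ny,
         xc = flow$xc, yc = flow$yc, dx = flow$dx, dy = flow$dy,
         flow = flow, solute = solute, time = time),
    class = "concentration_field")
}

#' Solve the drift-diffusion transport of a solute in a chamber
#'
#' Solves
#' \deqn{\partial c/\partial t = \nabla\cdot[D \nabla c - (u - S_T D \nabla T)\, c]}
#' on the 2-D (height x gap) slab, with no-flux walls, fixed inlet
#' concentration and advective outflow at the open boundary segments of
#' `flow`. In `"steady"` mode the stationary linear system is solved directly
#' (for a closed chamber the one-dimensional null space is fixed by the
#' chamber-mean constraint); in `"transient"` mode implicit-Euler steps are
#' taken with a single factorization of the step operator, which is
#' unconditionally stable.
#'
#' @param flow a [convective_flow_field()].
#' @param solute a [solute()].
#' @param mode `"steady"` or `"transient"`.
#' @param duration transient duration in s (required for `"transient"`).
#' @param n_steps number of implicit time steps; defaults to the value in the
#'   flow field's solver settings.
#' @param c_init initial condition (uniform scalar or `nx * ny` matrix);
#'   default 1.
#' @param c_in inlet concentration (dimensionless), default 1.
#' @return an object of class `concentration_field` with an `nx x ny` matrix
#'   `values` (first index across the gap, second upward along the height).
#' @export
solve_drift_diffusion <- function(flow, solute, mode = c("steady", "transient"),
                                  duration = NULL, n_steps = NULL,
                                  c_init = 1, c_in = 1) {
  stopifnot(inherits(flow, "flow_field"), inherits(solute, "solute"))
  mode <- match.arg(mode)
  op <- assemble_operator(flow, solute)
  ns <- op$ns

  if (mode == "steady") {
    if (flow$Q_in > 0) {
      vals <- as.numeric(Matrix::solve(op$A, -op$b * c_in))
    } else {
      # closed chamber: A is singular with the steady profile as null space;
      # columns of A sum to zero, so one balance row is redundant and can be
      # replaced by the mean-concentration constraint
      A2 <- rbind(op$A[seq_len(ns - 1), , drop = FALSE],
                  Matrix::Matrix(1 / ns, 1, ns))
      vals <- as.numeric(Matrix::solve(A2, c(rep(0, ns - 1), mean(c_init))))
    }
    return(new_concentration_field(matrix(vals, flow$nx, flow$ny), flow,
                                   solute, Inf))
  }

  assert_number(duration, "duration", 0, Inf, strict = TRUE)
  n_steps <- as.integer(n_steps %||% flow$settings$n_steps)
  dt <- duration / n_steps
  c0 <- if (length(c_init) == 1L) rep(c_init, ns) else as.numeric(c_init)
  M <- op$vol / dt
  S <- Matrix::Diagonal(ns, M) - op$A
  f <- Matrix::lu(S)
  cc <- c0
  bb <- op$b * c_in
  for (k in seq_len(n_steps)) {
    cc <- as.numeric(Matrix::solve(f, M * cc + bb))
  }
  new_concentration_field(matrix(cc, flow$nx, flow$ny), flow, solute, duration)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("concentration field %d x %d, time = %s, mean = %.6g\n",
              x$nx, x$ny, if (is.infinite(x$time)) "steady" else
                sprintf("%.3g s", x$time), mean(x$values)))
  invisible(x)
}

# laterally averaged vertical profile (bottom to top)
vertical_profile <- function(field) colMeans(field$values)

#' Average a concentration field over equal-height fractions
#'
#' Splits the chamber into `n_fractions` equal-height slabs (mimicking the
#' freeze-and-cut readout) and returns the volume-weighted mean concentration
#' of each, in top-first order (fraction 1 = top, matching the labelling of
#' measured fraction tables). Partial cells at slab boundaries are weighted by
#' their overlap, so the mean of the fraction means always equals the chamber
#' mean.
#'
#' @param field a `concentration_field`.
#' @param n_fractions number of slabs.
#' @return numeric vector of length `n_fractions`, top first.
#' @export
fraction_averages <- function(field, n_fractions = 4L) {
  stopifnot(inherits(field, "concentration_field"), n_fractions >= 1)
  prof <- vertical_profile(field)            # bottom to top, cell means
  ny <- field$ny
  H <- ny * field$dy
  h <- H / n_fractions
  ylo <- (seq_len(ny) - 1) * field$dy
  yhi <- ylo + field$dy
  out <- numeric(n_fractions)
  for (j in seq_len(n_fractions)) {          # j = 1 top
    a <- H - j * h; b <- a + h
    wgt <- pmax(0, pmin(yhi, b) - pmax(ylo, a))
    out[j] <- sum(prof * wgt) / sum(wgt)
  }
  out
}

# volume-weighted mean over the lowest `probe_height` of the chamber
bottom_region_mean <- function(field, probe_height) {
  ylo <- (seq_len(field$ny) - 1) * field$dy
  yhi <- ylo + field$dy
  wgt <- pmax(0, pmin(yhi, probe_height) - ylo)
  prof <- vertical_profile(field)
  sum(prof * wgt) / sum(wgt)
}

#' Summarize a chamber solution as a transfer response
#'
#' Collapses a concentration field into the quantities the network model
#' consumes: fraction means, the bottom-region mean (lowest
#' `bottom_probe_height`), and the concentrations leaving through the top and
#' bottom outlets (the outflow segments withdraw fluid from the top and
#' bottom cell rows, so the outlet concentrations are the means of those
#' rows). All values are relative to a unit inlet/initial concentration.
#'
#' @param field a `concentration_field`.
#' @return an object of class `chamber_response` with fields `profile`
#'   (laterally averaged, bottom to top), `fraction_means` (top first),
#'   `bottom_mean`, `c_out_top`, `c_out_bot` and `chamber_mean`.
#' @export
chamber_response <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  geom <- field$flow$geometry
  structure(
    list(profile = vertical_profile(field),
         yc = field$yc,
         fraction_means = fraction_averages(field, geom$n_fractions),
         bottom_mean = bottom_region_mean(field, geom$bottom_probe_height),
         c_out_top = mean(field$values[, field$ny]),
         c_out_bot = mean(field$values[, 1]),
         chamber_mean = mean(field$values)),
    class = "chamber_response")
}

# convenience wrapper: steady (or transient) response for a parameter set
compute_response <- function(geometry, thermal, solute_obj, Q_in, f_bot,
                             settings, mode = "steady", duration = NULL) {
  flow <- convective_flow_field(geometry, thermal, Q_in, f_bot, settings)
  fld <- solve_drift_diffusion(flow, solute_obj, mode = mode,
                               duration = duration)
  chamber_response(fld)
}
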