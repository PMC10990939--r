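# Kinetic model of trimetaphosphate (TMP)-driven glycine dimerization:
#   Gly + TMP -k1-> GlyAct        (activation / phosphorylation)
#   GlyAct    -k2-> Gly           (hydrolysis of the activated species)
#   GlyAct + Gly -k3-> GlyGly     (dimerization)
#   TMP       -k4-> waste         (TMP hydrolysis)
#   GlyGly    -k5-> 2 Gly         (dimer hydrolysis)
# k1, k3 are bimolecular (M^-1 s^-1); k2, k4, k5 first order (s^-1). The
# glycine-unit total [Gly] + [GlyAct] + 2 [GlyGly] is exactly conserved.

#' Rate constants of the glycine-dimerization scheme
#'
#' @param k1 activation rate (M^-1 s^-1).
#' @param k2 activated-glycine hydrolysis rate (s^-1).
#' @param k3 dimerization rate (M^-1 s^-1).
#' @param k4 TMP hydrolysis rate (s^-1).
#' @param k5 dimer hydrolysis rate (s^-1).
#' @param rel_error optional named numeric of relative (1-sigma) errors.
#' @return an object of class `rate_constants`.
#' @export
rate_constants <- function(k1, k2, k3, k4, k5, rel_error = NULL) {
  for (nm in c("k1", "k2", "k3", "k4", "k5")) {
    assert_number(get(nm), nm, 0, Inf)
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 rel_error = rel_error),
            class = "rate_constants")
}

#' Reference rate constants at 90 degC, initial pH 10.5
#'
#' The rate set used by the network-yield model: fitted to bulk
#' TMP-titration and time-series dimerization measurements at 90 degC and
#' initial pH 10.5. Bimolecular constants are in M^-1 s^-1.
#'
#' @return a [rate_constants()] object.
#' @export
reference_rate_constants <- function() {
  rate_constants(k1 = 1.0e-3, k2 = 1.1e-4, k3 = 9.7e-5,
                 k4 = 3.5e-7, k5 = 1.2e-6,
                 rel_error = c(k1 = 0.41, k2 = 0.10, k3 = 0.21,
                               k4 = 0.19, k5 = 0.20))
}

#' Reaction state vector
#'
#' @param Gly,GlyAct,GlyGly,TMP concentrations in M, >= 0.
#' @return named numeric vector of class `reaction_state`.
#' @export
reaction_state <- function(Gly = 0, GlyAct = 0, GlyGly = 0, TMP = 0) {
  v <- c(Gly = Gly, GlyAct = GlyAct, GlyGly = GlyGly, TMP = TMP)
  if (any(v < 0)) stop("concentrations must be >= 0")
  structure(v, class = "reaction_state")
}

#' Right-hand side of the dimerization ODE system
#'
#' @param state a [reaction_state()] or named numeric vector (M).
#' @param rates a [rate_constants()].
#' @return named numeric vector of time derivatives (M s^-1). The glycine
#'   unit total `Gly + GlyAct + 2 GlyGly` has exactly zero derivative.
#' @export
reaction_rhs <- function(state, rates) {
  G <- state[["Gly"]]; GA <- state[["GlyAct"]]
  GG <- state[["GlyGly"]]; TMP <- state[["TMP"]]
  with(rates, c(
    Gly    = -k1 * TMP * G - k3 * GA * G + k2 * GA + k5 * 2 * GG,
    GlyAct =  k1 * G * TMP - k2 * GA - k3 * GA * G,
    GlyGly =  k3 * GA * G - k5 * GG,
    TMP    = -k1 * G * TMP - k4 * TMP))
}

#' Integrate the dimerization kinetics in a closed batch
#'
#' Stiff-capable integration (`deSolve::lsoda`) of the five-reaction scheme
#' from an initial state over `duration`, reporting `n_out` evenly spaced
#' output times (plus t = 0).
#'
#' @param initial a [reaction_state()].
#' @param rates a [rate_constants()].
#' @param duration total time (s), > 0.
#' @param n_out number of output times.
#' @param times optional explicit output times (s), overriding `n_out`.
#' @param rtol,atol integration tolerances.
#' @return data.frame with columns `time`, `Gly`, `GlyAct`, `GlyGly`, `TMP`.
#' @export
integrate_batch <- function(initial, rates, duration = 120 * 3600,
                            n_out = 50L, times = NULL,
                            rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(rates, "rate_constants"))
  if (is.null(times)) {
    assert_number(duration, "duration", 0, Inf, strict = TRUE)
    times <- seq(0, duration, length.out = n_out + 1L)
  } else {
    times <- sort(unique(c(0, times)))
  }
  y0 <- unclass(reaction_state(initial[["Gly"]], initial[["GlyAct"]],
                               initial[["GlyGly"]], initial[["TMP"]]))
  fn <- function(t, y, p) list(reaction_rhs(y, rates))
  out <- deSolve::lsoda(y0, times, fn, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")")
  }
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df
}

#' Dimer yield metric
#'
#' Fraction of glycine units bound in dimers: `2 c_GlyGly / (2 c_GlyGly +
#' c_Gly)`. Invariant under joint rescaling of both concentrations.
#'
#' @param glygly,gly concentrations (any common unit); vectors allowed.
#' @return yield in \[0, 1\].
#' @export
reaction_yield <- function(glygly, gly) {
  if (any(glygly < 0 | gly < 0)) stop("concentrations must be >= 0")
  den <- 2 * glygly + gly
  if (any(den == 0)) stop("yield undefined: both concentrations zero")
  2 * glygly / den
}

#' Fit the TMP hydrolysis rate from a decay time series
#'
#' Least-squares fit of a single exponential `TMP(t) = A exp(-k4 t)` to a
#' TMP-only hydrolysis series (no glycine present). Initialized from the
#' log-linear regression; a non-decaying series returns `k4 = 0` with a
#' boundary flag.
#'
#' @param times time points (s), >= 3 values.
#' @param tmp measured TMP concentrations (M), > 0.
#' @return list with `k4` (s^-1), `A` and `at_boundary`.
#' @export
fit_k4 <- function(times, tmp) {
  stopifnot(length(times) >= 3, length(tmp) == length(times))
  if (any(tmp <= 0)) stop("TMP concentrations must be > 0")
  lf <- stats::lm(log(tmp) ~ times)
  k0 <- -unname(stats::coef(lf)[2])
  if (k0 <= 0) {
    return(list(k4 = 0, A = exp(mean(log(tmp))), at_boundary = TRUE))
  }
  st <- list(A = exp(unname(stats::coef(lf)[1])), k = k0)
  # on (near-)noiseless data the log-linear fit is already exact and nls
  # cannot improve a zero-residual problem
  if (stats::sd(stats::residuals(lf)) < 1e-10) {
    return(list(k4 = k0, A = st$A, at_boundary = FALSE))
  }
  fit <- tryCatch(
    stats::nls(tmp ~ A * exp(-k * times), start = st,
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(k4 = k0, A = st$A, at_boundary = FALSE))
  co <- stats::coef(fit)
  list(k4 = unname(co["k"]), A = unname(co["A"]), at_boundary = FALSE)
}

# predict GlyGly at requested times for one initial-condition group
predict_glygly <- function(gly0, tmp0, times, rates, rtol = 1e-9,
                           atol = 1e-15) {
  ts <- sort(unique(times))
  out <- integrate_batch(reaction_state(Gly = gly0, TMP = tmp0), rates,
                         times = ts, rtol = rtol, atol = atol)
  out$GlyGly[match(times, out$time)]
}

#' Simultaneously fit the free rate constants to dimerization data
#'
#' Fits `(k1, k2, k3, k5)` in log-space by Levenberg-Marquardt least squares
#' (with `k4` held fixed from its separate TMP-decay determination) to all
#' supplied product-concentration measurements at once: typically a TMP
#' titration (product at a fixed time over a ladder of initial TMP
#' concentrations at two initial glycine levels) plus a time series.
#' Residuals are formed on `log10(c + 1e-12)` so that measurements spanning
#' several decades contribute comparably. Multi-start: `n_starts` seeded
#' log-space perturbations around a nominal start; the best converged fit is
#' returned. Relative (1-sigma) uncertainties come from the residual
#' covariance of the log-parameters.
#'
#' @param data data.frame with columns `gly_init_M`, `tmp_init_M`, `time_s`,
#'   `glygly_M`.
#' @param k4 fixed TMP hydrolysis rate (s^-1).
#' @param start named numeric starting guess for `c(k1, k2, k3, k5)`.
#' @param n_starts number of seeded multi-starts.
#' @param seed seed for start placement.
#' @return a [rate_constants()] with `rel_error` estimates and attributes
#'   `deviance` and `condition_number`. A warning is issued if the Jacobian
#'   is ill-conditioned (flat directions: unidentifiable fit).
#' @export
fit_rates <- function(data, k4, start = c(k1 = 1e-3, k2 = 1e-4,
                                          k3 = 1e-4, k5 = 1e-6),
                      n_starts = 5L, seed = 1L) {
  req <- c("gly_init_M", "tmp_init_M", "time_s", "glygly_M")
  if (!all(req %in% names(data))) {
    stop("data needs columns: ", paste(req, collapse = ", "))
  }
  assert_number(k4, "k4", 0, Inf)
  grp <- split(data, interaction(data$gly_init_M, data$tmp_init_M, drop = TRUE))
  obs <- log10(data$glygly_M + 1e-12)
  residfun <- function(lp) {
    k <- exp(lp)
    rts <- rate_constants(k[["k1"]], k[["k2"]], k[["k3"]], k4, k[["k5"]])
    pred <- numeric(nrow(data))
    for (g in grp) {
      p <- tryCatch(
        predict_glygly(g$gly_init_M[1], g$tmp_init_M[1], g$time_s, rts),
        error = function(e) rep(NA_real_, nrow(g)))
      pred[as.integer(rownames(g))] <- p
    }
    if (anyNA(pred)) return(rep(1e3, nrow(data)))
    log10(pred + 1e-12) - obs
  }
  rownames(data) <- NULL
  grp <- split(data, interaction(data$gly_init_M, data$tmp_init_M, drop = TRUE))

  starts <- with_seed(derive_seed(seed, 707L), {
    jit <- matrix(stats::runif(4L * n_starts, -1, 1), n_starts, 4L)
    jit[1, ] <- 0                                # first start unperturbed
    sweep(jit * log(10), 2, log(start), "+")     # +/- one decade
  })
  lob <- rep(log(1e-12), 4L); upb <- rep(log(1e2), 4L)
  best <- NULL
  for (i in seq_len(n_starts)) {
    lp <- stats::setNames(starts[i, ], names(start))
    fit <- tryCatch(
      minpack.lm::nls.lm(lp, fn = residfun, lower = lob, upper = upb,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all rate-fit starts failed")
  at_bound <- any(abs(unlist(best$par) - lob) < 1e-6 |
                    abs(unlist(best$par) - upb) < 1e-6)
  if (at_bound) {
    warning("rate fit hit a parameter bound: degenerate data (flagged)")
  }
  k <- exp(best$par)
  J <- best$hessian
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.eps)
  if (cond > 1e10) {
    warning(sprintf(
      "rate fit ill-conditioned (condition number %.2g): flat directions",
      cond))
  }
  dof <- max(1L, nrow(data) - 4L)
  s2 <- best$deviance / dof
  cov <- tryCatch(s2 * solve(J), error = function(e) matrix(NA, 4, 4))
  sdlog <- sqrt(pmax(diag(cov), 0))
  rel <- stats::setNames(sdlog, names(start))  # sd of log(k) ~ relative error
  out <- rate_constants(k[["k1"]], k[["k2"]], k[["k3"]], k4, k[["k5"]],
                        rel_error = rel)
  attr(out, "deviance") <- best$deviance
  attr(out, "condition_number") <- cond
  attr(out, "at_boundary") <- at_bound
  out
}

#' Precompute a reaction-outcome lookup grid
#'
#' Integrates the dimerization scheme over a log-spaced grid of initial
#' glycine and TMP concentrations and stores Gly and GlyGly at `n_times`
#' evenly spaced times. The network-yield coupling interpolates this grid
#' (log-bilinearly) instead of integrating an ODE per chamber.
#'
#' @param rates a [rate_constants()].
#' @param duration batch reaction time (s), default 120 h.
#' @param n_times number of stored time points.
#' @param conc_axis initial-concentration axis (M), used for both species;
#'   default 1e-10 to 1 M with five values per decade.
#' @return an object of class `reaction_grid`.
#' @export
build_reaction_grid <- function(rates, duration = 120 * 3600, n_times = 20L,
                                conc_axis = 10^seq(-10, 0, by = 0.2)) {
  stopifnot(inherits(rates, "rate_constants"))
  ng <- length(conc_axis)
  times <- seq(duration / n_times, duration, length.out = n_times)
  glygly <- array(NA_real_, c(ng, ng, n_times))
  gly <- array(NA_real_, c(ng, ng, n_times))
  fails <- character(0)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    out <- tryCatch(
      integrate_batch(reaction_state(Gly = conc_axis[i], TMP = conc_axis[j]),
                      rates, times = times, rtol = 1e-9, atol = 1e-20),
      error = function(e) e)
    if (inherits(out, "error")) {
      fails <- c(fails, sprintf("cell (%d, %d): %s", i, j,
                                conditionMessage(out)))
      next
    }
    sel <- match(times, out$time)
    glygly[i, j, ] <- out$GlyGly[sel]
    gly[i, j, ] <- out$Gly[sel]
  }
  if (length(fails)) {
    stop("reaction-grid cells failed:\n", paste(fails, collapse = "\n"))
  }
  structure(list(conc_axis = conc_axis, times = times,
                 glygly = glygly, gly = gly, rates = rates),
            class = "reaction_grid")
}

# log-bilinear interpolation of grid arrays at (gly0, tmp0), final time index
reaction_grid_lookup <- function(grid, gly0, tmp0, time_index = NULL) {
  ti <- time_index %||% length(grid$times)
  ax <- grid$conc_axis
  li <- axis_locate(ax, max(gly0, min(ax)), "gly_init", TRUE, TRUE)
  lj <- axis_locate(ax, max(tmp0, min(ax)), "tmp_init", TRUE, TRUE)
  gg_corners <- log10(grid$glygly[c(li$i0, li$i1), c(lj$i0, lj$i1), ti] + 1e-300)
  g_corners  <- log10(grid$gly[c(li$i0, li$i1), c(lj$i0, lj$i1), ti] + 1e-300)
  wi <- c(1 - li$w, li$w); wj <- c(1 - lj$w, lj$w)
  gg <- 10^(as.numeric(wi %*% gg_corners %*% wj))
  g  <- 10^(as.numeric(wi %*% g_corners %*% wj))
  c(glygly = gg, gly = g)
}

#' Map network chamber concentrations to reaction outcomes
#'
#' For every chamber, takes the bottom-region concentrations of glycine and
#' TMP predicted by the network model (feed concentration times the
#' chamber's bottom enrichment factor), looks up the closed-batch reaction
#' outcome in a precomputed [build_reaction_grid()] by log-bilinear
#' interpolation, and reports the dimer concentration and yield. The batch
#' view treats each chamber bottom as an independent, well-mixed 120 h
#' reactor (chamber relaxation times are tens of hours, so reactants are
#' continuously replenished on the reaction timescale).
#'
#' `mode = "path_cumulative"` additionally transports the product
#' downstream as a passive tracer: a chamber's product is its own batch
#' production plus the flow-weighted mixture of its feeding chambers'
#' product. This brackets the ambiguity of how much product accumulates
#' along a flow path; the plain batch value is the default.
#'
#' @param states a [propagate()] result containing species `"Gly"` and
#'   `"TMP"`.
#' @param grid a [build_reaction_grid()].
#' @param feed_gly,feed_tmp absolute feed concentrations (M) that the
#'   dimensionless network concentrations multiply.
#' @param mode `"batch"` or `"path_cumulative"`.
#' @param topology,flows required for `"path_cumulative"` only.
#' @return data.frame with columns `m`, `n`, `gly_bot`, `tmp_bot`,
#'   `glygly`, `gly_after`, `yield`.
#' @export
couple_network_reaction <- function(states, grid, feed_gly = 1e-6,
                                    feed_tmp = 1e-6,
                                    mode = c("batch", "path_cumulative"),
                                    topology = NULL, flows = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "reaction_grid"))
  sg <- states[states$species == "Gly", ]
  st <- states[states$species == "TMP", ]
  stopifnot(nrow(sg) > 0, nrow(st) > 0,
            all(paste(sg$m, sg$n) == paste(st$m, st$n)))
  gly_bot <- feed_gly * sg$c_bot
  tmp_bot <- feed_tmp * st$c_bot
  look <- t(mapply(function(g, tm) reaction_grid_lookup(grid, g, tm),
                   gly_bot, tmp_bot))
  out <- data.frame(m = sg$m, n = sg$n,
                    gly_bot = gly_bot, tmp_bot = tmp_bot,
                    glygly = look[, "glygly"], gly_after = look[, "gly"])
  if (mode == "path_cumulative") {
    if (is.null(topology) || is.null(flows)) {
      stop("path_cumulative mode needs topology and flows")
    }
    ch <- flows$channels
    P <- matrix(0, topology$N_y, topology$N_x)
    Pch <- rep(NA_real_, nrow(ch))
    for (n in seq_len(topology$N_x)) {
      for (m in seq_len(topology$N_y)) {
        own <- out$glygly[out$m == m & out$n == n]
        if (n == 1L) {
          pin <- 0
        } else {
          feedch <- which(ch$to_n == n & ch$to_m == m)
          w <- ch$flow[feedch]
          pin <- sum(Pch[feedch] * w) / sum(w)
        }
        P[m, n] <- pin + own
        outch <- which(ch$from_m == m & ch$from_n == n)
        Pch[outch] <- P[m, n]
      }
    }
    out$glygly <- P[cbind(out$m, out$n)]
  }
  out$yield <- reaction_yield(out$glygly, out$gly_after)
  out
}
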