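# Finite-volume chamber solver: flow-field invariants, transport solutions
# against the closed-form oracle, conservation, fraction averaging, and the
# transfer table.

test_that("flow field satisfies its structural invariants", {
  geom <- single_chamber_geometry()
  sett <- coarse_settings()

  # delta_T = 0 and no throughflow: everything at rest
  f0 <- convective_flow_field(geom, thermal_conditions(30, 30),
                              settings = sett)
  expect_equal(max(abs(f0$u_conv)), 0)
  expect_equal(max(abs(f0$Vface)), 0)
  expect_equal(max(abs(f0$Uface)), 0)

  # closed convection roll: zero net volume flux through every horizontal cut
  f1 <- convective_flow_field(geom, thermal_conditions(25, 40),
                              settings = sett)
  expect_lt(abs(sum(f1$Vface)), 1e-20)

  # max convective speed: linear in delta_T, quadratic in alpha
  th_film <- function(dT) thermal_conditions(32.5 - dT / 2, 32.5 + dT / 2)
  u1 <- max(abs(convective_flow_field(geom, th_film(5), settings = sett)$u_conv))
  u2 <- max(abs(convective_flow_field(geom, th_film(10), settings = sett)$u_conv))
  expect_equal(u2 / u1, 2, tolerance = 1e-10)
  geom2 <- chamber_geometry(thickness = 2 * geom$thickness)
  u3 <- max(abs(convective_flow_field(geom2, th_film(5), settings = sett)$u_conv))
  expect_equal(u3 / u1, 4, tolerance = 1e-10)

  # the geometry constructor already refuses low aspect ratios
  expect_error(chamber_geometry(height = 0.005, thickness = 1.7e-4), "aspect")
})

test_that("steady closed-chamber solution matches the closed-form log-slope", {
  # oracle equivalence on the default grid for a mid-range q; the full
  # q in [10, 100] sweep runs in the acceptance suite
  geom <- single_chamber_geometry()
  th <- thermal_conditions(25, 40)
  s <- solute("amp", 1.4e-9, 5.1e-3)
  flow <- convective_flow_field(geom, th)
  fld <- solve_drift_diffusion(flow, s, mode = "steady")
  prof <- colMeans(fld$values)
  yy <- fld$yc
  sel <- yy > 0.2 * geom$height & yy < 0.8 * geom$height
  slope <- unname(stats::coef(stats::lm(log(prof[sel]) ~ yy[sel]))[2])
  lam <- -thermotrap:::steady_profile_rate(s, geom, th)
  expect_equal(slope / lam, 1, tolerance = 0.05)
  expect_equal(mean(fld$values), 1, tolerance = 1e-9)
  expect_true(all(fld$values > 0))
})

test_that("uniform limits: S_T = 0 and delta_T = 0 preserve a uniform field", {
  geom <- single_chamber_geometry()
  sett <- coarse_settings()
  flow <- convective_flow_field(geom, thermal_conditions(30, 30),
                                settings = sett)
  fld <- solve_drift_diffusion(flow, solute("s", 1.4e-9, 0),
                               mode = "transient", duration = 3600,
                               n_steps = 10)
  expect_lt(max(abs(fld$values - 1)), 1e-10)
})

test_that("closed-chamber transient conserves mass to 1e-6 relative", {
  geom <- single_chamber_geometry()
  sett <- coarse_settings()
  flow <- convective_flow_field(geom, thermal_conditions(25, 40),
                                settings = sett)
  fld <- solve_drift_diffusion(flow, solute("s", 1.4e-9, 5e-3),
                               mode = "transient", duration = 18 * 3600,
                               n_steps = 60)
  expect_equal(mean(fld$values), 1, tolerance = 1e-6)
  # no meaningful undershoot from the central scheme
  expect_gt(min(fld$values), -1e-9 * max(fld$values))
})

test_that("transient approaches the steady profile monotonically", {
  geom <- single_chamber_geometry()
  sett <- coarse_settings()
  th <- thermal_conditions(25, 40)
  s <- solute("s", 1.4e-9, 5.1e-3)
  flow <- convective_flow_field(geom, th, settings = sett)
  ratio <- function(fld) {
    fr <- fraction_averages(fld, 4)
    fr[4] / fr[1]
  }
  r18 <- ratio(solve_drift_diffusion(flow, s, "transient",
                                     duration = 18 * 3600, n_steps = 60))
  r72 <- ratio(solve_drift_diffusion(flow, s, "transient",
                                     duration = 72 * 3600, n_steps = 120))
  rst <- ratio(solve_drift_diffusion(flow, s, "steady"))
  expect_gt(r18, 1)
  expect_gt(r72, r18)       # still developing after 18 h in this model
  expect_gt(rst, r72)
})

test_that("fraction averaging is conservative and exact on analytic fields", {
  geom <- single_chamber_geometry()
  sett <- coarse_settings()
  flow <- convective_flow_field(geom, thermal_conditions(25, 40),
                                settings = sett)
  # uniform field
  u <- solve_drift_diffusion(flow, solute("s", 1.4e-9, 0), "steady")
  expect_equal(fraction_averages(u, 4), rep(1, 4), tolerance = 1e-7)

  # mean of fraction means = chamber mean
  f <- solve_drift_diffusion(flow, solute("s", 1.4e-9, 5e-3), "steady")
  expect_equal(mean(fraction_averages(f, 4)), mean(f$values),
               tolerance = 1e-9)

  # analytic exponential field: slab integrals in closed form
  lam <- 60
  fld <- f
  prof <- exp(-lam * fld$yc)
  fld$values <- matrix(rep(prof, each = fld$nx), fld$nx, fld$ny)
  got <- fraction_averages(fld, 4)
  H <- geom$height; h <- H / 4
  ya <- (4 - (1:4)) * h
  # cell-midpoint field: compare against the discrete-cell closed form
  exact <- vapply(1:4, function(j) {
    cells <- which(fld$yc > ya[j] & fld$yc < ya[j] + h)
    mean(prof[cells])
  }, 0)
  expect_equal(got, exact, tolerance = 1e-12)
  # and against the continuum slab integral to discretization accuracy
  cont <- (exp(-lam * ya) - exp(-lam * (ya + h))) / (lam * h)
  expect_equal(got, cont, tolerance = 1e-3)
})

test_that("throughflow steady state balances solute fluxes within 1 %", {
  geom <- network_chamber_geometry()
  sett <- coarse_settings()
  th <- thermal_from_film(6, 32.5)
  for (fb in c(0.05, 0.5, 1)) {
    flow <- convective_flow_field(geom, th, Q_in = 1e-12,
                                  bottom_outflow_fraction = fb,
                                  settings = sett)
    fld <- solve_drift_diffusion(flow, solute("s", 1.4e-9, 7e-3), "steady")
    r <- chamber_response(fld)
    bal <- flow$Q_out_top * r$c_out_top + flow$Q_out_bot * r$c_out_bot
    expect_equal(bal / flow$Q_in, 1, tolerance = 0.01)
  }
})

test_that("delta_T = 0 throughflow response is the identity", {
  geom <- network_chamber_geometry()
  sett <- coarse_settings()
  flow <- convective_flow_field(geom, thermal_conditions(32.5, 32.5),
                                Q_in = 1e-12, bottom_outflow_fraction = 0.3,
                                settings = sett)
  r <- chamber_response(solve_drift_diffusion(flow, solute("s", 1.4e-9, 7e-3),
                                              "steady"))
  expect_equal(r$c_out_top, 1, tolerance = 1e-6)
  expect_equal(r$c_out_bot, 1, tolerance = 1e-6)
  expect_equal(r$bottom_mean, 1, tolerance = 1e-6)
})

test_that("grid refinement changes the bottom mean by less than 1 %", {
  # halving both grid spacings relative to the package default
  geom <- network_chamber_geometry()
  th <- thermal_from_film(6, 32.5)
  s <- solute("s", 1.4e-9, 7e-3)
  r1 <- thermotrap:::compute_response(geom, th, s, 1e-12, 0.2,
                                      solver_settings(nx = 40, ny = 200))
  r2 <- thermotrap:::compute_response(geom, th, s, 1e-12, 0.2,
                                      solver_settings(nx = 80, ny = 400))
  expect_equal(r1$bottom_mean / r2$bottom_mean, 1, tolerance = 0.01)
})

test_that("transfer table stores exact nodes and interpolates accurately", {
  tab <- gly_tmp_table()
  sett <- coarse_settings()

  # node query returns the stored response bit-identically
  r <- interpolate_transfer(tab, 10, 1.4e-9, 7e-3, 1e-12, 0.5)
  direct <- thermotrap:::compute_response(network_chamber_geometry(),
                                          thermal_from_film(10, 32.5),
                                          solute("x", 1.4e-9, 7e-3),
                                          1e-12, 0.5, sett)
  expect_identical(r$bottom_mean, direct$bottom_mean)

  # midpoint between two adjacent nodes of the (linear) S_T axis with all
  # else on-node = arithmetic mean of the stored responses
  ra <- interpolate_transfer(tab, 10, 1.4e-9, 1.4e-3, 1e-12, 0.5)
  rb <- interpolate_transfer(tab, 10, 1.4e-9, 1.7e-3, 1e-12, 0.5)
  rmid <- interpolate_transfer(tab, 10, 1.4e-9, 1.55e-3, 1e-12, 0.5)
  expect_equal(rmid$bottom_mean, (ra$bottom_mean + rb$bottom_mean) / 2,
               tolerance = 1e-12)

  # midpoint on the log Q_in axis = value at the log-mean flow
  qa <- 1e-12; qb <- 5e-12
  rq <- interpolate_transfer(tab, 10, 1.4e-9, 7e-3, sqrt(qa * qb), 0.5)
  ra2 <- interpolate_transfer(tab, 10, 1.4e-9, 7e-3, qa, 0.5)
  rb2 <- interpolate_transfer(tab, 10, 1.4e-9, 7e-3, qb, 0.5)
  expect_equal(rq$bottom_mean, (ra2$bottom_mean + rb2$bottom_mean) / 2,
               tolerance = 1e-12)

  # off-grid S_T within 10 % of a direct solve
  roff <- interpolate_transfer(tab, 10, 1.4e-9, 6.5e-3, 1e-12, 0.5)
  doff <- thermotrap:::compute_response(network_chamber_geometry(),
                                        thermal_from_film(10, 32.5),
                                        solute("x", 1.4e-9, 6.5e-3),
                                        1e-12, 0.5, sett)
  expect_equal(roff$bottom_mean / doff$bottom_mean, 1, tolerance = 0.1)

  # out-of-hull error names the axis; clamp mode accepts
  expect_error(interpolate_transfer(tab, 10, 1.4e-9, 7e-3, 1e-9, 0.5),
               "Q_in")
  expect_silent(interpolate_transfer(tab, 10, 1.4e-9, 7e-3, 1e-9, 0.5,
                                     clamp = TRUE))

  # delta_T = 0 cells are the identity
  t0 <- identity_table()
  r0 <- interpolate_transfer(t0, 0, 1e-9, 3e-3, 1e-12, 0.3)
  expect_equal(r0$c_out_top, 1)
  expect_equal(r0$c_out_bot, 1)
  expect_equal(r0$bottom_mean, 1)
})

test_that("transfer tables persist losslessly and respond monotonically to S_T", {
  tab <- gly_tmp_table()
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_transfer_table(tab, tf)
  tab2 <- load_transfer_table(tf)
  expect_equal(tab2$bottom_mean, tab$bottom_mean, tolerance = 1e-14)
  expect_equal(tab2$axes, tab$axes)

  # larger S_T -> larger bottom accumulation at fixed other axes
  bm <- vapply(tab$axes$S_T, function(st)
    interpolate_transfer(tab, 10, 1.4e-9, st, 1e-12, 0.2)$bottom_mean, 0)
  expect_true(all(diff(bm) > 0))
})
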