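# Measurement pipeline: normalization, enrichment statistics, Soret fitting
# and the replicate error decomposition.

mk_table <- function(values_by_species, replicate = 1, delta_T = 15) {
  do.call(rbind, lapply(names(values_by_species), function(sp) {
    v <- values_by_species[[sp]]
    data.frame(species = sp, replicate = replicate,
               fraction_index = seq_along(v), value = v,
               delta_T_K = delta_T)
  }))
}

test_that("normalization implements the per-replicate fraction mean", {
  tab <- fraction_table(mk_table(list(a = c(2, 2, 2, 2), b = c(4, 2, 1, 1))))
  nn <- normalize_fractions(tab)
  expect_equal(nn$value[nn$species == "a"], c(1, 1, 1, 1))
  expect_equal(nn$value[nn$species == "b"], c(2, 1, 0.5, 0.5))

  # idempotent
  nn2 <- normalize_fractions(nn)
  expect_equal(nn2$value, nn$value)

  # calibration invariance: scaling one species' raw values changes nothing
  tab2 <- tab
  tab2$value[tab2$species == "b"] <- 37.2 * tab2$value[tab2$species == "b"]
  expect_equal(normalize_fractions(tab2)$value, nn$value)

  tab3 <- mk_table(list(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1)))
  expect_error(normalize_fractions(fraction_table(tab3)), "all-zero")
})

test_that("pairwise enrichment averages ratios, not concentrations", {
  t1 <- mk_table(list(A = c(1, 1, 1, 2), B = c(1, 1, 1, 1)), replicate = 1)
  t2 <- mk_table(list(A = c(1, 1, 1, 2), B = c(1, 1, 1, 1)), replicate = 2)
  t3 <- mk_table(list(A = c(1, 1, 1, 2), B = c(1, 1, 1, 1)), replicate = 3)
  em <- pairwise_enrichment(fraction_table(rbind(t1, t2, t3)), "bottom")
  expect_equal(unname(diag(em$mean)), c(0, 0))
  # per-replicate bottom ratios are all (2/1.25)/(1/1) = 1.6
  expect_equal(em$mean["A", "B"], 0.6, tolerance = 1e-12)
  expect_equal(em$sd["A", "B"], 0)

  # averaging order matters: hand-computed example with jittered replicates.
  # bottom values A: 2, 3; B: 1, 2 -> mean of ratios = (2/1 + 3/2)/2 = 1.75
  # whereas ratio of averages would be 2.5/1.5 ~ 1.667
  ta <- mk_table(list(A = c(1, 1, 1, 2), B = c(1, 1, 1, 1)), replicate = 1)
  tb <- mk_table(list(A = c(1, 1, 1, 3), B = c(1, 1, 1, 2)), replicate = 2)
  tab <- fraction_table(rbind(ta, tb))
  tab <- normalize_fractions(tab)
  # undo normalization effect by using raw bottom entries directly:
  m <- thermotrap:::fraction_matrix(tab, 4)
  got <- mean(m["A", ] / m["B", ]) - 1
  em2 <- pairwise_enrichment(tab, "bottom")
  expect_equal(em2$mean["A", "B"], got)
  expect_true(abs(got - (mean(m["A", ]) / mean(m["B", ]) - 1)) > 1e-6)
})

test_that("mean-of-ratios obeys the Jensen inequality property", {
  set.seed(42)
  for (i in 1:20) {
    vals <- list(A = stats::runif(4, 0.2, 3), B = stats::runif(4, 0.2, 3))
    tabs <- do.call(rbind, lapply(1:3, function(k) {
      v <- lapply(vals, function(x) x * exp(stats::rnorm(4, 0, 0.2)))
      mk_table(v, replicate = k)
    }))
    em <- pairwise_enrichment(fraction_table(tabs), "bottom")
    prod_ <- (1 + em$mean["A", "B"]) * (1 + em$mean["B", "A"])
    expect_gte(prod_, 1 - 1e-12)
  }
})

test_that("pool enrichment matches hand arithmetic and is scale-invariant", {
  tab <- fraction_table(mk_table(list(A = c(1, 1, 1, 2) / 1.25,
                                      B = c(1, 1, 1, 1))))
  # normalized bottom values: A = 1.6, B = 1; pool = 1.3
  pe <- pool_enrichment(tab, "bottom")
  expect_equal(pe$enrichment[pe$species == "A"], 1.6 / 1.3 - 1,
               tolerance = 1e-12)
  expect_equal(pe$enrichment[pe$species == "B"], 1 / 1.3 - 1,
               tolerance = 1e-12)

  # two species with normalized values 2 and 1: pool 1.5 -> +1/3, -1/3
  tab2 <- fraction_table(mk_table(list(A = c(0.5, 0.5, 1, 2),
                                       B = c(1.25, 1.25, 0.5, 1))))
  pe2 <- pool_enrichment(tab2, "bottom")
  expect_equal(sort(pe2$enrichment), c(-1 / 3, 1 / 3), tolerance = 1e-12)

  # difference form differs from ratio form on the same data
  pd <- pool_enrichment(tab2, "bottom", form = "difference")
  expect_false(isTRUE(all.equal(pd$enrichment, pe2$enrichment)))

  expect_error(pool_enrichment(fraction_table(
    mk_table(list(A = c(1, 1, 1, 1)))), "bottom"), "2 species")
})

test_that("noiseless synthetic tables refit their generating S_T within 2 %", {
  sett <- coarse_settings()
  for (st_true in c(1e-3, 4e-3, 8e-3)) {
    sp <- synthetic_spec(data.frame(name = "x", D = 1.4e-9, S_T = st_true),
                         delta_T = 15, jitter = 0, K = 1, noise = 0,
                         seed = 5)
    tab <- synth_fraction_table(sp, settings = sett)
    est <- fit_soret(tab, D = 1.4e-9, settings = sett)
    expect_equal(est$S_T, st_true, tolerance = 0.02)
    expect_false(est$at_boundary)
  }
})

test_that("uniform fractions fit to S_T = 0 and boundary optima are flagged", {
  sett <- coarse_settings()
  tab <- fraction_table(mk_table(list(x = c(1, 1, 1, 1))))
  est <- fit_soret(tab, D = 1.4e-9, settings = sett)
  expect_equal(est$S_T, 0, tolerance = 1e-6)

  # generating value outside the (deliberately narrow) search interval
  sp <- synthetic_spec(data.frame(name = "x", D = 1.4e-9, S_T = 8e-3),
                       delta_T = 15, jitter = 0, K = 1, noise = 0, seed = 5)
  tab2 <- synth_fraction_table(sp, settings = sett)
  est2 <- fit_soret(tab2, D = 1.4e-9, settings = sett, bounds = c(-1e-3, 5e-3))
  expect_true(est2$at_boundary)
})

test_that("fitted S_T depends only marginally on the assumed D", {
  sett <- coarse_settings()
  sp <- synthetic_spec(data.frame(name = "x", D = 1.4e-9, S_T = 5.1e-3),
                       delta_T = 15, jitter = 0, K = 1, noise = 0, seed = 5)
  tab <- synth_fraction_table(sp, settings = sett)
  lo <- fit_soret(tab, D = 0.7e-9, settings = sett)$S_T
  hi <- fit_soret(tab, D = 2.1e-9, settings = sett)$S_T
  expect_lt(abs(lo / 5.1e-3 - 1), 0.1)
  expect_lt(abs(hi / 5.1e-3 - 1), 0.1)
})

test_that("replicate error split separates systematic from random parts", {
  # identical replicates: nothing to split
  f0 <- cbind(c(1, 2, 3) * 1e-3, c(1, 2, 3) * 1e-3)
  s0 <- replicate_error_split(f0)
  expect_equal(s0$sigma_systematic, 0, tolerance = 1e-12)
  expect_equal(s0$sigma_random, 0, tolerance = 1e-12)

  # replicate B = 1.1 x A exactly: pure systematic error ~ 10 %
  f1 <- cbind(c(1, 2, 5) * 1e-3, c(1, 2, 5) * 1.1e-3)
  s1 <- replicate_error_split(f1)
  expect_equal(s1$sigma_systematic, 0.10, tolerance = 0.05)
  expect_equal(s1$sigma_random, 0, tolerance = 1e-15)

  expect_error(replicate_error_split(matrix(1:2, 1)), "2 species")

  # Monte Carlo: injected Gaussian noise is recovered as the random error
  set.seed(7)
  rec <- replicate(200, {
    S <- stats::runif(8, 1e-3, 8e-3)
    f <- vapply(1:3, function(k) S + stats::rnorm(8, 0, 3e-4), numeric(8))
    replicate_error_split(f)$sigma_random
  })
  expect_equal(mean(rec), 3e-4, tolerance = 0.1)
})

test_that("temperature jitter appears as systematic, not random, error", {
  sett <- coarse_settings()
  sol <- fixture_solutes("aminoazoles")
  sp <- synthetic_spec(sol, delta_T = 15, jitter = 1.5, K = 3, noise = 0,
                       seed = 11)
  tab <- synth_fraction_table(sp, settings = sett)
  est <- fit_soret(tab, D = 1.4e-9, settings = sett)
  spl <- replicate_error_split(attr(est, "replicate_fits"))
  expect_gt(spl$sigma_systematic, 0.01)
  expect_lt(spl$sigma_random, 0.05 * mean(est$S_T))
})
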