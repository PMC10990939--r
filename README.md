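# thermotrap

Heat flowing across a thin, water-filled rock fracture sets up a laminar
convection roll; thermophoresis superimposes a slow drift of dissolved
molecules toward the cold wall. Their interplay — thermogravitational
accumulation — builds an exponential vertical concentration profile whose
strength depends sensitively on each solute's Soret coefficient `S_T`
(units K⁻¹, drift velocity `v_T = −∇T · S_T · D`). Because `S_T` differs
even between molecules of identical mass, networks of such fractures act as
highly parallel separation cascades for prebiotic building blocks: amino
acids, nucleobases, nucleotides, 2-aminoazoles and polyphosphates.

`thermotrap` is for researchers modelling this scenario. It provides:

* **Thin-gap chamber physics.** Water properties, the dimensionless
  accumulation exponent
  `q = ΔT β g ρ α³ / (6 η D)`
  (gap thickness `α`, film-temperature water properties), and the
  closed-form steady profile
  `c(y) ∝ exp(−[(q/120)/(1 + q²/10080)] · S_T ΔT · y/α)`,
  which peaks in strength at `q = √10080 ≈ 100`.
* **A finite-volume drift–diffusion solver** for the 2-D (height × gap)
  chamber with optional throughflow. The hydrodynamics is the analytic
  thin-gap limit (cubic convection profile plus Poiseuille throughflow)
  rather than a finite-element Navier–Stokes solve — justified by aspect
  ratios of 300–1200:1 and verified against the closed-form profile to
  ~0.1 % in log-slope.
* **The Soret-measurement pipeline**: normalization of four-fraction
  freeze-and-cut readouts, pairwise/pool enrichment statistics (ratios are
  averaged over replicates *after* being formed per replicate), bounded
  least-squares fitting of `S_T` against the transient forward model, and a
  decomposition of replicate scatter into systematic (temperature-jitter)
  and random parts.
* **A stochastic crack-network simulator**: seeded random topologies on an
  `N_y × N_x` chamber grid with strictly left-to-right flow, solvent-mass
  conserving channel flows, column-wise concentration propagation through a
  precomputed transfer table, the median-of-ten-maxima enrichment
  statistic, and ensemble error propagation by Gaussian resampling of
  Soret coefficients.
* **TMP-driven glycine dimerization kinetics** (activation, hydrolysis,
  dimerization; rate constants `k1…k5`), simultaneous rate fitting by
  Levenberg–Marquardt in log-space, a reaction lookup grid, and the
  coupling that maps network chamber concentrations to 120 h batch yields
  `2c_GlyGly/(2c_GlyGly + c_Gly)`.
* **Seeded synthetic-data generators** for every input: fraction tables
  (forward model + 1–2 K replicate temperature jitter + multiplicative
  noise), titration/time-series reaction data, and solute presets with
  explicit provenance labels (reported anchors vs calibrated stand-ins).

## Worked example

```r
library(thermotrap)

## 1. How strongly does a nucleotide accumulate in a single crack?
geom <- single_chamber_geometry()                    # 50 mm x 170 um
th   <- thermal_conditions(T_cold = 25, T_hot = 40)  # 15 K across the gap
amp  <- solute("3',5'-AMP", D = 1.4e-9, S_T = 5.1e-3)
soret_exponent_q(geom, th, amp$D)
#> [1] 36.78439
p <- steady_profile(amp, geom, th, y = c(0, 0.05))
p[1] / p[2]          # steady-state bottom/top concentration ratio
#> [1] 437.3849
```

A `q` of ~37 and a 437-fold steady bottom/top ratio: even a 15 K difference
across a 170 µm crack separates this nucleotide strongly from weaker
accumulators.

```r
## 2. Fit Soret coefficients from (here: synthetic) fraction data
spec <- synthetic_spec(fixture_solutes("aminoazoles"), delta_T = 15,
                       jitter = 1.5, K = 3, noise = 0.03, seed = 1)
tab <- synth_fraction_table(spec, settings = solver_settings(nx = 24, ny = 120))
est <- fit_soret(tab, D = 1.4e-9, settings = solver_settings(nx = 24, ny = 120))
est[, c("species", "S_T", "sigma_random", "sigma_systematic")]
#>   species         S_T sigma_random sigma_systematic
#> 1     2AI 0.007116764 1.274699e-04       0.02498499
#> 2     2AO 0.004191559 7.265614e-05       0.02498499
#> 3     2AT 0.005487270 1.401060e-04       0.02498499
```

The 2-aminoazole coefficients are recovered within a few per cent of the
generating values (7.5, 4.5, 6.0 ×10⁻³ K⁻¹) despite 3 % measurement noise
and a 1.5 K replicate temperature jitter; the jitter shows up as the shared
`sigma_systematic`, not as random error.

```r
## 3. A small crack network (10 x 10 chambers, 1 nl/s inlets, dT = 10 K)
sol <- fixture_solutes("gly_tmp")                    # glycine (weak) + TMP (strong)
tabT <- build_transfer_table(
  axes = list(delta_T = 10, D = sort(unique(sol$D)), S_T = sort(sol$S_T),
              Q_in = c(0.01, 0.1, 1, 10) * 1e-12,
              Q_out_bot = c(0.01, 0.1, 0.5, 1)),
  settings = solver_settings(nx = 24, ny = 120))
topo <- generate_topology(N_x = 10, N_y = 10, Q_in = 1e-12, seed = 7)
fl   <- solve_flow_rates(topo)
st   <- propagate(topo, fl, sol, delta_T = 10, tabT, clamp = TRUE)
max_enrichment(st, "TMP", "Gly")    # median of the ten largest ratios
#> [1] 2.588725

## 4. What does that do to glycine dimerization?
grid <- build_reaction_grid(reference_rate_constants())
cp <- couple_network_reaction(st, grid, feed_gly = 1e-6, feed_tmp = 1e-6)
max(cp$tmp_bot) / 1e-6              # best chamber: 125x the 1 uM feed
#> [1] 125.4975
max(cp$yield)
#> [1] 2.754958e-06
```

In this single small system the best chamber concentrates TMP 125-fold and
raises the dimer yield six orders of magnitude above the no-heat-flow level
(~1e-12 at ΔT = 0). Larger ensembles (20 × 20 chambers, dozens of pooled
systems, as in the acceptance suite) develop thousand-fold pairwise
enrichments and niches with >99.9 % purity of the thermophoretically weaker
species.

All stochastic steps (topologies, flow splits, Soret resampling, noise) are
pure functions of explicit integer seeds.

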