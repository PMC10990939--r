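---
title: "Models and numerical methods in thermotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in thermotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical models, the numerical choices, and the
deliberate design decisions behind `thermotrap`, in enough detail that a
reader can judge what the package's results do and do not show.

## 1. The single-chamber transport model

A heat-flow chamber is a vertical water-filled slab of height $H$ (50 mm
for the measurement chamber, 200 mm for network chambers), width $W$
(60 mm), and gap thickness $\alpha = 170\,\mu$m between a hot and a cold
wall. Solute transport obeys the drift–diffusion equation

$$\frac{\partial c}{\partial t} =
  \nabla\cdot\left[D\nabla c - (\mathbf u - S_T D \nabla T)\,c\right],$$

with diffusion coefficient $D$, Soret coefficient $S_T$ (positive
$\Rightarrow$ drift toward the cold wall) and solvent velocity $\mathbf u$.
The temperature profile across the thin gap is taken as linear, so the
thermophoretic drift is a constant horizontal velocity
$-S_T D \,\Delta T/\alpha$.

**Thin-gap hydrodynamics instead of Navier–Stokes.** With aspect ratios of
300–1200:1, the convection roll is fully developed over essentially the
whole height, and the classical lubrication/Boussinesq limit applies: the
vertical velocity is the antisymmetric cubic profile
$u_y(s) = K\,(s/4 - s^3)$, $s = x/\alpha - 1/2$,
$K = \rho g \beta \Delta T \alpha^2/(6\eta)$, rising at the hot wall and
sinking at the cold wall with zero net flux. Throughflow adds a parabolic
(Poiseuille) profile carrying the bottom-outlet share of the inflow. This
analytic replacement of a finite-element hydrodynamics solve is the largest
deliberate modelling simplification in the package; its accuracy is checked
against the closed-form steady profile (Section 3). The turning regions at
the chamber ends, whose physical height is of order $\alpha$, are collapsed
into the first and last finite-volume cell rows, where in-plane fluxes are
reconstructed from continuity so that the discrete field is exactly
divergence-free.

Water properties ($\rho$, $\eta$, $\beta$) are evaluated once at the film
(mean) temperature from the Kell (1975) density polynomial (with
$\beta = -\rho^{-1}\,\mathrm d\rho/\mathrm dT$ as its exact derivative, so
$\beta \to 0$ near the 4 °C density maximum) and a Vogel-type viscosity
correlation, both standard 1-atm liquid-water fits valid over the 5–95 °C
range the code accepts.

## 2. Discretization

The solver is a finite-volume scheme on a uniform rectangular grid, default
$40$ cells across the gap $\times\ 200$ along the height.

* **Vertical (axial) advection is central, not upwind.** This is the one
  place where the obvious robust choice is quantitatively wrong: upwinding
  the vertical convective flux adds a numerical axial dispersion
  $u_\max \Delta y/2$ that is comparable to molecular diffusion itself at
  the default resolution. Axial dispersion is exactly what limits
  thermogravitational accumulation (it is the origin of the
  $1 + q^2/10080$ denominator in the steady profile), so upwinding flattens
  the exponential profile by a factor of order two at $q \approx 36$. With
  central vertical fluxes the steady log-slope agrees with the closed form
  to about 0.1 % across $q \in [10, 100]$. The cost is that the operator is
  not an M-matrix; in practice undershoots are below $10^{-9}$ of the peak
  concentration, and a test enforces this.
* **Horizontal advection (thermophoretic drift and the end-row closure
  flow) is upwinded.** The drift cell Péclet number is $\sim 10^{-2}$, so
  upwinding there adds negligible dispersion; the end rows are turning
  regions where first-order accuracy is harmless.
* **Steady solutions are computed directly** by sparse LU factorization of
  the stationary operator: for a throughflow chamber the system is regular;
  for a closed chamber the operator's one-dimensional null space *is* the
  steady profile, and one (redundant) balance row is replaced by the
  mean-concentration constraint. This is exact up to linear-solver
  round-off, strictly tighter than iterating a pseudo-transient to a
  $10^{-8}$ tolerance.
* **Transients use implicit Euler** with a single factorization of the step
  operator (default 120 steps for an 18 h solve; halving or quadrupling the
  step count changes 18 h fraction means by well under 1 %). Mass
  conservation is exact by flux antisymmetry.

Outlet concentrations are the mean concentrations of the top and bottom
cell rows from which the outflow segments withdraw fluid; the "bottom"
concentration of a network chamber is the volume-weighted mean over the
lowest 1.5 mm (partial cells included).

**A finding worth stating plainly:** in this model an 18 h transient at the
measurement-chamber conditions reaches only a few per cent of the *steady*
bottom/top ratio; the steady state is approached on a $\sim$150 h scale
(the profile builds at $v \approx \lambda D_{\mathrm{eff}} \approx
0.2\,\mu$m/s over 50 mm). The Soret-fitting pipeline therefore always uses
the 18 h *transient* forward model — the same model in both the generating
and the fitting direction — and never assumes the experiment is at steady
state. The steady closed form serves only as the analytic oracle for the
solver.

## 3. The closed-form oracle

For a closed chamber the classical thermogravitational-column series
solution gives the steady profile

$$c(y) \propto \exp\!\left(-\frac{q/120}{1+q^{2}/10080}\,
  S_T\,\Delta T\,\frac{y}{\alpha}\right),\qquad
  q = \frac{\Delta T\,\beta g \rho\,\alpha^{3}}{6 \eta D},$$

with $y$ measured upward from the bottom and profiles renormalized to
chamber-mean 1 (matching the normalization applied to measured fraction
tables). The package treats this expression as exact by definition and
validates the numerical solver against its log-slope (within 5 % required,
$\sim$0.1 % achieved) for $q \le 100$; beyond the optimum $q = \sqrt{10080}$
the profile shortens toward the grid scale and accuracy degrades gracefully
with resolution.

## 4. Soret-coefficient inference

Measured fraction tables (four equal-height slabs, top-first indexing) are
normalized per species and replicate to mean 1, which removes calibration
factors entirely. Enrichment statistics form concentration ratios *per
replicate* and average afterwards, because run-to-run temperature
differences shift all species of a replicate together; averaging
concentrations first would bias the ratios. For the species-versus-pool
statistic the ratio form (replicate mean of $[A]/\bar c$, minus 1) is the
default; a literal difference form is available behind a flag for
comparison, and no claim is made about which variant any particular
published analysis used.

Fitting minimizes the sum of squared differences between measured and
simulated fraction means over $S_T \in [-10^{-2}, 2\times10^{-2}]$ K⁻¹.
Because the objective is one-dimensional and unimodal (fraction means are
monotone in $S_T$), a bounded golden-section search replaces multi-start
least squares; an optimum within $10^{-4}$ of a bound is flagged. Default
diffusion-coefficient assumptions are $8\times10^{-10}$ m²/s for amino
acids and $1.4\times10^{-9}$ m²/s for 2-aminoazoles and nucleotide
components; perturbing $D$ by ±50 % moves fitted coefficients by less than
10 %, so these class-level values suffice.

Replicate variability is decomposed by regressing, for every ordered
replicate pair, one replicate's fitted coefficients on the other's through
the origin across species: the mean deviation of the slopes from 1 is the
systematic error (the multiplicative signature of temperature jitter); the
mean residual s.d., divided by $\sqrt 2$ because both coordinates carry one
replicate's noise, is the per-replicate random error. Monte-Carlo tests
confirm the random error estimator recovers injected Gaussian noise.

## 5. The crack-network model

Chambers sit on an $N_y$ rows $\times\ N_x$ columns grid; flow is strictly
left-to-right (the column-wise solution scheme requires a DAG, and the
row-adjacency rule — targets within one row — is taken from the study
system's connectivity description). Each chamber draws one or two outflow
channels (two with probability 1/2); a repair pass guarantees every
next-column chamber at least one feed, so in-degrees range from 1 to 3 —
the column renormalization is a flow-weighted mixture over however many
channels feed a chamber. Two-outflow chambers split their flow with a
seeded uniform ratio in [0.1, 0.9] between a randomly designated bottom
port and a top port; a lone outflow uses a random port, giving a
bottom-outflow fraction of exactly 0 or 1. All of these distributional
choices are interpretations of a connectivity scheme that does not pin them down;
they are fixed defaults, not tuned quantities. With 1 nl/s inlets the
resulting chamber flows mostly (about 89 % of chambers over 30 seeds) fall
between 0.1 and 10 nl/s.

Concentrations propagate column by column through a precomputed **transfer
table**: steady single-chamber responses on a five-axis grid
$(\Delta T, D, S_T, Q_{\mathrm{in}}, f_{\mathrm{bot}})$, interpolated
multilinearly with the two flow axes in $\log_{10}$. Two numerical details
matter:

* Every interpolated outlet pair is projected onto the exact per-chamber
  solute flux balance $(1-f)\,c_{\mathrm{top}} + f\,c_{\mathrm{bot}} =
  c_{\mathrm{in}}$. Interpolation errors of a fraction of a per cent would
  otherwise compound multiplicatively over a 20-column cascade into tens of
  per cent of lost or invented solute; with the projection, system-wide
  solute conservation is exact and the $f = 0$ (top-port-only) limit needs
  no special case.
* Network flows can leave the tabulated $Q_{\mathrm{in}}$ range after many
  uneven splits; ensemble runs therefore clamp queries to the table hull
  (logged). When a table is built for a specific species set, its $S_T$
  axis should include the species' mean coefficients as exact nodes, with
  flanking nodes covering the resampling spread.

The "maximum enrichment" of species A over B is the median of the ten
largest per-chamber ratios $c_{\mathrm{bot},A}/c_{\mathrm{bot},B}$, pooled
across the $Z$ systems of a run (per-system evaluation is available); the
median guards against single-chamber outliers. Ensembles repeat the whole
simulation with each species' $S_T$ redrawn from a Gaussian with its random
error as s.d., propagating measurement uncertainty into enrichment
predictions.

Because every chamber passes its solute flux downstream at steady state,
*column means* of bottom concentrations do not decay along the flow
direction; the separation manifests as niche structure: chains of
bottom-routed chambers multiply the strong accumulator's concentration
(dominance niches at high absolute concentration), chains of top-routed
chambers deplete it exponentially (weak-species niches at low absolute
concentration, purity above 99.9 % in pooled 20×20 ensembles), and the weak
species' relative share grows downstream.

## 6. Glycine-dimerization kinetics

The reaction scheme is: activation of glycine by TMP
($k_1$, M⁻¹s⁻¹), hydrolysis of the activated species ($k_2$, s⁻¹),
dimerization ($k_3$, M⁻¹s⁻¹), TMP hydrolysis ($k_4$, s⁻¹) and dimer
hydrolysis ($k_5$, s⁻¹). Although bimolecular rates are sometimes printed
with the unit "M s⁻¹", dimensional consistency of the rate equations
requires M⁻¹ s⁻¹, which is what the package uses. The glycine-unit total
$[\mathrm{Gly}] + [\mathrm{GlyAct}] + 2[\mathrm{GlyGly}]$ is conserved
exactly by the scheme and to $10^{-8}$ relative by the integrator
(`deSolve::lsoda`, rtol $10^{-10}$).

$k_4$ is fitted separately from a TMP-only decay series (log-linear
initialization, `nls` refinement when the data carry noise). The remaining
four rates are fitted simultaneously in log-space by Levenberg–Marquardt
(`minpack.lm`) to the full titration-plus-time-series design, with
residuals on $\log_{10}(c + 10^{-12})$ so measurements spanning decades
contribute comparably; five seeded multi-starts (±1 decade) guard against
local minima, box bounds $[10^{-12}, 10^{2}]$ flag degenerate data, and
relative uncertainties come from the residual covariance of the
log-parameters. On noiseless self-generated data all four rates are
recovered to $\ll$1 %.

At trace concentrations the scheme admits a closed-form check: with
quasi-steady GlyAct and first-order decay of TMP and GlyGly,

$$[\mathrm{GlyGly}](t) = \frac{k_1 k_3 G_0^2 T_0}{k_2}\,
 \frac{e^{-k_4 t} - e^{-k_5 t}}{k_5 - k_4},$$

which the integrator matches to $\sim$1 % at 1 µM over 120 h. (The simpler
linear-in-$t$ estimate is off by ~30 % because $k_4 t$ and $k_5 t$ are not
small over 120 h.)

**Network coupling.** Each chamber's bottom glycine and TMP concentrations
(feed × enrichment factor) index a precomputed grid of closed-batch
outcomes (default $10^{-10}$–$1$ M, five concentrations per decade, 120 h
in 20 stored time points; log-bilinear interpolation, accurate to
$\lesssim$10 % against direct integration). The batch view — each chamber
bottom as an independent well-mixed 120 h reactor — is justified by chamber
relaxation times of $10^1$–$10^2$ h; rates fitted at 90 °C are applied
without temperature correction, a deliberate simplification. A
`path_cumulative` variant additionally transports product downstream as a
passive tracer, bracketing the ambiguity in how much product accumulates
along a flow path; without heat flow the plain batch gives $\sim$0.3 fM
from a 1 µM feed and the cumulative variant a few fM.

## 7. Synthetic data and solute presets

The generators emulate: triplicate fraction tables produced by the forward
transient model with a uniform ±`jitter`/2 spread of the true temperature
difference around the nominal value (default total spread 1.5 K, within
the 1–2 K range such experiments show) and multiplicative lognormal noise
on fraction means (default σ = 3 %; chromatographic integrals are positive
with roughly proportional error — the noise model itself is a package
choice, not a measured property); reaction datasets integrated at the
experimental design points (9 TMP levels × 2 glycine levels at 16 h, a
100 mM/100 mM time series to 120 h, and a 0.2 mM TMP-only decay); and
seeded network topologies. The generated tables deliberately report the
*nominal* temperature difference: the jitter represents run-to-run gradient
error the experimenter cannot correct for, which is exactly the mechanism
that produces the systematic error branch of the replicate decomposition.

What passing round trips show — and what they do not: zero-noise closure
(fit recovers generator input within 2 % for $S_T$, 5 % for rates)
validates the estimation machinery, not the physical fidelity of the
forward model to any real chamber; those are separate claims, backed by the
oracle tests for the transport core and by nothing stronger than
order-of-magnitude network comparisons for the full cascade.

Solute presets carry a `provenance` column. Two coefficients are
`reported` measurement anchors (3′,5′-AMP, $5.1\times10^{-3}$ K⁻¹;
TMP, $\approx 7\times10^{-3}$ K⁻¹). All others are synthetic stand-ins:
`calibrated-synthetic` values were obtained once by inverting this
package's 18 h forward model against reported single-chamber bottom/top
enrichment pairs at ΔT = 15 K and then constrained to the reported global
range $[1.4, 7.5]\times10^{-3}$ K⁻¹ (the inversion inherits the thin-gap
model's bias, so two raw values fell just outside);
`interpolated-synthetic` values are placed between calibrated neighbours to
reproduce the reported qualitative ordering. Ensemble predictions built on
these stand-ins should be read as order-of-magnitude statements.

## 8. Problem sizes, tolerances and degenerate inputs

Defaults: 40 × 200 cells, 120 implicit steps per 18 h transient,
interpolation tables built per run with axes chosen to cover the query
hull. The test suite exercises reduced sizes (24 × 120 cells; 10 × 10
networks with Z = 5; one 20 × 20 ensemble with Z = 12 plus a Z = 30 pooled
purity check) chosen so the full suite completes in a few minutes; grid
refinement changes bottom means by <1 %, and halving/octupling the
transient step count moves fraction means by ≪1 %.

Degenerate inputs are handled explicitly: ΔT = 0 short-circuits to exact
identity responses everywhere (chamber, table, network, reaction coupling
at feed level); all-zero fraction rows, zero denominators in enrichment
ratios, pool means of zero, out-of-hull interpolation queries, non-decaying
decay series and zero-product rate fits raise named errors, warnings or
boundary flags rather than returning silent numbers. Aspect ratios below
50:1 are refused because the thin-gap flow model is invalid there.

## 9. Known limitations

* The thin-gap hydrodynamics ignores end-region recirculation details and
  any lateral (width-direction) structure; width enters only through the
  flow-rate conversion. Agreement with a finite-element treatment is
  expected at the level of a few per cent in single-chamber responses, and
  this bias is inherited by the calibrated stand-in coefficients.
* Temperature dependence of $S_T$ is not modelled (coefficients are used at
  the experiment's mean temperature), and reaction rates fitted at 90 °C
  are applied to chambers notionally at 25–45 °C.
* The network model is steady-state only; start-up transients of the
  cascade are out of scope, as are geological realism of fracture geometry,
  3-D embedding and heat-flow-driven pH gradients.
* Enrichment tails (the median-of-ten-maxima at 20 × 20 and beyond) are
  heavy-tailed across topology seeds; quantitative tail statistics should
  always be reported with the ensemble size that produced them.
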