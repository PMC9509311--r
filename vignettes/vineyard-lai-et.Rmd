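---
title: "Methods: vineyard LAI estimation and ET sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vineyard LAI estimation and ET sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vineflux)
options(vineflux.quiet = TRUE)
```

## The problem

Thermal two-source energy-balance (TSEB) models partition vineyard
evapotranspiration (ET) into soil/cover-crop evaporation (E) and vine
transpiration (T) using two biophysical inputs above all others: radiometric
surface temperature and leaf area index (LAI). Satellite LAI over trellised
grapevines is hard: the canopy is strongly clumped, so the same vegetation
index can correspond to wildly different leaf areas depending on trellis
architecture, and most retrieval algorithms assume horizontally homogeneous
canopies. This package implements the full desk-scale chain needed to study
the consequences: an empirical LAI estimator from multispectral reflectance,
a TSEB solver, an LAI-perturbation experiment, and a synthetic scene
generator that reproduces the statistical structure the analysis relies on.

## Vegetation indices and band semantics

Reflectance tables are keyed by sensor-independent semantic names
(`blue ... swir2`, with `red_edge1..3` and `nir_wide` for Sentinel-2-like
data). `compute_vi()` evaluates NDVI, EVI, GCI, NDWI and, when red-edge
bands are present, the red-edge inflection point

$$\mathrm{REIP} = 705 + 35\,
  \frac{(\rho_{665}+\rho_{783})/2 - \rho_{705}}{\rho_{740}-\rho_{705}}
  \;\mathrm{nm}.$$

Two numerical choices: the REIP ratio is clamped to $[-1, 2]$ (wavelengths
stay in $[670, 775]$ nm, the physically interpretable red-edge window) with
denominators below $10^{-6}$ returning `NA`; and every undefined index
propagates as `NA` rather than raising, so one bad sample never aborts a
table. NDWI ships in two conventions: the default `as_printed` form
(SWIR1−Red)/(SWIR1+Red) follows the formulation used in the vineyard
LAI-VI literature this package mirrors, while `nir_swir` gives the
conventional water-index form (NIR−SWIR1)/(NIR+SWIR1); the discrepancy
between the two conventions in that literature is unresolved, so both are
provided and the choice is explicit.

## The rule-based piecewise-linear LAI model

`model_tree()` fits the "rules with linear leaves" structure used for
empirical vineyard LAI models: ordered root-to-leaf paths of single-band
threshold tests that partition feature space, each leaf holding a weighted
least-squares multivariate linear model. Defaults follow the use cases:
`max_rules = 2` for ground-sample-only models (more rules overfit small
ground archives), ~30 for mixed ground + background training;
`min_leaf_n = 20` (as total sample *weight*, so integer weights behave
exactly like duplicated samples).

**Split scoring.** Candidate thresholds are midpoints between sorted unique
feature values. A split is scored by the drop from the leaf's weighted
outcome standard deviation to the pooled residual RMSE of per-side simple
linear fits in the candidate feature. The more common choice — reduction of
the raw outcome SD — was evaluated and rejected as this package's design:
for a *continuous* piecewise-linear signal (e.g. LAI = 2·NIR below a kink
at 0.4 and 5·NIR − 1.2 above it) the outcome-SD optimum sits well away from
the kink (near 0.49 for that example), because outcome spread is minimized
by balancing value ranges, not by isolating linear regimes. Scoring
residuals around side-wise lines recovers the breakpoint exactly, which is
the behaviour a model tree with linear leaves should have. Ties break to
the lowest-indexed feature, then the lowest threshold, making fits
deterministic. Growth is best-first under the global leaf budget.

**Leaf models.** Each leaf's weighted OLS model undergoes backward feature
elimination: a band is dropped when the reduced model's training RMSE stays
within 1% of the *full* model's RMSE (using the full-model RMSE as the
fixed budget keeps training error monotone in `max_rules`). Rank-deficient
bands get zero coefficients. Negative LAI predictions are clamped to zero
with a flag, since LAI is non-negative.

**Hybrid weighting.** When $n_g$ ground samples are pooled with $n_b$
background samples and the ground-sampled land cover occupies a fraction
$f$ of the domain, `hybrid_weights()` sets
$w_g = fN/n_g$, $w_b = (1-f)N/n_b$ with $N = n_g + n_b$, so the ground
group's share of total weight is exactly $f$.

## Validation harnesses

`regression_metrics()` reports RMSE, MAE, bias (mean of predicted minus
observed), MAPE, Pearson $r$ and $R^2 = 1 - SS_{res}/SS_{tot}$ (negative
when a model is worse than the observed mean). MAPE excludes observations
at or below 0.05 LAI — percentage error against a near-zero canopy is
meaningless — and reports the excluded count.

`cv_kfold()` runs repeated k-fold cross-validation: each repetition
reshuffles (seeded, repetition $i$ uses `seed + i - 1`), pools held-out
predictions within the repetition, and the final report averages the pooled
metrics across repetitions. Defaults (k = 5; 20 or 200 repetitions for the
two standard table layouts) are conventions, not statistics: the original
"repeat until RMSE stabilizes" stopping rule is not reconstructible from
its description, so repetition counts are explicit configuration.
`cv_leave_site_out()` holds out one vineyard at a time — the test of
spatial generalization, which fails informatively when sites have different
clumping.

## The TSEB-PT solver

`solve_tseb_pt()` implements the series-network Priestley–Taylor TSEB for
one timestep. The configuration choices that the generic model family
leaves open are fixed as follows:

* **Network**: series (canopy and soil coupled through an in-canopy air
  node), the standard choice for row crops.
* **Radiation**: shortwave split by Beer's-law interception
  $1 - \exp(-K_s\,\Omega\,\mathrm{LAI}/\cos\theta_s)$ with $K_s = 0.6$,
  component albedos 0.20 (canopy) and 0.25 (soil); longwave by a
  single-layer exchange with canopy transmittance
  $\exp(-K_L\,\Omega\,\mathrm{LAI})$, $K_L = 0.95$, emissivities 0.99
  (canopy) and 0.94 (soil/cover crop), reflected longwave neglected.
  The clumping index $\Omega$ scales LAI everywhere leaf area enters, as
  trellised canopies demand. The soil albedo is the textbook dry-bare-soil
  value: the stated world is the dry interrow of an irrigated California
  vineyard in summer (a moist dark-soil value like 0.15 would be wrong for
  that surface).
* **Resistances**: log-profile $r_a$ with $z_{0m} = 0.125\,h_c$,
  $d = 0.65\,h_c$ and Dyer–Businger stability corrections iterated with the
  fluxes, $|z/L|$ capped at 2; leaf boundary-layer
  $r_x = (90/\mathrm{LAI})\sqrt{w_\ell/u_{d+z0m}}$ with an exponential
  in-canopy wind profile; soil surface $r_s = 1/(0.004 + 0.012\,u_s)$.
* **Iteration**: canopy latent heat starts at
  $\alpha_{PT}\,f_g\,[\Delta/(\Delta+\gamma)]\,R_{n,c}$ with
  $\alpha_{PT} = 1.26$; canopy temperature follows from canopy sensible
  heat; soil temperature from the radiometric decomposition
  $T_{rad}^4 = f\,T_c^4 + (1-f)\,T_s^4$ at nadir view (the hemispherical
  radiometric temperature is treated as nadir-equivalent — an explicit
  simplification); soil latent heat is the residual $R_{n,s} - G - H_s$
  with $G = 0.35\,R_{n,s}$. If soil evaporation is negative, the canopy is
  deemed stressed: $\alpha_{PT}$ is reduced in steps of 0.05 and the
  solution recomputed; at $\alpha_{PT} = 0$ soil evaporation is forced to
  zero and soil sensible heat closes the budget. The stepwise decrement is
  deterministic and mirrors the "iteratively reduce transpiration"
  mechanism, at the cost of small flux discontinuities (one step moves
  hourly fluxes by up to ~20 W/m², ~0.02 mm/day) at stress onset.
* **Constants**: $\lambda = 2.45$ MJ/kg fixed (temperature dependence is a
  <2% effect); daytime is `sw_in > 25` W/m²; green fraction $f_g = 1$ by
  default (configurable).

Energy closes exactly at every timestep by construction
($R_n - G = H + LE$ to machine precision), soil evaporation is
non-negative at convergence, and recomposing $f\,T_c^4 + (1-f)\,T_s^4$
returns $T_{rad}^4$ to float precision — these are tested invariants, not
aspirations.

`lst_from_longwave()` derives the radiometric temperature the solver
consumes from upwelling and incoming longwave via the cover-weighted
composite emissivity, and `residual_closure_correction()` applies the
standard residual closure ($LE = R_n - G - H$) used to make
eddy-covariance reference fluxes comparable.

## The LAI-perturbation experiment

`run_lai_sensitivity()` perturbs each scenario's LAI by ±5…±50% (zero
excluded; the baseline runs through the identical code path so shared
numerical error cancels). The perturbation propagates to everything LAI
controls inside the model — cover, interception, resistances — and to
nothing else; in particular the radiometric forcing stays at its baseline,
which is precisely the experiment's premise ("the map is wrong, the world
is not"). ET and T changes are baseline-relative percentages; E, which
approaches zero under dense canopies, uses the symmetric relative change
$100\,(x - b)/((x + b)/2)$, bounded by ±200%. `summarize_box()` uses
linear-interpolation quartiles (R type 7) and 1.5·IQR whiskers so the
boxplot summaries are exactly reproducible.

## The synthetic world

The generator emulates four features of the real analysis setting:

1. **Clumping contrast.** Three site archetypes with $\Omega$ = 0.85
   (BAR-like), 0.65 (SLM-like), 0.45 (RIP-like) and per-site endmember
   spectra (dark coastal → bright hot-interior). Reflectance is linear
   endmember mixing with band-specific extinction
   $f_b = 1 - \exp(-k_b\,\Omega\,\mathrm{LAI})$; red-edge extinctions sit
   between red and NIR so REIP shifts with LAI while NDVI saturates in
   clumped canopies. The $\Omega$ values and soil-red endmembers were
   calibrated once, before any test existed, so that the median true LAI of
   samples with NDVI in [0.60, 0.65] lands near the anchors 1.3 / 1.7 / 3.4
   for the three archetypes — tuning constants, not physical claims — and
   were not revisited. Per-site endmembers also make the band-vector → LAI
   mapping identifiable (sites are spectrally distinctive), which a shared
   endmember set would not be.
2. **Noisy ground samples and saturating background.** Ground samples carry
   Gaussian reflectance noise (sd 0.01); background samples emulate a
   coarse-resolution mixed-land-cover pool whose reported LAI saturates at
   4 (`reported = min(true, 4) + noise`).
3. **Diurnal forcing.** Clear-sky half-sine shortwave (06–18 h), lagged
   sinusoidal air temperature, Brutsaert clear-sky incoming longwave, and a
   radiometric temperature built as
   $T_{rad} = T_{air} + (a_0 + a_1 s)\,(SW/SW_{peak})\,(1 - 0.5 f_c)$ with
   stress knob $s = 0.3$, $a_0 = 2$ K, $a_1 = 8$ K and 0.3 K noise, so
   radiometric heating scales with bare-soil exposure. Climate presets
   (mild coastal / moderate / hot interior; peak shortwave 850–950 W/m²,
   mean air temperature 291–299 K, wind 2.2–3.0 m/s) are realistic
   stand-ins — no tower data are embedded.
4. **The 14-scenario ensemble.** One scenario per intensive-observation
   period, with the published measured LAI (0.51 to 3.86) as baseline and
   site-appropriate clumping, height and climate.

**What a green test does and does not establish.** The generator reproduces
the *structure* of the problem — clumping-driven VI ambiguity, retrieval
saturation, site-specific spectra, energy-limited vs stress-limited flux
regimes — so green tests establish that the estimator, solver and
experiment behave correctly in that world. They do not establish agreement
with any particular tower: the synthetic midday radiometric contrast
(≤ ~4 K above air temperature under the default stress knob) is mild
compared with real vineyard interrows, whose surfaces run tens of kelvin
hot. Consequences, all computed by the package's own tests and acceptance
script: LAI *under*estimation behaves as reported over real vineyards
(daily ET deviates by under ~10% at −50% LAI while transpiration drops by
roughly a third — compensation through soil evaporation); the dense-canopy
rise-then-fall response of T and ET to an LAI sweep appears; but the strong
transpiration down-regulation under *over*estimated LAI that hot interrow
surfaces induce is only marginally expressed, so the default world shows a
weaker positive-bias ET response than field-forced analyses report, and the
corresponding acceptance checks fail honestly rather than being tuned to
pass. Raising the stress knob `s` toward 1 strengthens that mechanism;
the default is kept at its stated value.

## Numerical conventions, in one place

* REIP ratio clamp $[-1, 2]$; degenerate-denominator tolerance $10^{-6}$.
* MAPE exclusion threshold 0.05 LAI.
* Negative LAI predictions clamped to 0, flagged.
* Leaf backward-elimination budget: 1% of full-model RMSE.
* Solver convergence: 0.01 K on component temperatures, ≤ 200 total
  iterations, non-convergence returned as a flagged state, never an error.
* Radiometric decomposition cover capped at 0.995 to keep the quartic
  inversion finite; an infeasible decomposition (implied negative soil
  emission) pins the soil cool and re-derives the canopy temperature from
  the decomposition, preserving radiometric consistency.
* Monin–Obukhov stability: $|z/L| \le 2$; wind floored at 0.1 m/s.
* Quartiles: linear interpolation (R type 7); whiskers 1.5·IQR.
* Every stochastic function takes an explicit seed; ensemble scenarios use
  deterministic per-scenario sub-seeds.

## Limitations

No atmospheric correction, fusion, or physical (radiative-transfer)
retrieval is included; the three-archetype clumping model is a coarse
abstraction of trellis geometry; row orientation and dual-vegetation
(vine + cover crop) energy balance variants are out of scope; and the
synthetic forcing cannot substitute for tower measurements where absolute
accuracy matters. The stepwise stress decrement makes component fluxes
piecewise-continuous in LAI with jumps of about one decrement step; use a
smaller step than 0.05 if smooth response curves matter more than fidelity
to the stepwise description.
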