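---
title: "Modelling trace-metal transfer from soil to wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trace-metal transfer from soil to wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`soilwheat` simulates how trace metals (Cu, Pb, Cd, Ni) move from soil and
near-surface atmosphere into a growing wheat plant, tracked in four
compartments: root, stem, leaf and grain.

**Growth.** Each compartment's mass follows a closed-form logistic curve

$$M_i(t) = \frac{M_{i,\max}}{1 + \frac{M_{i,\max}-M_{i,0}}{M_{i,0}}
  \, e^{-G_i (t - t_{0,i})}}$$

with initial mass $M_{i,0}$ (kg), maximal mass $M_{i,\max}$ (kg), growth
coefficient $G_i$ (1/d) and an emergence day $t_{0,i}$ at which the
compartment starts to exist (mass 0 before). Root, stem and leaf emerge at
sowing; the grain emerges at day 50 by default. The logistic law has no
emergence term of its own, so the per-part offset restarts the logistic
clock at emergence — the minimal change that lets one closed form describe
all four compartments. Metal toxicity feedback on growth, phenology,
temperature and water stress are deliberately outside the model.

**Transport fluxes.** Xylem (upward) volumetric flux is modelled as
proportional to compartment mass, $Q^{up}_i(t) = q_{up,i} M_i(t)$ with
$q_{up,i}$ in L/(kg d), and phloem (downward) flux as a fixed fraction
$\phi_i < 1$ of it. The proportionality is a modelling choice — the sap-flow
literature supplies magnitudes, not a formula — and it is the simplest
scheme that keeps fluxes monotone with mass, keeps phloem below xylem
everywhere, and makes the inter-part transfer rates
$r_{i \to j} = Q_j / (K_{iw} M_j)$ constant once both compartments exist
(the receiving mass cancels). The coefficients are exposed in the `flux`
config block and echoed in every result's assumption log.

**Uptake and transfer rates.** Three elementary rate families drive the
model:

* soil to root: $r_{S\to R} = (Q + A_R f_c D_R) / (M_S K_{SW})$, additive in
  the transpiration-pull (advection) and diffusion pathways;
* between parts: $r_{i\to j} = Q_j / (K_{iw} M_j)$, where down-up edges use
  the receiving part's xylem flux and up-down edges its phloem flux;
* atmosphere to leaf/grain: $r_{A\to i} = A_i P_i (1-f_P) + A_i v_{dep} f_P$,
  additive in cuticular permeation (metabolic) and particle deposition
  (non-metabolic).

Serial pathways (e.g. soil → root → stem → leaf) are composed
multiplicatively: the first stage keeps its native units and each later
stage enters as a dimensionless efficiency $r \tau$ with a reference time
$\tau$ (default 1 d, configurable). The source material lists the chains
without an explicit operator; multiplication with a $\tau$
non-dimensionalisation preserves the serial semantics, keeps each composed
rate monotone in every stage, and makes the one-stage chain the identity.
Per-part loss rates are the sums of outgoing elementary edges
($k_R = r_{R\to St}$; $k_{St} = r_{St\to L} + r_{St\to G} + r_{St\to R}$;
$k_L = r_{L\to St}$; $k_G = 0$ — nothing leaves the grain).

**Accumulation.** Tissue concentration $C_i$ (mg/kg) obeys

$$\frac{dC_i}{dt} = \frac{r_{S\to i}\,(C_S + C_t)\,W_i + r_{A\to i}\,C_A}
  {M_i(t)} - k_i\, C_i$$

with water-soluble plus exchangeable soil concentrations $C_S + C_t$ (mg/L),
tissue water content $W_i$ (L/kg) and atmospheric concentration $C_A$
(mg/m³). The equation is applied verbatim: the loss term is not re-injected
into the receiving compartment (no inter-part mass balance beyond the
composed chains), the soil pool is constant over a season, and the printed
form is not dimensionally closed once the composed rates are substituted —
partition coefficients and the soil mass therefore act partly as effective
constants, which is why the shipped configuration labels them placeholders.
The equation is linear in $(C_S, C_t, C_A)$; several tests and the Monte
Carlo engine rely on that exactly.

## Numerical choices

* **Integrator:** fixed-step classical RK4 (default `dt` = 0.5 d over 0–160
  d), with forward Euler retained for cross-checks. The system is linear
  with smoothly varying coefficients; the only stiffness is a startup
  boundary layer where loss rates (~2/d in the calibrated setting) are
  comparable to 1/dt, which affects only the first few days of the
  trajectory.
* **Emergence handling:** integration is segmented at each emergence day
  with an explicit per-segment activity mask. Without the mask, the RK4
  stage landing exactly on the grain's emergence day inside the *preceding*
  step injects an O(dt) spurious mass of metal which, because the grain has
  no loss term, persists to harvest. With segmentation the scheme shows
  clean fourth-order convergence; successive step halvings at dt = 0.125 d
  agree to better than 1e-4 relative at every output point.
* **Instability policy:** non-finite trajectories trigger up to three
  step-halvings before failing with a diagnostic.
* **Steady state:** for compartments with $k_i > 0$ the plateau fixed point
  $C_i^* = [r_{S\to i}(C_S{+}C_t)W_i + r_{A\to i}C_A]/(M_{i,\max} k_i)$ is
  available in closed form; the grain diverges under constant sources
  ($k_G = 0$) and is flagged rather than reported.
* **Variogram fitting:** weighted least squares (pair counts as weights)
  via Nelder-Mead on log-transformed nugget/partial-sill and a
  sigmoid-bounded range (at most 3× the largest empirical lag — beyond that
  the parameters are not identifiable from the curve and the fit surface
  degenerates). Non-convergence falls back to an exponential model with
  moment-based starts, flagged on the returned object.
* **Kriging:** the ordinary-kriging system in semivariance form with the
  unbiasedness (Lagrange) constraint, solved densely; predictions are exact
  at sample sites when the nugget is zero and weights sum to one to 1e-10.
  Duplicate coordinates are rejected outright rather than jittered.
* **Error classes:** relative prediction errors bin into half-open intervals
  [0, 0.25), [0.25, 0.5), [0.5, ∞) — a ratio of exactly 0.25 is "25–50%",
  exactly 0.5 is ">50%".
* **Lognormal gate:** soil concentrations are fitted on the log scale and
  gated by a Kolmogorov-Smirnov test against the fitted normal with
  estimated parameters, without a Lilliefors correction — this mirrors the
  field workflow the package reproduces; the uncorrected p-value is
  conservative (rejects too rarely), which only makes the gate permissive.
* **Monte Carlo:** only the soil total varies; the soluble and exchangeable
  fractions scale proportionally (preserving the reference fraction
  ratios), and everything else is fixed. Because the accumulation equation
  is linear in the sources, the default engine computes two basis
  simulations and scales them per draw — identical to the literal
  per-replicate loop (retained as `method = "direct"` and asserted equal in
  tests) at a tiny fraction of the cost.

## Agreement statistics and bioconcentration factors

Model-measurement agreement uses root-mean-square values
($X_{rms} = \sqrt{\tfrac1N \sum X_i^2}$), the value difference rate
$V_{DR} = |X_{rms,mod} - X_{rms,mea}| / X_{rms,mea}$, the coefficient of
variation $CV = STD / mean$ (sample SD by default — field-sample usage; the
population variant is a flag) and the fluctuation difference rate
$F_{DR} = |CV_{mod} - CV_{mea}| / CV_{mea}$. Statistics are computed per
metal × part over sites, then averaged over parts within each metal, then
over metals with equal weights.

Bioconcentration factors are $BCF_{sw} = C_{wheat}/C_{soil}$ and
$BCF_{sg} = C_{grain}/C_{soil}$. The whole-plant concentration is defined
as the **sum** of the four part concentrations: of the candidate readings
of $C_{wheat}$, only the sum reproduces all eight conventionally reported
factor values from the corresponding per-part means at two-decimal
rounding (the mean of parts does not), and the test suite carries that
arithmetic check for all four metals.

## The synthetic survey generator

`generate_soil_field()` emulates the shape of the study design the package
targets: 52 sites scattered uniformly over a rectangular extent, of which
32 carry mature-wheat tissue measurements. Log soil concentrations are a
Gaussian-process draw with exponential covariance (log-SD 0.4–0.5,
correlation range 800 m by default — mid-range field heterogeneity over a
~5 km extent), exponentiated to strictly positive totals; soluble and
exchangeable fractions default to 5% and 10% of the total with a
configurable soil-solution conversion ratio (default 1 L/kg, since no
conversion is prescribed by the workflow being emulated).
`generate_measurements()` runs the calibrated simulator at each mature
site and multiplies by unit-mean lognormal noise (CV 0.3 by default,
a typical field-plus-analytical error scale).

What this does *not* emulate: real landscapes (land use, hotspots around
point sources), censoring or detection limits, correlated multi-metal
contamination, inter-site agronomic variability, or model misspecification
— synthetic measurements are generated by the same model that is later fit,
so passing round-trip tests demonstrates internal consistency of the
pipeline, not predictive accuracy on real surveys.

## The shipped configuration is a placeholder

Growth parameters and total soil concentrations are survey-scale values;
everything else (partition coefficients, geometry, fluxes, atmospheric
parameters, soil mass) is a documented placeholder chosen **once** so that
the simulated tissue concentrations reproduce the qualitative ordering
root > leaf > stem, grain for all four metals, with the whole-plant factors
largest for Cd/Cu and grain transfer weakest for Pb/Ni. Per-part reported
mean concentrations are *not* a calibration target: they depend on
unpublished site measurements and unprinted literature parameter values.
Every parameter carries a `source` tag and the loader lists all
placeholders at load time.

Known wrinkles, kept deliberately: the root growth coefficient 0.0075 1/d
implies a logistic inflection near day 613 — far beyond the season — so
root mass is still far from its maximum at harvest; the value is used as
given and exposed in the config rather than silently corrected. Grain
uptake integrates against a near-zero initial mass (5.6e-6 kg), so final
grain concentrations are sensitive to the grain flux coefficient, which is
correspondingly small in the placeholder set.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use the season grid
(0–160 d at 0.5 d), a 3000 d horizon for fixed-point convergence, n = 5000
samples for lognormal parameter recovery, 10,000-replicate ensembles for
distribution-preservation checks, 30–300 sites for variogram/kriging
recovery, and the 52-site / 32-mature survey shape for the end-to-end
pipeline regression. These sizes were chosen to keep Monte Carlo error
comfortably below the asserted tolerances.

## Worked example

```r
library(soilwheat)

cfg <- load_config(default_config_path())
inp <- config_inputs(cfg, "Cu")
res <- simulate_accumulation(inp$env, inp$geom, inp$rt, inp$atm,
                             inp$growth, inp$cfg, inp$flux)
res$final                       # mg/kg at harvest per part
bcf(res$final, inp$env$c_total) # whole-plant and grain factors

# synthetic survey -> noisy measurements -> agreement statistics
tab <- generate_soil_field(synthetic_field_spec(seed = 7))
tab <- generate_measurements(tab, cfg, noise_cv = 0.3, seed = 7)
```

## Limitations

* No speciation or pH/SOM/CEC dependence of partitioning; no
  soil-depletion or multi-season carryover; no toxicity feedback.
* The composed-rate dimensional ambiguity means absolute concentrations are
  only as meaningful as the (placeholder) calibration behind them.
* Kriging assumes planar metric coordinates, isotropy and a single
  variogram per variable; no co-kriging.
* Default validation extracts predictions at the sampled sites
  (leave-nothing-out), matching the emulated workflow; honest error rates
  need the provided leave-one-out option.
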