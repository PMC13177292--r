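---
title: "Modelling on-column enantiomerization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling on-column enantiomerization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynchrom)
```

This vignette records how the models in `dynchrom` are put together,
which numerical choices were open and how they were settled, and what
the synthetic-data suite can and cannot demonstrate about real
chromatograms.

## The physical picture

A stereolabile analyte on a chiral column is a two-state continuous
process: a molecule spends its run partly as the first-eluting
enantiomer A, partly as B, switching with first-order rates. Molecules
that never switch form the two outer peaks; molecules that switch
produce intermediate retention and build the plateau of the "Batman"
profile. Two complementary descriptions are implemented.

**Unified equation.** A closed-form expression maps the descriptor set
of a Batman chromatogram — plate number `N`, retention times `tA`,
`tB`, Gaussian SDs `sA`, `sB`, the plateau height `hp` and the injected
fraction `A0` — to the apparent forward rate constant; the reverse rate
follows from `k_r = k_f (A∞/B∞)(tA/tB)`. All logarithms are natural. The
"100" constants inside the expression presuppose heights normalised so
the taller retained peak reads 100; `estimate_peak_params()` enforces
that scale, and reads `hp` from the raw signal at the smoothed
(local-quadratic, window 2% of points) location of the inter-apex
minimum. Half-widths are measured on the **outer** flanks and doubled:
the inner flanks drown in the plateau once `hp` exceeds 50. In
controlled experiments with exact descriptors the closed form tracks
the true rate to a few percent while `hp` stays below about 35 (on the
0–100 scale) and degrades beyond; the pooling stage therefore uses it
only in that domain (`ue_hp_max` argument, default 35).

**Stochastic model.** Retention is a compound Poisson process: `n`
expected adsorption events, exponential sojourns of mean `τ` (two site
classes with visitation fractions `p1`, `p2` in the two-site variant).
Its characteristic function is analytic, so a peak profile is one
inverse FFT. Interconversion enters through the Keller–Giddings
densities over `x`, the fraction of the run spent as A. As implemented,

* `P_AA(x) = e^{−ax−b(1−x)} √(abx/(1−x)) I₁(2√(abx(1−x)))`,
* `P_AB(x) = a e^{−ax−b(1−x)} I₀(2√(abx(1−x)))`,
* a point mass `e^{−a}` at `x = 1` for molecules that never convert,

with the start-in-B forms obtained by swapping `a↔b`, `x↔1−x`. This
orientation (exponent pairing `a` with `x`) is the one that satisfies
the probability balance `e^{−a} + ∫P_AA + ∫P_AB = 1` exactly, which the
test suite checks to 1e−8; note that the density is *not* symmetric in
`x` at `a = b` — the symmetry is the mirror identity between the two
start states. Bessel factors are evaluated exponentially scaled and
recombined in log space, so counts in the hundreds pose no overflow
problem.

A Batman profile is the mixture of the two unconverted profiles
(handled analytically, never discretised as spikes) and converted
contributions whose model parameters are blended linearly in `x`
between the A and B parameter sets — the package's documented
interpretation of "fraction of time spent as A"; sojourn budgets
(`n·τ` products) interpolate linearly. The mixture is assembled in the
frequency domain (one FFT total).

## Numerical choices

* **FFT grid.** Power-of-two length (default 4096 for analysis, 2048
  for generated data), span at least `tM + 8·(mean + 4·SD)`; a
  boundary-mass check (> 1e−4 of the area in the last 2% of the grid)
  raises an aliasing error rather than wrapping silently.
* **Quadrature over `x`.** The return density carries integrable
  `1/√(1−x)` endpoint singularities, which plain Gauss–Legendre
  resolves poorly. All mixtures therefore integrate under the
  substitution `x = (1 − cos πu)/2`, whose Jacobian cancels the
  singularity; 24–64 nodes then hold the mixture mass to machine
  precision. An optional node-doubling check (`check_quadrature`)
  guards unusual parameter corners.
* **Monte-Carlo cross-check.** `simulate_batman_mc()` samples the same
  model by direct event simulation (exponential switching over the
  run, Poisson adsorption counts, gamma sojourn sums) without Fourier
  transforms, Bessel functions or quadrature; agreement is measured as
  a Kolmogorov–Smirnov distance (below 0.01 at 10⁵ molecules across
  slow, intermediate and fast exchange).

## Fitting protocol

The per-run fit is deliberately staged:

1. **Descriptors and warm start.** Measured geometry gives `(n, τA,
   τB)` by moment inversion; the unified equation seeds `(a, b)`. For
   coalesced runs, where apices are unmeasurable, a candidate scan
   over exchange intensities `a = b ∈ {0.25 … 32}` places the geometry
   by matching the profile's first two moments through the mixture's
   `x`-distribution, and the best few candidates are pre-polished.
2. **Smoothed global stage.** The exact objective is razor-sharp in
   the peak positions (basins about one peak SD wide), so differential
   evolution runs on a Gaussian-smoothed pair: the data convolved once
   with a kernel of SD `0.3·√(profile variance)`, the model broadened
   for free through its dispersion term. DE uses population 8×dim,
   at most 40–60 generations with early stopping after 12 stagnant
   generations, half the population seeded around the warm start. The
   heavier settings sometimes quoted for global stages buy nothing
   here because the scan already lands in the right basin; the chosen
   budget keeps a 60-run suite to a few minutes.
3. **Local stage.** Box-constrained Levenberg–Marquardt
   (`minpack.lm::nls.lm`) in log coordinates (logit within the ±1
   window around the isotherm-derived prior for `p2`), first on the
   smoothed objective, then on the raw one; the box constraints are
   structural, not penalties. Convergence means the LM relative-SSE or
   gradient criterion fired (`info` codes 1–4).

Per-run standard errors come from the LM Jacobian (`σ²(JᵀJ)⁻¹`),
delta-transformed to the natural scale.

## Isotherm stage

Overload profiles follow the equilibrium-dispersive model with
competitive bi-Langmuir equilibrium, first-order upwind advection and
central dispersion over 100–200 cells (the ED idealisation tolerates
modest numerical dispersion folded into `Dax = uL/2N`), Danckwerts
inlet (purely advective feed flux) and zero-gradient outlet,
stiff-capable integration by `deSolve::lsoda`. Interconversion is
neglected during overload — the series is assumed recorded at the
lowest temperature, where exchange is minimal. Profiles count as
overloaded when the 10%-height asymmetry factor exceeds 1.5 or the
retention shifts by more than 2% against the smallest injection;
non-overloaded profiles are excluded from the global fit (and the fit
refuses to run on none). Both enantiomers share the selective-site
capacity; the independent-capacity variant adds correlation without
improving fits. The fitted ratio `ρ = Qs/Qns` feeds the two-site prior
through `p2/(1−p2) = ρ·bs/bns` — capacity sets abundance, affinity
sets visitation odds; the affinity ratio defaults to one when unknown.

## Decomposition and thermodynamics

Apparent rates mix the phases through the capacity factor
(`k_fact = (tR − tM)/tM`, per enantiomer):
`k_obs = k_mob/(1+k_fact) + k_stat·k_fact/(1+k_fact)`. Multiplying by
`(1+k_fact)` linearises this, and the transformed rates are modelled
with `lme4::lmer` (REML): fixed intercept (mobile basis), fixed
`k_fact` slope and a direction contrast, random intercepts per
eluent×temperature, random slopes per column×temperature,
heteroskedastic weights `1/((1+k_fact)²·se²)` normalised to mean one.
A singular variance component is dropped with a warning. Conditional
(empirical-Bayes) variances from `ranef(condVar = TRUE)` enter the
cell-level SEs; negative extracted rates are flagged, never truncated.
Weighted Eyring–Polányi fits use weights `1/SE(ln k)²`; with stated
SEs the fixed-effect (absolute-weight) convention applies, otherwise
the scale comes from the residuals. Gibbs energies at the reference
temperature use the full enthalpy–entropy covariance — the strong
negative correlation largely cancels there, which is why `ΔG‡` is far
better determined than either component.

## Empirical-Bayes stage

The global model approximates every run's enantiomer peaks as
Gaussians at the run's moments, convolves them with the
interconversion densities, and ties all runs together through
Eyring-linearised phase rates referenced to the median temperature of
the supplied runs. Priors come from the mixed-model stage (SEs
inflated twofold, widths capped to stay proper); the posterior mode is
found by BFGS from the prior mean (plus optional jittered restarts)
and uncertainties by a central-difference Laplace approximation with a
positive-definiteness check. Moments for runs too coalesced to measure
are interpolated along the family's van't Hoff retention trend with
plate-number widths — this is what lets the global stage use the
strongly exchanged, information-rich part of the design.

**A candid limitation.** On synthetic designs the EB point estimates
of the mobile-phase enthalpies scatter *less* around the truth than
the mixed-model ones (the shrinkage works), but they carry a residual
systematic error of a few kJ/mol from the Gaussian-peak approximation,
while the Laplace SEs — which see only measurement noise — are tenths
of kJ/mol. Curvature-based uncertainties under model misspecification
are overconfident; `ΔG‡` at the reference temperature is far more
robust than `ΔH‡`. The test suite records this gap explicitly rather
than widening any tolerance.

## CD validation

Off-column racemization is fitted as `θ(t) = θ₀ e^{−k(t+delay)}` with
the acquisition delay supplied or co-estimated within [0, 120] s;
`θ₀` always refers to true time zero, so a mis-specified fixed delay
biases the amplitude by `e^{kΔ}` but never the rate. The fitted decay
rate is the racemization rate; division by two gives the
unidirectional enantiomerization rate that matches the
chromatographic convention. The G-factor uses the standard
32 980 mdeg-per-ΔA conversion (exposed as an argument). Equivalence
with the chromatographic mobile-phase rates is declared per
temperature when confidence intervals overlap.

## What the synthetic suite does and does not show

The generator reproduces the study geometry — four cellulose-type
columns, three eluents, seven temperatures (283.15–313.15 K in 5 K
steps), six flow rates (0.5–1.2 mL/min) — with phase-specific Eyring
truths in the 60–90 kJ/mol, −0.08–0.01 kJ/(K mol) range typical of
conformationally stereolabile drugs, capacity factors 0.6–1.8 with
selectivities 1.15–1.45 and mild van't Hoff temperature dependence,
plate numbers scaling as `√(0.5/flow)` from 6000, racemic injections,
and 1% proportional Gaussian noise. Every intermediate (phase rates,
apparent rates, conversion counts, stochastic parameters) is recorded
in a truth table, and recovery tests compare against that table only.

It does **not** emulate instrument drift, detector saturation,
injection-profile asymmetry beyond the EMG marker, temperature
gradients inside the column, or site heterogeneity beyond two classes
— so passing tests demonstrate the statistical machinery, not the
absence of such artefacts in real data. The end-to-end tests run a
desk-scale twin of the design (three of the six flow rates; the
mixed-model and EB stages at 100–120 profile points and 20–24
quadrature nodes per run); these sizes are the package's default
trade-off between resolution and turnaround and are stated here rather
than buried in the tests.

## Known limitations

* The site-capacity ratio `ρ` is only weakly identified from the total
  outlet signal of an analytical injection ladder: the SSE surface is
  nearly flat along compensating `ρ`/`Q_tot`/affinity directions unless
  both site classes are driven deep into saturation. The global fit
  reliably recovers the isotherm function (loadings over the sampled
  concentration range) and the qualitative dominance of the selective
  class; point estimates of `ρ` should be treated as order-of-magnitude
  and, where possible, anchored by frontal-analysis data.

* The unified equation is used strictly inside its small-plateau
  domain; no bias correction is attempted outside it.
* The two-site fit is structurally underdetermined without a site
  ratio prior; `p2` is only ever estimated inside the ±1 logit window
  around the isotherm value.
* Stationary-phase rate constants are intrinsically noisier than
  mobile-phase ones (they are slope, not intercept, quantities); their
  activation parameters should be read with their SEs, not as point
  values.
* The overload stage assumes no interconversion during the overload
  run and identical selective capacities for both enantiomers.
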