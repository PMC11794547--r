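---
title: "Estimating maize shoot phosphorus uptake from canopy spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating maize shoot phosphorus uptake from canopy spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maizeSPU)
```

## The estimation problem

Shoot phosphorus uptake (SPU, kg P/ha) is the amount of phosphorus held in
the aboveground plant: here the sum of leaf, stem and grain pools. Direct
measurement requires destructive sampling and wet chemistry, so the package
estimates SPU from canopy hyperspectral reflectance (350–2500 nm field
spectroradiometer data) collected at three growth stages of summer maize —
jointing, filling and milk — across phosphorus-fertilization treatments.

A single whole-plant regression from one stage's spectrum to SPU is limited
by two physical facts. First, dense maize canopies saturate: beyond a leaf
area index (LAI) of roughly five, near-infrared reflectance barely responds
to further biomass, so the highest-P plots become spectrally
indistinguishable. Second, the organs carry phosphorus in different
proportions and at different times; grain fill in particular is expressed in
the *milk*-stage canopy (stay-green leaf area, dry-matter status), which a
filling-stage spectrum cannot see. The package therefore decomposes SPU
organ-wise:

* **leaf P** = predicted canopy leaf P concentration (LPC, g/kg) × leaf
  biomass (t/ha) retrieved by a hybrid radiative-transfer inversion
  (g/kg × t/ha ≡ kg/ha exactly);
* **stem P** = a degree-2 polynomial link fitted from measured leaf P to
  measured stem P, applied to the predicted leaf P;
* **grain P** = grain biomass predicted from milk-stage spectra × the
  mature-leaf P concentration, substituting for the unobservable grain
  concentration (50–85 % of leaf P and 15–50 % of stem P are re-fixed into
  the developing grain, which makes the mature-leaf concentration a usable
  proxy);
* **SPU** = leaf P + stem P + grain P, exactly additive by construction.

## Band selection by 2D correlation spectroscopy

Generalized two-dimensional correlation spectroscopy (2DCOS) orders the m
spectra by the perturbation variable (the trait, ascending; ties broken by
sample identifier) and forms the synchronous map
Φ(ν₁,ν₂) = Σⱼ ỹⱼ(ν₁)ỹⱼ(ν₂)/(m−1) of the mean-centred dynamic spectra ỹ,
plus the asynchronous map Ψ via the Hilbert–Noda transform
N_{jk} = 1/(π(k−j)). Diagonal maxima of Φ ("autopeaks") mark bands that
respond strongly to the perturbation. The two-trace variant (2T2DCOS)
correlates exactly two spectra — here the filling- and milk-stage spectra of
one plot — with Φ = (a⊗a + b⊗b)/2 and Ψ = (a⊗b − b⊗a)/2.

Numerical choices worth knowing:

* **Derivative enhancement.** Band selection operates on Savitzky–Golay
  first derivatives (window 15, order 2 — a common setting for 1-nm field
  spectra). The filter's start-up transient distorts the first and last
  half-window, so those points are replaced by plain finite differences,
  and grid-boundary bands are never peak candidates (a boundary maximum
  cannot be verified on both sides, and the one-sided derivative there is
  the noisiest on the grid).
* **Autopeak threshold.** Peaks must reach `rel_threshold` of the global
  maximum autopeak (default 0.1) and are merged within 10 nm, the stronger
  peak winning (ties keep the lower wavelength). For *concentration* work
  the threshold should be small (0.02): derivative variance of structural
  NIR/SWIR bands dwarfs the pigment-driven visible bands, and a 10 %
  global threshold would discard the visible autopeaks that carry the
  concentration signal.
* **Support tolerance.** The filling–milk 2T2DCOS consensus (strictly more
  than half of the pairs) counts support within ±3 nm, because sensor
  noise moves a derivative extremum by a few grid steps between physically
  distinct samples — without the tolerance, genuinely shared features are
  scattered across neighbouring bands and no majority forms. The
  repeated-subsampling stability protocol (≥ 8 of 10 draws) instead counts
  exact positions: its draws resample the *same* measured dataset, so
  genuine peaks reproduce on the grid, and exact counting keeps the
  pure-noise null clean (random variance peaks fail to reach consensus
  once the subsample fraction is small enough that draws are nearly
  independent).
* Subsampling for the stability protocol is stratified by trait quantile
  bins so each draw tracks the full trait distribution.

## The canopy radiative-transfer forward model

Canopy reflectance is simulated by a PROSPECT-5B-style generalized plate
model (five absorbers: chlorophyll a+b, total carotenoids, brown pigment,
water, dry matter; N stacked elementary layers solved with the Stokes
system) coupled to the 4SAIL four-stream turbid-medium canopy model with a
Campbell ellipsoidal leaf-angle distribution, a hot-spot-corrected
single-scattering term, and a Lambertian soil mixed from dry/wet end
members by the brightness scalar `psoil`. Geometry defaults to a 30° solar
zenith, nadir view, 0° relative azimuth.

The specific absorption coefficients and refractive index are *synthetic*:
smooth Gaussian emulations of the known absorption features (chlorophyll at
430/670 nm with a broad in-vivo base, carotenoids below 550 nm, water at
970/1200/1450/1790/1940/2270 nm, dry matter at 1720/2100/2300 nm),
generated in code (`R/leaf-constants-synthetic.R`). Spectra are therefore
realistic in shape and dynamics but not instrument-calibrated; every claim
the package tests is relative to this forward model, which is also the
generator of all synthetic data, so the inversion problem is well posed.

Verification: the 4SAIL closed-form four-flux factors are checked against
an independent numerical integration of the same two-stream boundary-value
system (deSolve, shooting method) to 10⁻⁶, the hot-spot quadrature against
adaptive numerical integration, and the LAI→0 limit against the soil
spectrum exactly.

Because the forward fit is poorest at 400–615 nm and 765–990 nm, hybrid
modeling is restricted to 615–765 nm and 990–2500 nm (1662 bands).

## Sensitivity screening and calibration

EFAST (extended Fourier amplitude sensitivity test) estimates first-order
and total variance-based indices per parameter, per spectral region
(visible 400–700, NIR 700–1300, SWIR 1300–2500 nm; scalar output = mean
region reflectance). Implementation notes: the driver parameter takes the
frequency ⌊(Ns−1)/(2M)⌋ with M = 4 harmonics; complementary parameters get
frequencies spread over 1…⌊ω_max/(2M)⌋ (poor spreading of the complementary
frequencies visibly biases the indices); each curve uses a seeded random
phase. A parameter is "free" if any region's index exceeds 0.1; the dry
matter content Cm is always kept free because it carries the biomass
response even though its spectral sensitivity is modest. Remaining fixed
parameters can be calibrated to the measured mean spectrum by the
sine–cosine chaotic sparrow hybrid, minimizing reflectance RMSE over the
modeling windows.

## Metaheuristics

Two population optimizers are implemented with greedy selection (so the
best-so-far history is non-increasing), bound clamping, and full
determinism under a seed:

* **NRBO** — a Newton–Raphson-based optimizer: each member takes a
  quasi-Newton step whose curvature is estimated from the population's best
  and worst members, plus a trap-avoidance move applied with probability
  0.6 and a step-shrink schedule δ = (1 − 2t/T)⁵. Details the published
  description leaves open (candidate weighting, trap constants) are fixed
  in code comments. With archiving on, all pop×(iters+1) evaluations are
  returned — the active-learning candidate pool is exactly such an archive.
* **SCA–SSA** — a sparrow search with logistic-map chaotic initialization,
  sine–cosine producer updates, Mantegna Lévy-flight (β = 1.5) scrounger
  perturbations and an alarm stage.

Both reliably reach 10⁻³ on a 5-D sphere with population 30 and 200
iterations; that budget is the package default.

## The NRBO-AL hybrid inversion

The hybrid leaf-biomass branch addresses the ill-posedness of look-up-table
inversion (different parameter combinations yield the same reflectance) by
filtering the simulated pool against measured data:

1. **Representatives.** K (default 20) measured plots are chosen by
   Kennard–Stone max–min distance in spectral space (SPXY and random
   selection are available).
2. **Candidate pool.** NRBO minimizes ‖forward(θ) − centroid‖ over the
   masked bands with archiving; the archive (restarted until the target
   size is reached) is a simulated pool concentrated near the measured
   centroid. Responses are 100·LAI·Cm t/ha (g/cm² × m²/m² → t/ha exactly).
3. **Spectral constraint.** Keep candidates with
   min_m ‖x_t − x_m‖ < ε₁ (strict; Euclidean). ε₁ defaults to the 5th
   percentile of the candidate distances — deliberately tight, mirroring
   selections that keep a few hundred of 10⁵ simulations.
4. **Response constraint.** An ordinary least squares model f from the
   representative spectra (a top-variance band subset keeps it
   identifiable; ridge fallback λ = 10⁻³ for singular designs) must agree
   with the simulated response: |f(x_t) − y_t| < ε₂, default half the
   standard deviation of the representative responses.
5. **Greedy augmentation.** Up to ⌊0.10·N⌋ additional measured samples are
   added one per iteration, each chosen to minimize the validation RMSE of
   the refitted f (the acquisition criterion is the package's
   interpretation of "most valuable"; the filters are re-applied after
   every addition and the loop stops early if no sample helps). The
   representative-set size and the new-sample budget are deliberately two
   distinct configuration fields.
6. **Regression.** An extreme learning machine (random fixed hidden layer,
   least-squares output weights) is fitted to the selected candidates plus
   the selected measured samples. The package default is a
   ridge-regularized (λ = 1), five-network ensemble with 200 hidden units:
   with the tens-of-samples training sets the filters produce, a pure
   Moore–Penrose fit interpolates noise and generalizes erratically. The
   pseudoinverse solution (λ = 0) remains the `fitRegressor("ELM", ...)`
   default and retains the exact-interpolation property when hidden units
   reach the sample count.

## Regressors, indices and metrics

`fitRegressor()` wraps SVR (e1071), gradient boosting (xgboost),
a 16-unit back-propagation network (nnet), random forest (ranger, impurity
importance), the ELM, single-feature polynomials, and a "committee"
(GBRT + SVR + RF average) used where a single learner is erratic on
tens of samples — the grain-biomass model defaults to it. The
concentration models default to a shallow, strongly regularized boosting
configuration (depth 2, learning rate 0.03, 800 rounds, 70 % subsampling).
Dual-band indices use the field's three forms (DSI difference, RSI ratio,
NDSI normalized difference), the longer wavelength first for the symmetric
forms; ranking keeps the 10 most positive and 10 most negative Pearson
correlations. Metrics follow the standard definitions; RPD uses the sample
(n−1) standard deviation of the evaluation set, the chemometrics
convention.

## What the synthetic campaign emulates

`generateCampaign()` reproduces the study design: seven P treatments
(90/65/45/32.5/9/9/9 kg P₂O₅/ha, plus 10 kg/ha residual soil P) × four
replicate plots × three stages. Traits respond to P through a saturating
curve (half-saturation 45 kg/ha); LAI peaks at 8.5 under saturation —
deliberately inside the spectral-saturation regime of dense maize. LPC
spans 1.4–3.6 g/kg and drives chlorophyll (≈ 22–24 µg/cm² per g/kg,
declining to 17 at milk as senescence sets in). Stage multipliers raise LAI
and dry matter from jointing to filling; milk-stage LAI carries 14 %
stay-green variability (jointing 5 %, filling 4 %), which decouples the
milk canopy — and with it grain fill — from the filling stage. Grain mass
tracks the milk-stage canopy (3.1·sat^0.25·(milk leaf biomass)^0.85),
stems follow an allometric power of leaf biomass, and every uptake entry is
concentration × biomass with re-fixation fractions drawn inside the
physiological ranges so the grain P balance closes. Spectra are forward
simulations plus 1 % multiplicative noise, 0.001 additive reflectance noise
(plot spectra are averages of many scans) and a low-order polynomial
baseline wiggle that exercises the derivative preprocessing.

The generator does **not** emulate: instrument wavelength drift, soil
heterogeneity beyond the brightness scalar, bidirectional-geometry
variation between plots, row-structure/clumping effects, weather or growth
dynamics, or model error between the forward model and a real canopy
(spectra are generated by the same model the hybrid branch inverts).
Passing recovery tests therefore demonstrate the pipeline's internal
consistency and its behaviour under noise, saturation and organ
heterogeneity — not field-data accuracy.

## Problem sizes and reproducibility

The recovery studies run the default campaign (28 plots) over ten seeds
with 2,000-candidate pools; the selection-versus-random comparison uses a
60-plot campaign (15 treatments × 4 replicates) with 4,000-candidate
pools; the look-up-table regression benchmark uses a 20,000-row Latin
hypercube, a 4,000-row screening subsample for the importance ranking, and
a 70/30 split for the final 30-band forest. Every stochastic step takes an
explicit integer seed; two runs with equal seeds are bitwise identical.

## Known limitations

* Absolute reflectances come from synthetic optical constants; only
  relative/structural behaviour is meaningful against real spectra.
* The whole-plant baseline and all empirical models are trained on tens of
  plots; their test-set R² carries the sampling noise of ~9-sample
  evaluation sets, which is why claims are made over ten seeds.
* The stem branch is a deterministic polynomial of leaf P and cannot
  recover stem-specific variability (a limitation the organ decomposition
  inherits from the unobservability of stems in canopy spectra).
* NRBO and SCA–SSA follow the cited algorithm families but fix details the
  original descriptions leave open; they are validated behaviourally on
  standard benchmarks rather than against a reference implementation.
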