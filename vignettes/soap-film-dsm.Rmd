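---
title: "Soap-film density surface models for point-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soap-film density surface models for point-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`soapdsm` implements two-stage model-based density estimation for
point-transect distance sampling (PTDS) surveys whose study regions have
complex boundaries — concave arcs, habitat edges, or holes of unsuitable
habitat.  The motivating setting is a forest-bird survey (the Hawaiʻi
ʻĀkepa at Hakalau Forest) where a penalized-spline density surface leaked
non-zero density across a pasture–forest boundary into habitat the birds
do not use.  The package's central object is the soap-film smoother: a
spatial smooth built from a cyclic smooth around the region edge plus an
interior "film" that is exactly zero on the edge, so the fitted surface
can never smooth across the boundary.

# The two-stage model

## Stage 1: detectability

Birds are counted from fixed points, recording the radial distance $r$
to each detection.  The probability of detecting a bird at distance $r$
is the detection function $g(r)$, either half-normal,
$g(r) = \exp\{-r^2/(2\sigma^2)\}$, or hazard-rate,
$g(r) = 1 - \exp\{-(r/\sigma)^{-b}\}$.  Distances beyond a truncation
distance $w$ are discarded; `select_truncation()` chooses $w$ where a
preliminary fit puts $g(w) \approx 0.1$.  Given presence, a bird's
distance in the radius-$w$ disk has density $2r/w^2$, so detected
distances have density
$$f(r) = \frac{r\,g(r)}{\int_0^w t\,g(t)\,dt}, \qquad 0 \le r \le w,$$
which `fit_detection()` maximizes directly (optimizing $\log\sigma$, and
$\log(b-1)$ for the hazard rate so the key keeps a shoulder and declines
monotonically, with jittered restarts because the hazard-rate likelihood
can be flat).  The average detection probability within the disk is
$P_a = (2/w^2)\int_0^w r\,g(r)\,dr$ (adaptive quadrature; the
half-normal closed form is kept as a cross-check), with a delta-method
standard error from the observed information.  The quantity passed to
stage 2 is the *effective area searched* per point,
$\hat\nu = P_a\,\pi w^2$ (m²).  Models are compared by AIC and checked
with an unweighted Cramér–von Mises test whose p-value uses the
asymptotic distribution without a parameter-estimation correction — it
is therefore approximate and mildly conservative, matching the
convention of standard distance-sampling software.

## Stage 2: the density surface

Counts $n_k$ at point $k$ (location $x_k, y_k$ in projected metres)
follow
$$\log E(n_k) = f(x_k, y_k) + \log\hat\nu,$$
a GAM with a log link, the effective area as offset, and a Poisson or
negative binomial response ($\mathrm{Var} = \mu + \mu^2/\theta$).
Smoothing parameters, and $\theta$ for the negative binomial, are
estimated by REML.  `fit_dsm()` supports two smoothers:

* **TPRS** — an isotropic thin plate regression spline, `k = 127` basis
  functions by default, of which one degree of freedom is absorbed by
  the sum-to-zero identifiability constraint (126 free coefficients).
  TPRS ignores the domain shape entirely.
* **Soap film** — two linked components entered as separate model
  terms, each with its own penalty and smoothing parameter: a cyclic
  smooth in boundary arc length (default basis dimension
  `k_boundary = 20`; cyclicity and centering each absorb one degree of
  freedom, leaving 18), and the interior film, one basis function per
  interior knot (a regular lattice from `make_knot_grid()`, default
  spacings 730 m east by 670 m north), each of which is exactly zero on
  the boundary.  The basis functions are defined through Laplace/Poisson
  problems on the region and are solved numerically on a grid with at
  most `nmax` cells on the longest side (`nmax = 140` in the worked
  pipeline; the fitted surfaces change negligibly beyond that, and a
  grid-refinement test checks Cauchy behaviour of the film basis).

The basis and penalty construction is delegated to `mgcv` (the standard
engine for these smoothers), behind the package's `smoother_spec()` /
`build_smoother()` interface; the behavioural contracts — film exactly
zero on the boundary, no predictions outside the region, cyclic boundary
smooth, PSD penalties — are what the package tests, not bit-level
equality with any particular construction.

Because the model is fitted by penalized likelihood, the returned object
carries the Bayesian posterior covariance $V_\beta$ of the coefficients
(the inverse penalized information), per-term effective degrees of
freedom, and the proportion of deviance explained.

## Boundary behaviour and evaluation conventions

Evaluation of the soap smoother outside the region returns `NA`, never
an extrapolated number.  Evaluation *on* the boundary uses the
construction directly: the film's Dirichlet condition makes it exactly
zero there, so film columns are returned as 0 for on-boundary points
(within a small snap tolerance), while the boundary smooth is evaluated
at a point nudged a fraction of a metre inward along the inward normal,
because the numerical PDE grid only supports interior interpolation.
Inside the region but near the edge, the film basis decays towards zero
at the scale of the solution grid cell; tests assert both the exact
boundary zero and the monotone interior decay.  The boundary profile of
a soap fit (`boundary_profile()`) is therefore the cyclic boundary
smooth plus intercept alone — by construction, not approximation.

## Abundance

`predict_surface()` evaluates the fitted surface on square cells
(200 m default) whose centres fall in the region; density is reported in
birds ha⁻¹ (1 ha = 10⁴ m²; the offset is excluded so predictions are per
unit area), with delta-method standard errors
$\hat D \sqrt{x^\top V_\beta x}$.  `posterior_abundance()` draws
coefficient vectors $\beta^{(s)} \sim N(\hat\beta, V_\beta)$, computes
$N^{(s)} = \sum_{\mathrm{cells}} \exp(x^\top_{\mathrm{cell}}\beta^{(s)})\,a_{\mathrm{cell}}$,
and reports the mean of the draws as the point estimate, the SD as the
SE, and the 2.5/97.5 percentiles as the 95% interval (10,000 draws by
default).  The mean (not the median) of the draws is used as the point
estimate; with a log link the draw distribution is right-skewed, so the
mean sits slightly above the plug-in value.  Detection-function
uncertainty is *not* propagated into model-based intervals by default —
the detection model has no spatial covariates, so its uncertainty is a
single multiplicative factor; an optional argument folds a detection CV
into the interval in quadrature for users who want it.

`design_based_abundance()` is the conventional comparison:
$\hat D = \sum_k n_k / (K \hat\nu)$, $\hat N = \hat D \times A$, with
$\mathrm{CV}^2(\hat N) = \mathrm{CV}^2(\text{encounter rate}) +
\mathrm{CV}^2(\hat P_a)$ — the encounter-rate variance is the empirical
between-point variance of $n_k$ with points as sampling units — and a
z-based lognormal 95% interval $\hat N \cdot C^{\pm 1}$,
$C = \exp\{1.96\sqrt{\ln(1+\mathrm{CV}^2)}\}$ (no small-sample
degrees-of-freedom correction).  Estimator pairs are compared by the
percentage change in confidence-interval width,
$(\mathrm{CIW}_b/\mathrm{CIW}_a - 1)\times 100\%$ with the soap model as
reference $a$.

## Model checking

Two diagnostics mirror standard density-surface practice.
`residual_refit_check()` refits the same smoother (Gaussian family, with
intercept) to the deviance residuals; with no remaining spatial pattern
the refitted EDF should be near zero per term.  The refit uses
`select = TRUE` so each term's penalty null space is also penalized —
without this a thin-plate term would always retain its two unpenalized
linear degrees of freedom and could never shrink to zero.  In null
simulations the refit EDF is exactly zero in the clear majority of
replicates and its median is zero, but REML estimates a nonzero EDF on
pure noise in roughly a fifth to a third of replicates; the diagnostic
is a screen, not a test with controlled size.  `basis_adequacy_index()`
is this package's convention for a basis-dimension check: the mean
squared difference of deviance residuals between nearest-neighbour
point pairs divided by twice the overall residual variance.  For
exchangeable residuals its expectation is 1; values clearly below 1
mean neighbouring residuals are more alike than chance, i.e. fine-scale
structure the basis did not capture.

# The synthetic survey generator

No survey data are shipped; `simulate_survey()` generates PTDS surveys
with known truth, and `hakalau_like_fixture()` instantiates the
conditions of the 2002 ʻĀkepa survey that the pipeline is exercised on:

* a region of exactly 5,671.8 ha with an irregular western
  (pasture–forest) edge and squared-off north, east and south sides.
  The real boundary coordinates were digitized interactively and never
  published, so the fixture is a synthetic stand-in matching the area
  and qualitative shape; its arc-length origin is the south-west
  corner.
* 14 east–west transects with gaps alternating 500 m and 1,000 m and
  evenly spaced points along each transect — exactly 289 points,
  deterministically (the excess raw points are trimmed one at a time
  from the east end of the currently longest transect, so every
  transect survives).  Scaling the synthetic polygon to the exact
  published area stretches the nominal 150 m spacing to about 162 m;
  the survey geometry (area, point count, transect count, spacing,
  gaps) is overdetermined, and the spacing absorbs the slack.  The six
  northern transects are east-anchored, leaving the low-density
  north-west corner unsampled, as in the real sampling frame (survey
  coverage at 289 points cannot tile a 56.7 km² region; the unsampled
  share is placed where the paper reports near-zero density, which is
  also why the *design-based* estimator on this fixture carries a
  frame-coverage bias that the model-based estimators do not).
* a density surface with a strong southern hotspot, a moderate central
  hotspot and a near-zero north (two Gaussian bumps, amplitudes 3.96
  and 2.16 birds ha⁻¹ with a 0.036 baseline, calibrated once so the
  expected number of detections matches the 276 recorded in 2002; the
  fraction of points with at least one detection then falls near the
  printed 121/289 without further adjustment).
* hazard-rate detection with $b = 3.5$ and $\sigma = 39.837$ m, the
  unique scale at which $P_a(58\,\mathrm{m}) = 0.631$, the published
  value; generation uses $w_{max} = 90$ m so that distances beyond the
  58 m analysis truncation exist, as in real data.
* negative binomial counts with dispersion $\theta = 10$, applied at
  the count level so generator and fitted model agree.  Birds are
  placed independently per point disk; at 150 m spacing and detection
  radii under 100 m the disks barely overlap, so no shared population
  is simulated.

All randomness flows from a single integer master seed.  What passing
recovery tests on this generator do **not** show: robustness to animal
movement, availability bias, observer heterogeneity, detection
covariates, or residual spatial correlation beyond what the NB count model
induces — none of which the generator emulates.

# Problem sizes and numerical choices

The test-suite studies use the sizes at which the answers stabilize
while keeping a desk-scale run: 30 fixture seeds for full-pipeline
abundance recovery and detection-scale recovery; 50 replicates for
interval coverage, simulated from a fitted soap surface with NB(θ=10)
counts, a known offset, and a regular ~300-point lattice spanning the
region so the estimating model is correctly specified (coverage of the
posterior-simulation interval is a stage-two property; stage-one
uncertainty is deliberately not in the interval, and sampling designs
that leave part of the region to extrapolation inflate exp-scale
abundance upward — on the fixture's own frame the same interval covers
at roughly 85%, every miss from above — so frame effects are assessed
by the recovery study, not the coverage study); 1,000 posterior draws
inside the replicated studies and
10,000 in the worked pipeline; PDE grid `nmax = 140`; IRLS/REML
convergence at mgcv defaults (deviance tolerance 1e-8).  Coordinates
are projected metres throughout; no geographic CRS handling is
attempted, and invalid polygons are rejected rather than repaired.

Known limitations: the CvM p-value ignores parameter estimation; the
hazard-rate fit needs a few hundred detections to pin down both
parameters (at the fixture's ~230 truncated detections the between-seed
spread of $\hat\sigma$ is of order 10%); the NB dispersion is weakly
identified when the spatial smooth absorbs most overdispersion, so
$\hat\theta$ is occasionally very large (effectively Poisson) on single
fixtures while its across-seed median is near the truth; and the
delta-method surface SE is first-order, matching posterior-simulation
SDs closely only where the link-scale SE is small.
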