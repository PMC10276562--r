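# soapdsm

Two-stage, model-based density and abundance estimation for
point-transect distance sampling surveys on study regions with complex
boundaries — habitat edges, concave arcs, holes of unsuitable habitat.
It is written for wildlife biologists and quantitative ecologists who
have per-point radial detection distances and a study-region polygon,
and who need density maps and abundance intervals that *respect the
region edge* instead of smoothing across it ("leakage").

The package grew out of forest-bird monitoring of the endangered
Hawaiʻi ʻĀkepa (*Loxops coccineus*), where a conventional thin plate
regression spline predicted non-zero densities across a pasture–forest
boundary into habitat the species does not use.

## The model

**Stage 1 — detectability.** Radial distances to detected birds are
truncated at *w* and fitted by maximum likelihood with the density
*f(r) = r g(r) / ∫₀ʷ t g(t) dt*, where *g* is a half-normal
(*g(r) = exp(−r²/2σ²)*) or hazard-rate (*g(r) = 1 − exp(−(r/σ)^(−b))*)
key. Keys are ranked by AIC and checked with an unweighted
Cramér–von Mises test. The fit yields the average detection
probability *P_a* and the effective area searched per point,
*ν̂ = P_a π w²*.

**Stage 2 — the density surface.** Counts *n_k* at point *k* follow a
GAM with log link and offset,

> log E(n_k) = f(Easting_k, Northing_k) + log ν̂,

with Poisson or negative binomial (Var = μ + μ²/θ) response and REML
smoothness selection. The smooth *f* is either a thin plate regression
spline (boundary-blind) or a **soap-film smoother**: a cyclic smooth
around the boundary plus an interior film that is exactly zero on the
boundary, so the surface cannot leak across the region edge.
Abundance is obtained by posterior simulation — coefficient draws from
N(β̂, V_β), abundance per draw summed over a 200 m prediction grid,
percentile 95% intervals — alongside a design-based conventional
distance sampling estimator and a confidence-interval-width (CIW)
comparison between estimators.

## Worked example

The package ships a synthetic survey generator calibrated to the
conditions of the 2002 ʻĀkepa survey (289 points on 14 transects in a
5,671.8 ha region, hazard-rate detection with P_a(58 m) = 0.631,
negative binomial counts, two density hotspots and a near-zero north):

```r
library(soapdsm)

sv <- hakalau_like_fixture(seed = 1)
sv
#> Synthetic point-transect survey: 289 points, 306 detections at 135 points
#>   truth: N = 4,622 birds; detection hr sigma 39.8 b 3.5 ; theta 10

res <- run_pipeline(sv$points, sv$records, sv$region,
                    truncation = 58, n_sims = 10000, seed = 1)

res$detection$table
#>   key npar      aic delta_aic       p_a     se_p_a
#> 1  hr    2 1937.930  0.000000 0.5810928 0.04795955
#> 2  hn    1 1939.909  1.979231 0.4769583 0.04106974

res$fits$soap
#> Density surface model (soap film smoother), family: negative binomial (theta = 15.02)
#>   n points: 289  total count: 246
#>   boundary  EDF   3.43 of 18
#>   film      EDF  11.96 of 116
#>   deviance explained: 48.8%

for (a in res$abundance) print(a)
#> soap     N = 6,027  SE = 476.89  CV = 0.079  95% CI (5,168, 7,023)
#> tprs     N = 6,030  SE = 468.82  CV = 0.078  95% CI (5,182, 7,012)
#> distance N = 7,862  SE = 940.65  CV = 0.120  95% CI (6,223, 9,931)

res$comparison$tprs
#> CIW change soap -> tprs: -1.4%
```

Reading the output: the hazard-rate key wins the AIC comparison (ΔAIC
2.0 against the half-normal), estimating that a bird within 58 m of a
point is detected with probability 0.58. The soap model uses 3.4 of 18
boundary degrees of freedom and 12.0 of 116 interior degrees of
freedom and explains 49% of the count deviance. The model-based
abundance estimates (soap 6,027; TPRS 6,030) are posterior-simulation
means with percentile intervals; the generating truth for this seed is
4,622 birds, which this particular draw overestimates — across
replicate seeds the soap estimate recovers the truth with a median
absolute error under 15% (see the recovery tests). The design-based estimate (7,862)
overshoots by construction on this fixture: its sampling frame leaves
the near-empty north-west corner unsampled, a frame-coverage bias the
model-based estimators do not share because they extrapolate the
fitted (near-zero) surface into that corner.

The boundary behaviour is the point of the package:
`boundary_profile(res$fits$soap)` evaluates the fitted density along
the region edge (for the soap model this is the cyclic boundary smooth
alone — the film is exactly zero there), and
`predict(res$fits$soap, newdata = ..., type = "density")` returns `NA`
outside the region rather than an extrapolated number.

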