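---
title: "foragescape: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foragescape: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not emulate,
the numerical conventions, and the known limitations — including one
quantified limitation of fine-scale detection that users should understand
before interpreting coarse-scale results.

## Tracks, behaviour, trips

GPS fixes arrive as `(individual, timestamp, lon, lat)` at roughly 5-minute
cadence. All geodesics are haversine distances on a sphere of radius
6371.0088 km (the IUGG mean radius); at foraging-trip scales the error
against an ellipsoid is below 0.5%, and no projection machinery is needed
at the interface. Where planar geometry is required internally (path
interpolation, FPT circles, kernel smoothing), coordinates are projected to
an azimuthal-equidistant plane centred on the colony, in km.

Behaviour is classified by the *incoming* speed of each fix (distance from
the previous fix over elapsed time, assigned to the later fix): strictly
below 3 km h⁻¹ is rest — drift on the water or time on land — everything
else flight. The threshold sits in the trough between the drift and flight
modes of typical shearwater speed distributions. The first fix inherits the
second's label.

A trip is a maximal run of fixes farther than a colony buffer (default
2 km) lasting at least 1 h with at least 5 fixes. These three values are
conventions, not estimates: colonial central-place data rarely say where
"at the colony" ends, so they are exposed as arguments and logged. Gaps
longer than 60 min inside a trip are reported but do not split it — GPS
dropout is common and splitting would manufacture spurious short trips.
Time is attributed to fixes trapezoidally (half of each adjacent gap), so
flight-hours-per-day is unbiased under regular sampling with dropouts.

## First-passage time and ARS detection

First-passage time at radius *r*, centred on a path point, is the backward
plus forward time to first exit the circle of radius *r* — the standard
reading of the time an animal takes to "pass through" the circle. Exits are
located by exact segment–circle intersection (solving the quadratic along
each segment) with the crossing time prorated linearly, so the straight-path
closed form FPT = 2r/v is reproduced to machine precision, not merely
approximately. Points whose circle is never exited before either path end
are undefined and excluded (not imputed).

Before FPT analysis, rest bouts are removed and the flight path is
reconnected: sub-100-m drift otherwise creates intense small-scale variance
that masks real ARS structure. The bridging leg across a removed bout keeps
the elapsed time minus the bout's internal duration, so vertex times measure
flight time. The reconnected path is re-interpolated at fixed along-path
spacing; vertex times interpolate linearly within each original leg.

The variance of log FPT across path points, as a function of *r*, peaks
near the spatial scale at which the animal concentrates its search; the log
transform makes the variance independent of the FPT magnitude so radii are
comparable. The detected ARS scale is the radius of the *interior global
maximum* of that profile; a maximum on the boundary of the scanned range
means the scan did not bracket a peak and no scale is returned; exact ties
break toward the smaller radius. The two-stage scheme scans r = 1–50 km in
1-km steps on a 1-km-interpolated path, then r = 0.1–10 km in 0.1-km steps
on a 0.1-km path.

ARS zones at the detected scale are maximal runs of points with FPT above
the trip's 0.75 quantile of defined FPT values (the quantile is exposed;
no delineation convention is standard in the literature), with runs merged
when separated by less than r\*/mean-flight-speed hours — the bird has not
left the scale's neighbourhood in between. Each zone reports its
time-weighted centroid, maximum FPT, entry time, residence and colony
distance. The variance profile is computed per trip; pooling across trips
would mix birds with different patch geometries.

## What the trajectory simulator emulates — and what it does not

`simulate_trajectory()` is a correlated random walk at the fix interval:
gamma step lengths (cruise mean 30 km h⁻¹, SD 5), wrapped-normal turning
angles, goal-biased commuting, and patch-restricted search inside a
circular prey patch — waypoints drawn uniformly in the patch disk keep the
usage spread over the whole patch, while a speed multiplier (0.45) and a
large turning-angle SD (80°) produce the elevated residence that FPT should
detect. Rest bouts appear as sub-3 km h⁻¹ drift runs at an exponential
rate; the bird homes between excursions and dwells at the colony. Defaults
(12 h of patch foraging, a 10-km patch ~57 km from the colony) were fixed
once from pilot runs of the generator itself and give the validation its
teeth: over 50 seeds the detected meso scale falls within ±20% of the
configured radius in ~86% of trips, median 10–11 km.

The generator does **not** emulate: diel rhythm (simulated birds rest far
less than real ones, so flight-hours-per-day runs high), wind drift,
memory or energetics, location error, or irregular sampling. Passing
recovery tests on this generator therefore shows the estimators are
correct *for movement of this class*, not that field data will be as clean.

### The nested two-scale condition and a known estimator bias

`traj_config_nested()` defines a hierarchical condition: a 30-km meso patch
~144 km from the colony containing four 2-km fine-scale patches on an
interior ring; a quarter of search waypoints target a fine-scale patch,
where a fast, tortuous, boundary-confined 1.5-h intensive bout follows.
Stage 1 recovers the meso scale reliably (50-seed median 34 km for a 30-km
patch — usage extends slightly beyond the patch boundary, so a small
positive bias is expected).

The fine scale is different, and users should know why. The variance of
log FPT at small radii mixes three signals: the intensive bouts themselves
(peaking at the bout-patch radius), the spacing between bout sites (circles
centred between sites capture bout time once *r* reaches the typical
site-to-site half-distance), and the texture of the extensive search walk.
Across a wide range of generator designs the second and third components
peak at 3–8 km and usually exceed the first, so the global-maximum rule
returns a fine scale near the *spacing* of intensive-search sites rather
than their radius: in the shipped condition the 50-seed median is ~7–8 km
for 2-km patches, and in many seeds no interior fine-scale peak exists at
all. Two structural constraints cap the achievable contrast: at a 5-min
cadence the intensive-search step length (~0.4–1 km) is not far below the
2-km patch radius, and ground speeds below ~3.5 km h⁻¹ are — correctly —
classified as rest and removed before FPT. We report this as a property of
variance-peak FPT analysis at fine scales under realistic sampling, not as
a tuning failure; the single-scale recovery results are unaffected. In
practice, fine-scale estimates from 5-min GPS data should be read as the
scale of *clustering of intensive search*, not the size of individual prey
patches.

## Kernel utilization distributions

Densities are estimated in the colony-centred metric plane with an
isotropic Gaussian kernel and reported on a 0.12° geographic grid (the
coarsest predictor resolution), renormalized to unit mass against exact
spherical cell areas. Estimating in degrees would stretch the kernel
east–west at these latitudes; estimating metrically and reporting on the
degree grid keeps both properties.

The bandwidth minimizes the least-squares cross-validation score on a
30-point log grid spanning 0.05–2 times the bivariate Gaussian reference
bandwidth σ·n^(−1/6). Exact duplicate points are removed first — duplicates
drive the LSCV minimum to zero bandwidth — and a boundary minimum falls
back to the reference bandwidth with a warning. One bandwidth, estimated on
the reference dataset, is reused across comparison datasets so that overlap
statistics compare distributions rather than smoothing choices.

Contours accumulate cells by descending density until the requested mass is
enclosed (the standard UD volume convention); the 50% and 95% sets are the
core foraging region and home range. On a 10⁴-point Gaussian sample the 95%
contour encloses 94–96% of mass, and the 95%/50% area ratio matches the
Gaussian level-set value ln 0.05/ln 0.5 ≈ 4.32 within 5%. Overlap uses the
volume-intersection index VI = Σ min(UD₁, UD₂)·area, which reproduces the
closed form 2Φ(−d/2σ) for separated Gaussians to ±0.01 at the 0.12°
resolution. Conservation-layer overlap is grid-based: the percentage of the
focal contour's spherical area whose cell centres fall inside the layer
polygons (union, outer rings); with 13-km cells this is accurate to roughly
one cell width along the layer boundary.

## Presence-only habitat models

The model is the Gibbs distribution q(x) ∝ exp(λ·f(x)) over all non-missing
grid cells (the background) that maximizes the L1-penalized log-likelihood
of the presence cells, with features the linear and quadratic terms of each
predictor scaled to [0, 1]. Duplicate presences per cell are removed. The
per-feature penalty is reg·max(sd_presence(f), 0.05)/√n with reg = 1 — a
floor keeps near-constant features penalized — and optimization is cyclic
coordinate descent with soft-thresholding, a unit trust region, and exact
objective re-evaluation per step, stopping when a full sweep gains less
than 1e-6. The fitted distribution satisfies the KKT moment conditions
|E_q[f] − mean_presence[f]| ≤ β to numerical slack (tested). Logistic
output p = e^H q/(1 + e^H q), with H the entropy of q, maps suitability to
(0, 1) with "typical" presence ≈ 0.5.

Evaluation repeats 50 random 70/30 presence splits: test AUC is the
rank-based presence-versus-background statistic (identical to the
trapezoidal ROC area); qualitative bands are excellent (> 0.9), good
(0.8–0.9), acceptable (0.7–0.8), bad (0.6–0.7), invalid (≤ 0.6). Percent
contribution is each variable's share of positive penalized-gain increments
along the optimization path; permutation contribution is the normalized AUC
drop when that variable is permuted across the test presences plus
background. Jackknife gains (each variable alone / all but one) are
computed once on the full presence set. Two calibration conditions back
these numbers: uniform presences give mean test AUC 0.45–0.55, and
presences drawn ∝ exp(2·SST) over a broad (10–26 °C) thermal ramp give mean
test AUC > 0.9 with SST ranked first in both contribution schemes. The
driver condition needs a wide predictor span because with presences
∝ exp(2·x) the attainable AUC is roughly 1 − 1/range(2·x); a narrow or
binary front saturates near 0.85 no matter how good the model.

Window gradients follow the relative-range formula 100·(max − min)/max over
each cell's 3×3 neighbourhood, dropping missing and out-of-bounds
neighbours and leaving the cell missing when the window maximum is 0. Note
the formula is *relative*: layers that approach zero (e.g. chlorophyll in
oligotrophic water) show near-100% gradients along their low tail, which is
why fronts are sought in gradient layers of fields with a well-separated
dynamic range.

## Isotopic niches

The standard ellipse of a bivariate (δ¹³C, δ¹⁵N) sample is the 1-SD
Mahalanobis ellipse of the fitted normal: SEA = π√(λ₁λ₂) (~40% of the
mass), with SEAc = SEA·(n−1)/(n−2) the small-sample correction. Some field
descriptions call this the "95%" ellipse; that conflicts with the standard
ellipse convention, and this package implements the standard definition —
areas are comparable with the mainstream isotope-niche literature.

SEA_B draws covariances from the conjugate normal-inverse-Wishart posterior
under a deliberately vague prior: identity scale, degrees of freedom
= dimension + 1 = 3 (the smallest proper value), κ₀ = 1e-3 and μ₀ = 0 so
the mean component contributes negligibly. Draws use the Bartlett
decomposition, so the posterior is a pure function of the seed. The
comparison probability P(area_A < area_B) is the fraction of paired draws
ordered that way; under a symmetric null its average over replicate sample
pairs is 0.5, and for a 4× area separation at n = 100 it exceeds 0.95.
Ellipse overlap is seeded Monte-Carlo over the joint bounding box (±1%
at 10⁵ points); exact conic intersection buys little at that tolerance.
Layman metrics are the per-axis ranges and the convex-hull (shoelace) area.

The isotope generator draws bivariate-normal groups emulating a
breeding-phase contrast — incubation centred at (−17.8, 10.2)‰ with SDs
(0.6, 0.5), chick-rearing at (−19.4, 13.8)‰ with SDs (0.7, 0.8) — so the
configured ordering (chick-rearing niche wider, δ¹⁵N higher, δ¹³C lower)
is known ground truth for the comparison machinery.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order from one config
(optionally YAML): simulate → trips → ars → kud → habitat, with isotopes
independent. Stage seeds derive from the master seed by fixed offsets;
every artifact is a text format (CSV, ESRI ASCII grid, GeoJSON, JSON) with
deterministic formatting, and each stage writes a manifest with its
parameters and input hashes. Two runs with the same config are
byte-identical — tested at the file-hash level.

Problem sizes throughout the tests and the acceptance script (50-seed
recovery batches, 40×40 predictor grids, 10⁴-point UD samples, 50-replicate
evaluations, 10³–10⁴ posterior draws) were chosen as the smallest at which
the statistical claims are stable; all are arguments, and nothing prevents
running larger studies.

## Known limitations

- Fine-scale ARS estimates reflect intensive-search clustering, not patch
  radius, as quantified above.
- The speed filter is a hard threshold; no hidden-Markov or state-space
  smoothing of behavioural states is attempted (deliberately, to stay with
  the FPT-only analysis).
- Contours and layer overlaps are grid-cell geometry at 0.12°; boundary
  effects are of order one cell.
- The habitat model uses linear + quadratic features only; threshold/hinge
  responses would need a feature extension.
- The isotope machinery assumes bivariate normality within groups; heavy
  tails inflate SEA.
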