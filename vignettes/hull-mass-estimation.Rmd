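---
title: "Convex-hull body-mass estimation: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-hull body-mass estimation: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullmass)
```

## The problem

Estimating the body mass of an animal from its skeleton is a central task in
palaeontology and physical anthropology. Volumetric approaches sidestep the
subjectivity of sculpting soft tissue onto a skeleton: wrap each skeletal
functional unit (trunk, limb segments, neck, skull) in its minimum convex
hull, sum the hull volumes into a whole-skeleton volume `vol_CH` (m³), and
calibrate the relationship between `vol_CH` and body mass `M_b` (kg) on
modern species whose masses are known. The calibration curve is a power law
fitted on the log10 scale,

    log10(M_b) = a + b · log10(vol_CH) + ε,   ε ~ Normal(0, σ²),

so `b = 1` corresponds to geometric similarity (isometry): a taxon whose
mass grows proportionally to its skeletal hull volume. `b` above or below 1
indicates that larger members of the group carry proportionally more or
less tissue outside the skeletal envelope.

`hullmass` implements the full pipeline: point-cloud ingestion (OBJ/PLY),
Quickhull volumes, segment subdivision and subsampling, OLS and
phylogenetic (Brownian and Ornstein–Uhlenbeck) calibration, ANCOVA slope
comparison, apparent-density analyses, and smearing-corrected mass
prediction. It ships the published 32-specimen calibration table (9 birds,
14 non-primate mammals, 9 primates) as its canonical dataset.

## Hull volumes

`compute_hull()` runs an incremental Quickhull (C++, conflict lists,
horizon-edge repair) and evaluates the volume by the divergence theorem:
signed tetrahedra over the outward-oriented triangular facets against the
centroid of the hull vertices. This makes the volume exact for polytopes,
invariant under rigid motion, and cubically equivariant under scaling —
all of which are asserted in the test suite, together with agreement to
machine precision with an independent Quickhull implementation on random
clouds.

Degenerate inputs (fewer than 4 points, or collinear/coplanar clouds) are
detected from the singular values of the centred cloud; any singular value
below 1e-9 of the largest marks rank deficiency. Scanners do not produce
such clouds in practice, but subdivided segments can.

Two manipulations mirror how scanned skeletons are actually processed:

* **Subdivision** (`subdivide_segment()`): a curved functional unit —
  giraffe or camel neck, primate tail — is cut into parts before hulling so
  each part hulls tightly. Parts are equal-count quantile slabs along the
  first principal component (or a coordinate axis). Rank-based cuts were
  chosen over equal-length cuts because scanner point density is far from
  uniform; for a convex segment the choice is immaterial (part volumes sum
  back to the unsplit volume within discretisation error), while for a
  curved tube the summed volume drops — that drop is the point of
  subdividing, and the package reproduces it on synthetic bent tubes.
* **Subsampling** (`subsample_pointcloud()`): LiDAR point counts scale with
  specimen size, so density-matched comparisons subsample without
  replacement with an explicit seed. A dense cloud subsampled 10-fold moves
  its hull volume by well under 1%.

## Calibration statistics

`fit_ols_loglog()` is deliberately plain simple regression (Type-I; the
curve is used predictively). Conventions, some of which the published study
leaves unstated, are fixed as follows:

* Confidence intervals: t distribution, n − 2 df.
* `MSE = RSS/(n − 2)` on the log10 scale (residual degrees of freedom).
* `AIC = −2 lnL + 2k` with the Gaussian ML likelihood and `k = 3`
  (intercept, slope, residual variance). This convention makes the
  Ornstein–Uhlenbeck model's AIC sit exactly 2 units above the OLS value
  when its extra parameter collapses (`d → 0`), matching the uniform +2
  offsets visible in the published comparison table.
* Back-transforming `10^(a + b log10 V)` yields a geometric-mean mass; the
  smearing correction `CF = exp(MSE · ln(10)²/2)` (base-10 Baskerville
  factor) converts it to an arithmetic mean. `CF = 1` exactly when
  `MSE = 0` and grows monotonically with MSE.
* `%PE = 100 · |M_obs − M_pred| / M_pred` with the *predicted* mass in the
  denominator and no CF, the convention of the mass-estimation literature
  this feeds into; the observed-mass alternative is available via an
  argument because the two differ by 1–2% on real data. The CI on mean %PE
  is the t-based interval.
* Slope comparison is the ANCOVA interaction F — separate-lines versus
  common-slope model, `(g − 1, N − 2g)` df — followed by Tukey HSD on the
  slope estimates with the studentized range. A classical ANCOVA table also
  prints a group main effect at the centred covariate (adjusted-means F);
  that statistic is reported alongside because software front-ends often
  label it ambiguously.
* α = 0.05, two-sided, everywhere; no multiplicity correction beyond Tukey.

Prediction (`predict_mass()`) returns the point estimate with and without
CF and a 95% interval computed on the log10 scale with the new-observation
variance, then back-transformed. Volumes outside the calibration range
trigger an extrapolation warning rather than an error: fossil applications
routinely extrapolate, but should do so knowingly.

## Phylogenetic calibration

Related species are not independent data points. `fit_pgls()` fits the same
log-log line by GLS with residual covariance proportional to shared
root-to-tip branch length (Brownian motion, `bm_covariance()`), and
`ou_transform()` re-weights that covariance under a stationary
Ornstein–Uhlenbeck process with transform parameter `d = e^(−α)`:

    V_ij(d) = d^(2(T − t_ij)) · (1 − d^(2 t_ij)) / (1 − d²)

on an ultrametric tree of height `T` with shared depths `t_ij`. The two
limits are the binding contract: `d = 1` recovers Brownian motion
elementwise, `d = 0` the star phylogeny, i.e. OLS. `estimate_d_reml()`
profiles the restricted likelihood (including the `log|X'V⁻¹X|` term) over
`d` on a 101-point grid with golden-section refinement to 1e-4; ML
log-likelihoods drive the AIC comparison in `compare_models()`.

A practical caveat the validation work surfaced: at calibration-sized
samples (30–50 taxa) on unit-height Yule trees, the restricted likelihood
is nearly flat in `d` — the profile at the generating value is typically
within a fraction of a log-unit of its maximum. Point estimates of `d` are
therefore poorly determined on any single dataset even though the
machinery is correct (it agrees seed-for-seed with an independent GLS/REML
implementation). Star-generated and Brownian-generated data are still
cleanly separated in the median over replicates, and that is what the test
suite asserts; single-dataset `d` values should be read qualitatively
(near 0: OLS adequate; near 1: strong phylogenetic signal), which is also
how the published study used them.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs with known ground
truth:

* `generate_segment_cloud()` samples uniformly on parametric surfaces
  (ellipsoid, box with corners pinned, cylinder with end caps, bent tube),
  optionally with isotropic Gaussian jitter — surface sampling because that
  is what scanners deliver. Ellipsoid/box/cylinder truths are closed-form;
  the bent tube's hull has no simple closed form, so its truth is a dense
  deterministic reference grid (1e6 points by default; the test suite uses
  2e5-point grids, which differ from the 1e6 reference by 0.24%, far below
  the 2% tolerances applied).
* `generate_skeleton()` assembles quadruped and biped-bird templates whose
  proportions are documented constants, not biological claims.
* `generate_allometric_dataset()` and `generate_tree_and_residuals()`
  implement the regression model above, the latter with star/BM/OU residual
  covariance on Yule trees rescaled to unit height.

All generators are pure functions of an explicit integer seed (the global
RNG state is preserved), and a quick check of what passing tests do *not*
show: synthetic clouds have no registration error, no occlusion holes, no
mount-induced pose variation, and the allometric generator has log-normal
homoscedastic residuals by construction. Agreement on synthetic data
validates the computations, not the biological adequacy of any particular
calibration set.

## Numerical choices

* Quickhull outside-tolerance: 1e-10 of the largest coordinate magnitude;
  points within it of a face plane are treated as non-exterior (volumes are
  asserted to 1e-9 relative under rigid motion).
* Rank threshold for degeneracy: singular-value ratio 1e-9.
* Curved-tube reference volumes are cached per geometry within a session.
* `density_mass_regression()` defines `r² = 0`, `p = 1` for an exactly
  constant density response (the 0/0 ratio in a standard summary is
  numerical noise there).
* REML grid for `d`: 101 points then golden-section to 1e-4; endpoint
  values are compared explicitly so the boundary cases `d = 0` and `d = 1`
  are exactly attainable.
* Problem sizes in the test suite: 1e5-point spheres for convergence
  checks, 2e4-point tubes for subdivision, 200–1000 replicates for
  simulation-based checks, 30–50 taxa for phylogenetic recovery. These are
  the package's validation scale; the hull code itself is routinely used on
  clouds 10× larger.

## Reproducing the published statistics

`reproduce_calibration()` recomputes every OLS-side statistic of the
source study from the packaged table and flags agreement at the printed
precision (coefficients and r²: one unit in the last printed digit; F
statistics and mean densities: 0.5; %PE: 0.5 percentage points). The
packaged volumes carry three significant figures, which is enough to
reproduce all slopes, intercepts (one marginal miss by 0.001), r², mean
densities and the gorilla-exclusion sensitivity, but a few residual-based
quantities (combined-curve MSE and %PE, the slope-heterogeneity F, the
primate density r²) land measurably away from the printed values, which
were evidently computed on unrounded volumes. The report — and the
acceptance test suite — state those misses rather than hiding them. Of
note, the printed slope-comparison F statistic (7.18) is not the
interaction F computed from the table (9.20), but is close to the
adjusted-means group effect in the same separate-lines model (7.55); both
statistics are therefore reported.

## Known limitations

* Hull facets are triangles; coplanar faces are not merged (facet counts
  are triangulation-dependent, volumes are not).
* PGLS assumes the tree is correct and ultrametric; `d` is weakly
  identified at small n (above).
* The packaged calibration is dominated by hominoids on the primate side
  and ratites on the bird side; predictions for taxa outside those groups
  extrapolate in composition even when the volume is in range.
* Anatomical segmentation of a scan into functional units is upstream of
  this package: segment membership of shared joint bones is the caller's
  choice.
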