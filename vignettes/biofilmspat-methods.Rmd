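---
title: "Methods: spatial inference of mineral selectivity by rock-hosted biofilms"
author: "biofilmspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial inference of mineral selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmspat)
```

## The scientific question

Microbial biofilms colonizing rock surfaces in the deep subsurface are not
distributed uniformly: energy-rich minerals (iron sulfides such as pyrite,
iron-titanium oxides such as ilmenite) can act as electron donors and are
expected to accumulate more cells than the surrounding silicate matrix.
The observable is a stitched SEM/XEDS transect (~0.025 mm² at high
magnification): per-pixel element signal maps `Z_k(u)` together with the
centroids of manually curated cell features. The question is whether the
spatial arrangement of cells depends on the underlying element
distributions — *mineral selectivity* — or is indistinguishable from a
spatially random scatter.

`biofilmspat` implements the complete chain: raster/window bookkeeping and
tile stitching, per-feature morphology, kernel-density hotspot surfaces,
inhomogeneous Poisson point-process models with element covariates,
likelihood-ratio model selection, L-function goodness-of-fit with
Monte-Carlo envelopes, community-level statistics, and a seeded synthetic
generator that makes every stage testable with known ground truth.

## The point-process model

Cell centroids are modelled as an inhomogeneous Poisson point process with
log-linear intensity

$$\lambda(u) = \exp\!\Big(\beta_0 + \textstyle\sum_k \beta_k z_k(u)\Big),$$

where `z_k` are element channels standardized to zero mean and unit
variance over the window's valid pixels. Standardization makes detector
units irrelevant (XEDS counts and quantified weight-% give identical
inference; the likelihood-ratio statistic is invariant to affine channel
rescaling, which the tests assert to 1e-6) and stabilizes the IRLS
iterations. Coefficients are reported on both the standardized and the raw
channel scale.

The log-likelihood
$\sum_i \log\lambda(x_i) - \int_W \lambda(u)\,du$
is discretized with the Berman–Turner device: dummy points on a regular
tile grid join the data points, each tile's valid area is split equally
among the points it contains, and the weighted sum
$\sum_j w_j \lambda(u_j)$ replaces the integral. Maximization is then a
weighted Poisson regression solved by `stats::glm.fit` (IRLS, relative
tolerance 1e-8, at most 100 iterations; non-convergence is flagged on the
fit, not raised). Weights sum to the valid window area exactly by
construction. Standard errors come from the Fisher information
$\sum_j w_j \lambda(u_j)\, x_j x_j^\top$ at the estimate.

**Dummy grid default.** At least 64 × 64 tiles and at least four times as
many dummy points as data points; tiles are never smaller than one pixel.
At this resolution, halving the spacing moves the fitted coefficients of a
default synthetic scene by well under 1%, and the quadrature approximation
of $\int \lambda$ agrees with pixel-resolution summation to a few tenths of
a percent — provided the covariates vary on scales the grid can resolve
(see *Synthetic data* below). Degenerate inputs are handled explicitly:
constant channels are dropped with a warning before fitting, perfectly
collinear channels are detected as aliased coefficients and dropped, and a
data point on an unscanned pixel is an error.

## Nested-model comparison and subset search

A fitted covariate model is compared with the homogeneous null by the
likelihood-ratio test: the statistic is `2 * (loglik_alt - loglik_null)`,
identically the deviance difference deviance(null) − deviance(complex),
referred to a chi-square distribution with degrees of freedom equal to the
difference in fitted parameter counts. A model tested against itself
returns statistic 0 and p = 1; a negative statistic beyond −1e-6 signals a
quadrature mismatch and is an error (tiny negatives are rounded to zero).

`model_search()` fits **every** covariate subset of size 1..5
(exhaustive rather than greedy, since the best model can saturate all five
covariates in ways greedy forward selection misses). The published
selection rule — lowest p-value, highest deviance, fewest covariates — is
not a total order, so ties are broken deterministically: (min p, then max
deviance, then min subset size, then alphabetical model name). Ordering
uses log-scale p-values so that overwhelmingly strong models (whose
double-precision p underflows to 0) still rank correctly by their actual
tail mass. No multiple-testing correction is applied across the subset
family; the report records how many models were fitted so users can apply
their own. Patterns with fewer than `min_cells = 70` points are flagged:
selection is still computed, but at such counts covariate models rarely
beat the null, and the flag marks the result as unreliable rather than
suppressing it.

## L-function goodness-of-fit

The inhomogeneous Ripley K,
$\hat K(r) = \sum_{i\neq j} \mathbf{1}\{d_{ij}\le r\}\,
e_{ij}(r) / (\hat\lambda(x_i)\hat\lambda(x_j)) \big/ D,$
is variance-stabilized by Besag's transform $L(r)=\sqrt{K(r)/\pi}$, with
$L(r)=r$ under the fitted model. Defaults and conventions:

* **Edge correction**: border (reduced-sample) — only points farther than
  `r` from the boundary serve as reference points, normalized by their
  intensity-weighted mass (`"none"` is available for analytic
  hand-checks). For masked windows the boundary distance uses a distance
  transform of the valid mask.
* **r grid**: 128 points from 0 to one quarter of the shorter window side.
* **Envelopes**: pointwise min/max of `n_sim = 99` simulations from the
  fitted intensity (thinning of a dominating homogeneous process), giving
  a pointwise two-sided exceedance probability of 2% under the model.
  Observed and simulated curves are all evaluated under the same plug-in
  intensity; plug-in envelopes are mildly conservative because the
  intensity is not re-estimated per simulation.
* **Estimator resolution floor**: below roughly half the mean
  nearest-neighbour spacing ($0.5/\sqrt{\lambda}$) the expected number of
  point pairs within `r` is of order one, so the empirical K has relative
  Monte-Carlo noise of tens of percent and $\sqrt{\cdot}$ introduces a
  strong small-count bias — at any sample size. Calibration checks of the
  mean L curve therefore apply above this floor; below it no pointwise
  accuracy statement is meaningful for *any* estimator of this family.

A brute-force double-loop evaluation of K is kept in the test suite as an
independent oracle; the production estimator (binned pair accumulation)
must agree with it to 1e-12.

## Morphology

Feature area is pixel count × pixel area. Perimeter uses weighted
local-configuration counting: border pixels (those losing 4-connected
erosion) are classified by their border-neighbour configuration and
contribute calibrated step lengths — the Proffitt–Rosen weights 0.948
(axis-aligned step) and 1.343 (diagonal step), their mean for mixed corner
configurations, uniformly rescaled by +2% as a one-off calibration against
analytic disks digitized at random sub-pixel offsets. Raw edge counting
would overestimate a disk's perimeter by ~27% and break the circularity
identity. Features of 1–2 pixels have no interior and no measurable
contour; they fall back to the equivalent-square perimeter `4*sqrt(A)`.

Circularity is `4*pi*A/P^2`; classes are filament (c ≤ 0.1), rod
(0.1 < c ≤ 0.7) and cocci (c > 0.7), with boundary values assigned
downward (0.1 is a filament, 0.7 is a rod) following the published
threshold wording. Transect summaries truncate the circularity axis at 1
and record the 0.1/0.7 thresholds for plotting.

**Digitization floor.** At the smallest observed cell sizes (~0.1 μm² at
0.05 μm/pixel, radius ≈ 3–4 px) digitized circularity is biased high by
20–30% regardless of the estimator — a raster limit that equally affects
the original image-editor measurements. Round-trip classification tests
therefore use stamp sizes above ~120 px (radius ≥ 6 px), where stamped
rod/cocci mixes are recovered with >95% per-feature agreement; the
contract shapes (disk of radius 20 px within [0.95, 1.05]) are far above
the floor. Reported cell sizes are minima (dehydration shrinkage); no
correction is applied.

## Hotspot densities

`kde2d_cells()` evaluates the Gaussian product-kernel density via
`MASS::kde2d` on a grid over the window. The default per-axis bandwidth is
the normal-reference rule `4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)`
(`MASS::bandwidth.nrd`, the default of the plotting stack this analysis
style grew out of), with the kernel standard deviation `h/4`. Degenerate
patterns (all points coincident) fall back to a pixel-scale bandwidth
floor with a warning. Surfaces can integrate to n (points per μm²,
default) or to 1; the flag is recorded on the object. There is **no edge
correction**: densities are biased low within a bandwidth of the transect
border, which matches how such overlays are conventionally drawn and is
documented rather than corrected. Contours are traced at equally spaced
density levels (default 10) between the surface extremes; a constant
surface has no contours.

## Community statistics

* `bulk_chemistry()`: element-wise mean of replicate low-magnification
  XEDS scans (the study convention is 8 scans at 70×).
* `filter_taxa()`: keep taxa reaching ≥ 1% relative abundance in at least
  one sample **and** present in at least half of the samples. Abundances
  are deliberately not renormalized afterwards, so retained values remain
  interpretable against the whole community; the table is flagged
  `filtered`. The filter is idempotent.
* `taxa_chem_correlation()`: Pearson by default (Spearman by flag), raw
  abundances by default (transform hook provided); zero-variance rows or
  columns give `NA` ("undefined", distinct from 0); rows and columns are
  ordered by complete-linkage clustering of correlation distance to
  reproduce clustered-heatmap clades.
* `bray_curtis()`: `vegan::vegdist`.
* `simper_contributions()`: per-pair taxon contributions
  `|x_ai - x_bi| / sum_k (x_ak + x_bk)` averaged over all between-group
  pairs; they sum to the mean between-group Bray–Curtis dissimilarity
  exactly (the suite checks the identity to 1e-12 and cross-checks against
  `vegan::simper`). The selected set is the smallest ranked prefix
  reaching 75% cumulative share.

## Synthetic data: what it emulates, and what it does not

`grain_scene()` builds a transect-like window (default 500 × 768 px at
0.05 μm/px — a working-size portion of a transect; `full_scale = TRUE`
gives the full 1024 × 1536 acquisition-tile geometry) containing an
elliptical Fe/S-rich grain in a Si/Al/O matrix. Channel signals are
arbitrary detector-like counts; fits standardize covariates, so units
cancel.

Two realism parameters matter and are deliberate choices:

* `psf_sigma_px = 8`: the deterministic grain/matrix structure is blurred
  by a Gaussian point-spread of 0.4 μm. The X-ray generation volume at
  typical SEM voltages spans ~0.5–1 μm — an order of magnitude wider than
  one high-magnification pixel — so real element maps cannot contain
  single-pixel composition steps. Set 0 for an idealized hard-edged grain
  (used by tests of the two-valued noiseless case).
* `noise_sd = 1` with `noise_smooth_px = 8`: spatially correlated detector
  noise at the PSF scale, truncated at zero. Counting noise cannot
  routinely drive signals far below zero, so the truncated channels stay
  count-like. Covariate fields that fluctuate *below* the quadrature
  resolution are a pathology for any point-sampled integral — with
  pixel-independent noise no dummy grid of practical size integrates
  `exp(beta * Z)` accurately — and they are also not what the instrument
  produces.

`simulate_selective_cells()` draws an inhomogeneous Poisson pattern by
thinning from `exp(beta0 + sum beta_k z_k(u))` over the *z-scored*
channels, so planted coefficients live on the same scale as fitted ones;
`target_n` calibrates `beta0` to a desired expected count (the observed
range in comparable transects is ~70–1,500 cells per transect at ~1–4.5%
coverage). `make_feature_mask()` stamps disks (cocci), 4:1 ellipses
(rods), thin elongated shapes (filaments) and bifurcating spore-tipped
shapes (fungal features), relocating overlaps up to 100 times before
warning. `make_community_fixture()` draws Dirichlet compositions whose
concentration parameters for linked taxa scale with a substrate's element
value, planting positive taxon–element correlations.

The generator does **not** emulate: real SEM texture or charging
artifacts, spectral deconvolution, spatially varying detector gain,
cell-shaped intensity exclusion (points are ideal centroids, so the
centroid artifacts that degrade model fit for unusually large cells in
real data are absent), or between-transect heterogeneity. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every acquisition artifact.

## Calibration checks and the problem sizes they use

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` recompute, from scratch:

* the homogeneous null identity (β₀ = log n on a unit window, 500 points);
* coefficient recovery and 95% Wald coverage over 200 fresh 250 × 384 px
  grain scenes with a planted β_S = 1.5 at ~500 cells each;
* the LRT type-I rate against a pure-noise covariate over 500 CSR
  patterns (nominal 5%);
* exact recovery of the planted element by the exhaustive 31-subset
  search over 100 scenes in which only S carries the grain structure;
* the mean inhomogeneous L curve against `L(r) = r` over 100 CSR patterns
  of ~500 points (held to ±5% above the estimator resolution floor), and
  the ~2% pointwise exceedance of truth-generated patterns against
  99-simulation envelopes over repeated meta-runs;
* quadrature convergence (coefficient shift on halving the dummy spacing;
  quadrature vs pixel-resolution intensity integrals);
* the morphology identities, the SIMPER decomposition identity, the
  brute-force K oracle, and byte-identical pipeline reruns.

Window and replicate sizes are chosen so the whole suite runs in a few
minutes on one core while keeping every Monte-Carlo band comfortably
narrower than its acceptance range; they are package choices, recorded
here, not statistical necessities.

## Known limitations

* Inference is strictly inhomogeneous Poisson: no interaction (Gibbs),
  cluster, or random-effect structure. Envelopes can *detect* unexplained
  clustering or dispersion but the package does not model it.
* The KDE has no edge correction, and the L-function's border correction
  discards reference points near the boundary, losing power at large r in
  small windows.
* Stitching uses supplied offsets only; there is no registration or
  feature matching, and overlap blending (last-wins / first / mean) is an
  explicit choice because the original manual photomerge blending is
  unspecified.
* Morphology classification is unreliable below the digitization floor
  (features under ~100 px), and centroids of very large or irregular
  features can misrepresent their occupied area, degrading point-process
  fit quality — both fundamental to the raster representation, not to a
  particular estimator.
* Quadrature accuracy presumes covariates resolved by the dummy grid;
  rasters with genuine sub-tile structure need a finer `dummy_spacing_um`
  or pre-smoothing (`smooth_sigma_px`, off by default).
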