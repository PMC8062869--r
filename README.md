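# biofilmspat

Spatial point-process analysis of mineral-hosted biofilm distributions.

Rock surfaces in the deep subsurface carry biofilms whose cells cluster on
energy-rich minerals (iron sulfides, iron-titanium oxides) rather than
spreading uniformly over the silicate matrix. Given a stitched SEM/XEDS
transect — per-pixel element maps `Z_k(u)` plus curated cell centroids —
this package asks whether the cell pattern depends on the underlying
element distributions, and quantifies that *mineral selectivity*.

The core model is an inhomogeneous Poisson point process with log-linear
intensity

    lambda(u) = exp( beta0 + sum_k beta_k z_k(u) )

over standardized element channels, fitted by Berman–Turner quadrature
(the likelihood becomes a weighted Poisson regression). Covariate subsets
(up to 5 elements, exhaustively) are compared against the homogeneous null
with the ANOVA likelihood-ratio test — statistic
`deviance(null) − deviance(complex)`, chi-square reference — and the best
model is the one with the lowest p-value, highest deviance, and fewest
covariates. Goodness-of-fit uses the inhomogeneous Besag L-function
`L(r) = sqrt(K(r)/pi)` with pointwise Monte-Carlo simulation envelopes:
an observed curve inside the envelope gives no evidence against the
fitted intensity.

Around the core, the package provides tile stitching into panoramic
element maps, per-feature morphology (area, perimeter, circularity;
filament / rod / cocci classes at 0.1 and 0.7), 2D kernel-density hotspot
surfaces and contours, community statistics (taxa filtering,
taxa–chemistry correlation, Bray–Curtis, SIMPER), a seeded synthetic
generator of grain scenes / cell patterns / feature masks / community
tables with known ground truth, and a `run_pipeline()` orchestrator with a
thin command-line wrapper (`inst/cli/biofilmspat`).

## Worked example

Simulate a transect with a planted selectivity for sulfur and recover it:

```r
library(biofilmspat)

scene <- grain_scene(seed = 42)            # 500 x 768 px, Fe/S grain in Si/Al/O matrix
map   <- make_element_map(scene)
cells <- simulate_selective_cells(map, beta = c(S = 1.5), target_n = 500,
                                  seed = 43)
cells
#> Cell pattern: 471 points in a 25 x 38.4 um window

search <- model_search(cells, map)         # all 62 subsets of 6 channels
search
#> Model search: 62 subsets fitted, n = 471 cells
#>   best model: S
#>    model n_covariates df p_value     log_p deviance converged
#> 1      S            1  1       0 -909.1577 1810.361      TRUE
#> 2 Fe + S            2  2       0 -905.6142 1811.228      TRUE
#> ...
```

The planted element S is selected exactly: its single-covariate model has
the smallest tail mass (`log_p`), and every competitor that beats its raw
deviance pays for an extra degree of freedom. The deviance column is the
likelihood-ratio statistic against the null; 1810 means the homogeneous
model is untenable. Refitting the winner gives the coefficient on the
z-scored sulfur channel:

```r
fit <- fit_ppm(cells, map, quad = search$quad, channels = search$best)
fit
#> Poisson point-process model (S), n = 471
#>   loglik = 98.7933, deviance = 1247.0597, converged = TRUE
#>                beta     se
#> (Intercept) -2.8738 0.1563
#> S            1.5262 0.0558
```

`beta_S = 1.53 ± 0.06` recovers the planted 1.5: one standard deviation of
extra sulfur signal multiplies the expected cell density by
`exp(1.53) ≈ 4.6`. Finally, the model is validated by simulation:

```r
env <- envelope_L(cells, fit, n_sim = 99, seed = 44)
env
#> L-function envelope (99 simulations): observed curve inside the envelope at all r
plot(env)
```

The observed L-curve staying inside the 99-simulation envelope means the
sulfur-driven intensity fully accounts for the second-order structure of
the pattern — no residual clustering or dispersion.

The same flow runs end-to-end from a config:

```r
run_pipeline(list(seed = 17, out_dir = "out",
                  cells = list(beta = c(S = 1.5), target_n = 500)))
```

writing the element map, cell table, morphology metrics, hotspot contours,
the model-search table (`substrate, coupon, model, p_value, deviance`),
the envelope verdict and a combined `report.json`.

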