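# densdep

Density dependence across tree life stages in mapped forest plots.

`densdep` is an R package for detecting conspecific negative density
dependence — the Janzen–Connell signature of lower survival at high local
conspecific density — in fully stem-mapped forest dynamics plots, while
factoring out the habitat heterogeneity that can mask or mimic it. It is
aimed at forest ecologists working with stem-mapped census data (tag,
species, x, y, dbh) and gridded seedling censuses.

## What it computes

**Later life stages (sapling → juvenile transition).** Spatial point-pattern
analysis with grid-based estimators (1 m² cells, 3 m ring width): the pair
correlation function g(r), Ripley's K and L(r) = √(K/π) − r, case–control
random-labeling null models with adults as controls, pointwise rank
envelopes (fifth-lowest/fifth-highest of 999 simulations), and the
Loosmore–Ford goodness-of-fit test. Density-dependent thinning is read from

- *additional aggregation* a_i(r) = g_ij(r) − g_ii(r) of cases (saplings or
  juveniles, pattern *i*) relative to adult controls (pattern *j*); a_i < 0
  means cases cluster beyond what they share with adults,
- its between-stage change d(r) = a_juveniles(r) − a_saplings(r), and
- d_max, the maximum of d(r) over 0–30 m.

**Early life stage (established seedlings).** Binomial mixed models
(Laplace, `lme4`) of five-year survival with neighbourhood covariates
(quadrat seedling counts S_CON/S_HET; basal area of stems within 10 m
B_CON/B_HET), compared across the standard nine-model set by AIC, with
quadrat and species random intercepts and optional habitat covariates
(canopy openness, topographic class); plus AIC-based neighbourhood-radius
selection.

**Synthetic forests.** A generator with recorded ground truth (habitat
gradients, dispersal-limited recruitment, density-dependent thinning,
model-based seedling survival) makes the whole pipeline testable without
field data.

## Worked example

```r
library(densdep)

stand <- simulateStand(seed = 42)          # 300 x 300 m synthetic stand
selectFocalSpecies(stand$stems)            # species with >= 40 per stage
#> [1] "ABINEP" "ACEMON" "PHISCH" "PINKOR" "TILAMU"

# later stages: is the PINKOR juvenile cohort a density-dependent
# thinning of its sapling cohort, with adults controlling habitat?
res <- runThinningPipeline(stand$stems, "PINKOR", nSim = 999, seed = 1)
res
#> ThinningResult: PINKOR (controls: observed_adults)
#>   d_max = 4.74 at r = 0 m; thinning detected: TRUE
#>   sapling GOF P = 0.001, juvenile GOF P = 0.037
```

PINKOR is generated with strong density-dependent mortality (β = 0.4 within
5 m), and the pipeline recovers it: saplings are additionally aggregated
relative to adults (GOF P = 0.001), the aggregation declines by the
juvenile stage, and the decline peaks in the first annulus (d_max = 4.74 at
r = 0 m) — thinning acts at the smallest scales, as neighbour-mediated
mortality should.

```r
# early stage: nine survival models on a generated seedling census
ds  <- generateSeedlingDataset(stand, seed = 7)
cmp <- compareNineModels(ds$seedlings, level = "community")
cmp
#> ModelComparison (whole): best fit = model 9
#>  model df     aic converged
#>      1  4 7251.13      TRUE
#>      ...
#>      9  8 7210.81      TRUE
bestFit(cmp)
#> ModelFit: model 9, n = 5815, logLik = -3597.41, AIC = 7210.8
#>         term estimate     se      z        p
#>  (Intercept)   0.7623 0.0806  9.461 3.05e-21
#>            H   0.2884 0.0335  8.611 7.22e-18
#>        S_CON  -0.1199 0.0334 -3.588 3.33e-04
#>        S_HET  -0.0763 0.0348 -2.193 2.83e-02
#>        B_CON   0.0244 0.0341  0.715 4.75e-01
#>        B_HET   0.1904 0.0352  5.404 6.50e-08
```

The full model wins; the conspecific seedling coefficient is significantly
negative (−0.12, the generating truth is −0.1 on the same z-scored scale)
while taller seedlings and heterospecific basal area help survival — the
classic early-stage density-dependence pattern.

A published worked-example table of thinning curves ships with the package
(`exampleThinningTable()`); `findDmax()` on its rows reproduces the
printed d_max locations, e.g. 58.1 at r = 0 m for *Pinus koraiensis*.

A thin command-line wrapper for simulation and both analyses is in
`inst/scripts/densdep.R`.

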