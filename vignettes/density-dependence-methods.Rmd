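---
title: "Methods: detecting density dependence across tree life stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting density dependence across tree life stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densdep)
```

## The scientific problem

Negative conspecific density dependence — lower survival where a species is
locally dense, as predicted by the Janzen–Connell mechanism — is a leading
explanation for tree species coexistence. Detecting it in a mapped forest
stand faces two obstacles. First, different life stages demand different
methods: seedlings die quickly enough to model survival directly, while
trees outlive any census interval, so density-dependent mortality must be
read off the *spatial* imprint it leaves as a cohort moves from one size
class to the next. Second, habitat heterogeneity confounds both analyses: a
species concentrated in its preferred habitat shows high local density *and*
high survival there, masking density-dependent mortality.

`densdep` implements a two-stage analysis that addresses both obstacles:

1. **Later stages** (sapling → juvenile transition): case–control spatial
   point-pattern statistics in which adults of the same species serve as
   controls, cancelling shared habitat structure.
2. **Early stage** (established seedlings): binomial mixed models of
   five-year survival with conspecific and heterospecific neighbourhood
   covariates, compared across the standard nine-model set by AIC, with
   habitat covariates available as controls.

Because census data of this kind are rarely redistributable, the package
ships a synthetic-forest generator that reproduces the statistical
structure the analysis assumes, with recorded ground truth; every stage of
the pipeline is tested against it.

## Later-stage analysis

### Summary statistics

All second-order statistics use the grid-based estimator family: around
each focal point, neighbours are counted in annuli `[r − w/2, r + w/2]`
(ring width `w`, default 3 m; scale r = 0 denotes the first annulus
`[0, w/2]`), and the annulus area is the number of 1 m² grid cells whose
centres fall inside both the annulus and the window. This cell-count
normalization handles plot edges without an isotropic correction and is
the convention used by grid-based point-pattern software in this field.
Points are kept at continuous coordinates; only the area normalization is
discretized, which avoids double-binning error while honouring the 1 m²
resolution. One consequence worth knowing: the cumulative `K` estimator can
show sub-percent non-monotone ripple at cell granularity.

The pair correlation function is estimated as

$$\hat g(r) = \frac{\sum_i C_i(r)}{\hat\lambda_j \sum_i A_i(r)},$$

with `C_i` the neighbour count and `A_i` the in-window annulus area around
focal point `i`. For the neighbour intensity we use
`λ̂_j = n_j / |W|` in bivariate mode and `λ̂ = (n − 1) / |W|` in univariate
mode — the conditional-on-n choice under which `E[ĝ] = 1` holds exactly for
a binomial (fixed-n) CSR pattern, and under which the random-labeling
permutation expectation of the case–control contrast below vanishes to
first order. `K̂(r)` applies the same area logic to discs,
`K̂(r) = πr² · Σ C_i / (λ̂ Σ A_i)`, and `L(r) = √(K/π) − r`.

Deliberately naive `O(n²)` pure-R oracles (`pcfBruteForce()`,
`lBruteForce()`) re-implement the identical normalization with explicit
loops over points and grid cells; the test suite requires agreement with
the fast path to 1e−9, and checks the estimator against the closed-form
pair correlation function of the Thomas cluster process,
`g(r) = 1 + exp(−r²/(4σ²))/(4πσ²ρ)`. Because a ring-width-w estimator
targets the annulus *average* of g rather than its pointwise value — a
distinction that matters when σ is comparable to w — the comparison uses
the exact ring average (`thomasPcfRingAverage()`),

$$\bar g(r) = 1 + \frac{e^{-l^2/4\sigma^2} - e^{-h^2/4\sigma^2}}
{\rho\,\pi\,(h^2 - l^2)}, \qquad l = \max(r - w/2, 0),\; h = r + w/2.$$

### Null models, envelopes, and the goodness-of-fit test

Habitat screening tests each species' adult pattern against conditional
(fixed-n) CSR with the L function; fixed-n simulation keeps envelopes
comparable to the observed pattern size. Aggregation at scales beyond
10 m, where direct tree–tree interaction is assumed negligible, is read as
habitat heterogeneity.

Envelopes are pointwise rank envelopes: the k-th lowest and k-th highest
of `nSim` null simulations per scale (defaults k = 5, nSim = 999 — the
extreme 0.5 % at either end). Because pointwise envelopes inspected across
many scales understate the type-I error, every inference is screened by
the Loosmore–Ford goodness-of-fit statistic

$$u_k = \sum_{r \in R} \left(H_k(r) - \bar H_{-k}(r)\right)^2,$$

where `H̄_{−k}` is the leave-one-out mean over all other functions; the P
value is the top-down rank of the observed `u` among all `u` values
divided by `nSim + 1`, with ties resolved toward the larger P. Scales at
which any function is undefined are dropped from the sum. Under
exchangeability this P is exactly discrete-uniform, which the test suite
verifies. The default screening threshold is P < 0.005 with 999
simulations; at reduced simulation counts (tests use 199) the attainable
minimum is 1/(nSim+1), so a matching threshold must be supplied — the
functions take both as arguments.

### The case–control thinning statistic

For a focal species, cases `i` (saplings, then juveniles) are compared
with controls `j` (adults) through the additional-aggregation statistic

$$a_i(r) = g_{ij}(r) - g_{ii}(r).$$

Pair correlation functions are invariant under independent random
thinning, so if cases were a random thinning of the joint process —
whatever habitat structure that process carries — all four pair
correlation functions would coincide and `a_i(r) = 0`. A significantly
negative `a_i(r)` means cases cluster among themselves beyond the
clustering they share with adults. Inference permutes the case/control
labels over the fixed joint locations (`randomLabelPermutation()`); scales
where the observed `a_i` falls below the lower envelope are classified
*additional aggregation*, above the upper envelope *regular*, otherwise
*random*.

Density-dependent thinning over the sapling → juvenile transition is the
decline of additional aggregation between stages,

$$d(r) = a_{\text{juveniles}}(r) - a_{\text{saplings}}(r),$$

with `d_max`, the maximum of `d(r)` over 0–30 m (ties broken toward the
smallest scale; missing scales propagate), as the strength-of-thinning
summary. A species is called *thinning* when (i) its sapling GOF P value
over 0–10 m is below the screening threshold, and (ii) at some scale
within 0–10 m the saplings are classified as additionally aggregated while
`d(r) > 0` there. The conjunction of envelope excursion and GOF screening
is our operationalization of "significant"; the source method combines
both devices without stating the conjunction explicitly.

Setting `controlMode = "randomized_adults"` replaces the adult controls
with a fresh conditional-CSR draw of the same size, removing the habitat
control; comparing the two modes shows how unmodelled heterogeneity
displaces apparent thinning toward larger scales.

### A known limitation of the sign rule

The per-scale rule "saplings aggregated and `d(r) > 0`" has no
false-positive control of its own: for a species whose cohorts are
genuinely aggregated but differ only by *density-independent* mortality,
`d(r)` is symmetric noise around zero, and with ~11 scales in play some
aggregated scale will show `d > 0` almost surely. The guarantee the
machinery does provide is at the screening stage: when the stages are
random labels of one process, the sapling GOF screen passes at most at its
nominal rate, bounding the thinning call rate. The calibration tests
exercise exactly that null; the power tests use strong constructed
thinning where `d > 0` is systematic. Users should read `d_max` as an
effect-size summary within screened species, not as an independently
tested hypothesis.

## Early-stage analysis

### Covariates

For each focal seedling: `S_CON`, `S_HET`, `S_TOTAL` count conspecific,
heterospecific and all seedling neighbours in its 4 m² quadrat (focal
excluded); `B_CON`, `B_HET`, `B_TOTAL` sum the basal area
(`π (dbh/200)²` m², dbh in cm) of stems ≥ 1 cm dbh within a neighbourhood
radius of the quadrat centre (default 10 m, strict exclusion beyond).
Neighbourhoods crossing the plot boundary are used truncated, without edge
correction — the convention that keeps every seedling in the analysis.
`selectNeighborhoodRadius()` re-fits the full model over candidate radii
(5, 10, 15, 20 m) and picks the AIC minimizer, smaller radius on ties.

### The nine models

Survival over the five-year interval (alive at first and final census;
intermediate censuses validate monotonicity; seedlings that crossed the
1 cm dbh threshold are scored as survivors and flagged) is modelled
per-seedling as Bernoulli with logit link. The nine fixed-effect
structures are the standard set: (1) height only; (2–4) pooled neighbour
terms `S_TOTAL`/`B_TOTAL`; (5–9) conspecific and heterospecific terms
separated in all combinations. All models carry a quadrat random
intercept (quadrats are 10 m apart, which absorbs residual spatial
autocorrelation); community-level models add a species random intercept.
With habitat controls on, canopy openness and topographic class enter as
fixed effects at the species level, and additionally as independent
species-varying effects (a random openness slope and a species ×
topography intercept, diagonal covariance) at the community level.

Fits use Laplace-approximated maximum likelihood (`lme4::glmer`,
`nAGQ = 1`). Continuous predictors are z-scored by default (the scaling is
recorded in the fit; raw-scale fitting is a flag) — coefficient magnitudes
are then comparable across covariates of very different units.
AIC = 2k − 2·logLik with k counting fixed effects *and* variance
components; comparisons select the minimum-AIC converged fit, ties toward
fewer parameters. The convergence flag is honest: optimizer failures and
convergence warnings exclude a fit from selection (with a warning), while
boundary (singular) variance estimates do not — a variance legitimately
estimated at zero reduces the model to its fixed-effect core, which the
test suite verifies against plain logistic regression.

Species-level analyses follow the abundance rule of at least 100 seedlings
of the species. Wald z with two-sided α = 0.05 marks significance in the
coefficient tables.

## The synthetic forest

The generator reproduces the processes the analysis assumes, each with
recorded truth:

* **Habitat surfaces** — adults are rejection-sampled against
  `exp(γ x / x_max)` (monotone gradient) or a two-patch good/bad surface;
  γ = 0 is CSR. Two qualitatively different surfaces guard against tests
  overfitting one form.
* **Dispersal-limited recruitment** — Poisson(μ) offspring per focus,
  isotropic Gaussian σ displacements. Recruitment foci are drawn from the
  *same* habitat surface as the adults but independently of their exact
  locations. This choice is deliberate: centring recruits on the surviving
  adults themselves would make the parent–offspring cross correlation
  exceed the sibling correlation (Thomas-process peaks
  `1/(2πσ²ρ)` vs `1/(4πσ²ρ)`), flipping `a_i` positive — the opposite of
  the additional-aggregation signature real dispersal-limited recruitment
  leaves, because in a real stand the current survivors are not the
  centres of the current recruit clusters. Decoupled foci preserve
  clustered recruits, shared large-scale habitat structure (which the
  case–control design then cancels), and `a_sap < 0`.
* **Density-dependent mortality** — each point of a cohort survives with
  probability `π₀ exp(−β D_i)`, `D_i` the number of conspecific
  cohort-mates within ρ (default 5 m, so maximum thinning lands at small
  scales). β = 0 is uniform thinning. The default stand spans β from 0 to
  0.4 across five species of different growth forms, σ of 2–4 m, and adult
  counts (80–180) that keep all stages above the 40-stem focal rule.
* **Seedling survival** — 900 quadrats on the 10 m lattice (4 m² plots in
  subplot corners), a Poisson number of seedlings per quadrat (default
  mean 6.4, ≈ 5,800 seedlings), species drawn from the local stem
  composition, and survival from the full model's linear predictor applied
  to the z-scored covariates — computed by the same
  `computeNeighborCovariates()` the analysis uses — plus quadrat and
  species random intercepts. Default truth (intercept 0.9, height effect
  0.3, conspecific seedling effect −0.1, heterospecific basal-area effect
  0.1, random-effect SDs 0.6) gives ≈ 30 % five-year mortality with a
  positive height effect and a weak conspecific penalty, magnitudes in
  line with temperate seedling-bank studies.

What the generator does *not* emulate: multi-year demographic dynamics
(one survival interval only), interspecific spatial interactions,
non-Gaussian dispersal, soil or moisture covariates, and measurement
error in coordinates. Passing tests therefore demonstrate that the
*methods* recover known structure of the kinds listed above, not that any
particular field system satisfies the assumptions.

## Numerical choices and problem sizes

* Annuli are `(lo, hi]` in squared distance; the first annulus includes
  distance zero exactly. The fast path and the oracles share this
  convention bit-for-bit.
* Relabeling envelopes reuse the precomputed pair-bin matrix and per-point
  annulus areas of the joint pattern (locations are fixed under the null),
  making 999 relabelings cheap; the counting kernels are C++.
* Ties in `u` ranks resolve toward the larger P; ties in `d_max` toward
  the smallest scale; ties in AIC toward fewer parameters (models) or the
  smaller radius (neighbourhoods).
* Degenerate inputs error early with informative messages: fewer than two
  points for univariate statistics, mismatched windows or scale grids,
  all-missing `d`, labels with fewer than two points on either side.
* The test suite scales simulations to what the properties need rather
  than to the source study's sizes: reduced simulation counts (99–199)
  with matching screening thresholds for calibration loops, 20–50 seeds
  for power and recovery experiments, ~5,000-seedling datasets for the
  mixed-model recovery runs. The acceptance script's envelope-calibration
  quantity uses the full 999 simulations and 2,000 fresh draws.

## Known limitations

* The `d(r) > 0` sign rule is an effect-size convention, not a test (see
  above).
* Wald intervals from Laplace fits are slightly anticonservative with few
  random-effect levels (e.g. 10 species); intercept coverage sits near
  the nominal boundary in the recovery experiments.
* Inhomogeneous (intensity-reweighted) second-order statistics are out of
  scope; the case–control design is the heterogeneity control.
* Rectangular windows only; no GIS support.
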