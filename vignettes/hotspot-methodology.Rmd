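---
title: "Trait-weighted hotspot delineation: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-weighted hotspot delineation: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefhotspots)
```

`reefhotspots` turns raw multi-method reef-survey observations into
decile-ranked biodiversity hotspot maps on a planning-unit grid, and models
where hotspots occur along depth and oceanographic gradients. This vignette
documents the statistical models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the choices we made
where the methodology left room.

## The abundance model

Counts $C_{t,i,l}$ of taxon $t$ by method $i$ at sampling event $l$ are
modelled as zero-inflated negative binomial with log link:

$$\log \mu_{t,i,l} = \beta X_{t,i,l} + b_u + \log E_l, \qquad
b_u \sim N(0, \sigma_u^2),$$

where $X$ holds the intercept and optional taxon, survey-method and
depth (linear and quadratic, per m and per m²) covariates, $b_u$ is a
planning-unit random intercept controlling for repeated sampling of the
same unit, and the log-effort offset makes $\beta$ describe abundance *per
unit of effort* (m² surveyed for visual methods, minutes fished for
hook-and-line). The negative binomial variance is
$\mu + \mu^2/k$; the zero-inflation component is a constant logit-scale
mixture probability. Sponge percent-cover categories are modelled with a
beta likelihood on the logit scale instead.

Assumptions worth stating explicitly:

- a *single* random-intercept level (the 1-km² unit); no spatial covariance
  beyond it, and no temporal structure — the analysis targets spatial
  variability, and most units are sampled in a single year;
- effort acts proportionally on expected counts (the offset contract:
  doubling effort doubles the expectation), which the tests verify;
- counts are assumed already corrected for method-specific detection biases.

Candidate models (nested covariate sets, each with and without zero
inflation) are fitted by maximum likelihood with the unit intercept
integrated out by the Laplace approximation (`glmmTMB`), and the
minimum-AIC converged candidate wins. Covariates with a single observed
level in a data subset (e.g. survey method among deep-video-only sponge
counts) are dropped from the candidate set because their contrasts are
inestimable. Predictions $\lambda_{t,i,l}$ use the *conditional modes*
$\hat b_u$ — we standardize abundance within the sampled units rather than
for a hypothetical average unit — and are multiplied by $1-\hat\pi$, the
estimated structural-zero probability. A marginal (population-level)
alternative would shrink all units toward the mean and change only the
scale, not the ranking, of unit-level indices.

### Cover categories and the beta likelihood

Field protocols record sponge cover in five categories
(0 = 0 %, 1 = 1–25 %, 2 = 26–50 %, 3 = 51–75 %, 4 = 76–100 %). The beta
likelihood needs a continuous response on (0, 1), so categories are mapped
to interval midpoints (0, 0.125, 0.375, 0.625, 0.875) and compressed by
$(y(n-1)+0.5)/n$ — the standard transformation for boundary-valued
proportions. The cover model carries **no** effort offset: percent cover is
already an area-standardized response, and a logit-scale offset would have
no likelihood justification; effort still enters the index through the
denominator of the per-unit standardization.

## Validity filtering

Excess zeroes that a gear could never have produced are removed before
fitting. The rules, in order of precedence: a detection always validates
the (taxon, method) pair; hook-and-line is never valid for undetected
corals, sponges, or planktivorous Sebastidae; an undetected Sebastidae zero
is valid only if the method's sampled depth span (its pooled 10th–90th
percentiles, computed over events) *encompasses* the species' expected
depth range; an undetected coral or sponge zero is valid only if the event
depth is at or below the taxon's minimum expected depth. We read
"encompasses" literally as full containment; because the verb is the only
guidance available, a `rule = "overlap"` flag relaxes it to interval
intersection so the sensitivity of the filter can be inspected. Percentiles
are computed over events rather than over metres surveyed — the event is
the sampling unit everywhere else in the pipeline.

## Conservation weights

Sebastidae weights combine four components with maxima $x = (4, 4, 2, 2)$:
vulnerability and depletion may contribute twice as much as trophic role
and evolutionary distinctiveness because the fauna includes extremely
long-lived, depleted species. Components with missing proxies drop out of
numerator and denominator alike, keeping $W_t \in (0,1]$ comparable across
species with unequal data coverage. Extrema (e.g. $\max(1/r)$) are computed
within the analyzed species set — the observed species, since weights are
only consumed for taxa that enter the index. Depletion ratios above 1
(stocks above unfished biomass) are clamped to 1 with a warning so the
depletion score stays non-negative. A trophic-level column with zero range
carries no information and is dropped (with a message) rather than mapped
to an arbitrary constant. Ties at extrema are left as ties.

## From abundance to hotspots

Per unit, $\mu_{t,i,u} = \sum_l \lambda_{t,i,l} / \sum_l E_{t,i,l}$, then a
min–max rescaling across units within each (taxon, method) puts methods
with different fields of view on a common [0, 1] scale. A zero range (all
units identical) is mapped to 0 everywhere: no spatial information means no
hotspot signal, and the alternative (0/0) is undefined. Group indices
average $\mu'$ over the methods valid for the group in that unit and sum
over taxa with weights $W_t$; the overall index multiplies the summed group
indices by Shannon's evenness $H$ (natural log, normalized by $\ln 3$ so
$H \in [0,1]$ and the log base cancels; $0\ln 0 = 0$), rewarding units
where all three groups co-occur.

Decile ranks use ordinal ranks with averaging for ties, sliced as
$\lceil 10r/N \rceil$. With heavy ties (many zero-index units) entire
blocks share a rank, which reproduces the strongly nonlinear rank–value
relationship such indices show in practice; the exact tie-break the field
studies used is not documented, so ours is declared rather than inferred,
and the sliced-rank rule keeps the hotspot fraction at approximately 20 %
(ranks 9–10) by construction. Corals use rank 10 only because their index
is near zero outside the very best units. At the 16-km² scale each parent
scores $(\max + \text{mean of the rest})/2$ of its children, and ranks are
recomputed among parents: normalization and ranking happen independently at
each scale.

## Occurrence models

Hotspot occurrence within 1-km² units is modelled by logistic regression
on the maximum depth sampled in the unit (raw, not orthogonal, polynomial —
the coefficients stay interpretable per m and per m², and the peak depth is
the vertex $-\beta_1/(2\beta_2)$, reported only when $\beta_2 < 0$ and the
vertex lies inside the observed depth span) and subregion with Mainland
Fjords as the reference level. Subregions with no recorded hotspots are
excluded: their contrast is infinite under maximum likelihood. If the
remaining data are still separable, the model refits with Firth's
penalized likelihood (bias-corrected score equations), which keeps
estimates finite; the fit is flagged. The published coefficient table
bundled in `inst/extdata` supplies worked-example inputs for the vertex and
odds-ratio arithmetic; odds ratios take an explicit direction argument
because a published odds-ratio column may mix $e^{\beta}$ and $e^{-\beta}$
conventions across rows.

## The synthetic-data generator

The generator is first-class, tested code: it draws survey designs and
observations with exactly the structure the analysis assumes, so every
stage can be checked against known truth.

What it emulates: four survey methods with their real operating depth
ranges and effort scales (dive belts of 120 m², video bins uniform on
75–130 m², hook-and-line sessions of 15 or 30 min); three subregions whose
depth profiles differ (only the fjord-like subregion exceeds 200 m);
planning units nested 4-to-1 in parents; right-skewed per-unit sampling
intensity (1 + NegBin(mu = 3.2, size = 1.2), median 3 samples, quartiles
2–6); unimodal quadratic depth responses; log-scale method and subregion
biases; shared-within-group unit random intercepts (drawn once per
taxonomic group and unit, matching the fitted model's single
random-intercept structure); overdispersed, zero-inflated counts; and
beta-distributed cover binned by the half-open category partition
((0, 0.25], (0.25, 0.5], …; exact 0 is category 0).

What it does not emulate: spatial autocorrelation beyond the unit
intercept, bathymetry, tides, visibility, observer effects, temporal
trends, or detection biases. Passing tests therefore demonstrate that the
pipeline recovers what it assumes — not that the assumptions hold for any
particular real seascape.

The default scenario (`default_scenario()`) uses 120 units, six Sebastidae
species with depth optima from 40 to 250 m, three corals, one pooled
sponge group, dispersion $k = 1.2$, zero inflation 0.1, and unit SD 0.4 —
moderate overdispersion and repeat-sampling correlation typical of reef
count surveys. Expected depth ranges are derived from the generating
curvature (the span within two log-units of each taxon's optimum), which
is what a field guide's "expected depth range" conveys.

## Numerical choices

- Laplace approximation (one quadrature point) for the marginal
  likelihood, the default of the estimation ecosystem this field uses; the
  test suite cross-checks it against 41-node adaptive Gauss–Hermite
  integration of the same likelihood on high-information tiny instances,
  where the two must agree to $10^{-4}$.
- Non-convergence and singular fits (random-intercept SD below $10^{-4}$)
  set flags instead of raising, so AIC selection can skip them.
- Firth fallback iterates bias-corrected IWLS to a $10^{-8}$ step
  tolerance.
- Degenerate inputs are resolved conservatively: zero min–max range → 0;
  all-zero group abundances → $H = 0$, $B_o = 0$; single-child parents keep
  their child's value.

## Testing scale

The test suite exercises parameter recovery at 100 replicates of 2 000
events across 50 units for the zero-inflated NB model, Monte-Carlo moment
checks at $n = 10^4$, and a 20-unit hand-built fixture checked against a
spreadsheet-style oracle to $10^{-10}$ — sizes at which Monte-Carlo error
is small relative to the tolerances while the suite stays quick to run.

## Known limitations

- The hotspot fraction is fixed by the decile definition, not estimated;
  the thresholds are configurable but any choice is a planning convention.
- Min–max rescaling is sensitive to the single best unit per
  (taxon, method); a dominant outlier compresses everyone else toward 0.
- Conditional-mode predictions are undefined for units never sampled; such
  units are absent from the index rather than imputed.
- The beta-cover model treats category midpoints as data; with only five
  categories the dispersion estimate is approximate.
- Weights treat trait proxies as known constants; no uncertainty is
  propagated.
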