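---
title: "Methods: population-weighted infrastructure access, inequality and health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-weighted infrastructure access, inequality and health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`infraccess` implements a complete analysis chain from gridded
infrastructure and population fields to country- or county-level access
scores, within-unit inequality, a composite classification, and
mixed-effects health-association models. This vignette is the package's
account of the underlying methods: the models, their assumptions, the
tunable parameters, the numerical conventions, and the limits of what
the synthetic test world can demonstrate.

## The mapping model

All computation happens on a regular latitude/longitude grid (nominally
0.1°), held in `grid_layer` objects that pair a value field with a
validity mask. Every reduction in the package — maxima, percentiles,
means, weighted sums — runs over valid cells only, and a derived cell
is masked only when *all* of its inputs are masked.

Seven infrastructure systems enter as per-cell facility counts:
telecommunication, energy and transport (economic); health and
education (social); water and waste (environmental). Because absolute
abundances differ by orders of magnitude (power poles vastly outnumber
hospitals), each type layer is first normalized by its maximum valid
cell, then types are aggregated into category layers by equal-weight
cell-wise means.

The environmental dimension combines the facility layer with ambient
living conditions:

$$\mathrm{Env} = 0.5\,\mathrm{CI}_{env} +
  0.5\,\frac{e^{\mathrm{Green}}}{\mathrm{Air} + \mathrm{Heat}},$$

where $\mathrm{CI}_{env}$ is the mean of the normalized water and waste
layers and Green, Air (normalized PM2.5) and Heat (normalized heat
duration) are unit-interval fields. The denominator is the exact value
of $\ln(e^{\mathrm{Air}}e^{\mathrm{Heat}})$; we evaluate it as
$\mathrm{Air}+\mathrm{Heat}$ and floor it at $\varepsilon = 10^{-6}$
(config key `env_epsilon`) because normalized layers can be exactly
zero, where the ratio form is undefined. The composite is deliberately
*not* rescaled inside the mapping stage: its scale is absorbed by the
95th-percentile normalization applied to access values downstream.

## Night-time-lights calibration

Volunteer-contributed infrastructure inventories are incomplete in
poorly mapped regions, so the socio-economic layers are recalibrated
against night-time-light radiance, a well-established socio-economic
surrogate. Over a caller-supplied mask of densely populated ("urban
plus buffer") cells, `fit_calibration()` regresses $\ln(\mathrm{NTL})$
on $\ln(I')$ by ordinary least squares and `apply_calibration()`
back-transforms

$$I = e^{b}\,(I')^{a},$$

with $I = 0$ kept at zero-infrastructure cells as a continuity
convention (the power law is undefined at zero; zero counts carry no
radiance signal either). For $a > 0$ the mapping is strictly
increasing, so cell rankings — and therefore everything downstream that
depends only on ranks — are unchanged. Cells with non-positive
infrastructure or radiance are excluded from the fit and retained in
application. One shared $(a, b)$ pair, fitted on the economic layer, is
applied to both socio-economic layers by default; `per_category_fit`
switches to separate fits. Geodesic buffering of real urban polygons is
out of scope; the mask is an input.

## Population-weighted access

Per administrative unit, access is the population-weighted mean of the
category layer:

$$IE^{k} = \frac{\sum_{i=1}^{N} P_i I_i^{k}}{\sum_{i=1}^{N} P_i},$$

so infrastructure counts in proportion to the people who live near it.
The statistic is bounded by the layer's envelope over the unit,
invariant to rescaling population within a unit, and linear in the
infrastructure argument — the property suite asserts all three. By
default, cells missing either layer are excluded from both sums;
`treat_missing_as_zero` instead keeps the population weight and scores
missing infrastructure as zero. The choice is surfaced rather than
hidden because it changes what "access" means in sparsely mapped units.

Raw $IE^k$ values are normalized by the 95th percentile over all units
of the same level and category and capped at 1. Percentiles use linear
interpolation between order statistics (`stats::quantile()` type 7),
the mainstream numerical convention; the pooling is global per level ×
category, and county-level normalization recomputes its own percentile
rather than reusing the country-level one.

## Inequality

Within-unit inequality treats per-cell population as the frequency
weight and per-cell access as the "income" analogue. Cells are sorted
by access; the Lorenz curve plots cumulative population share against
cumulative share of $\sum_i P_i I_i$, and the Gini coefficient is one
minus twice the trapezoid-integrated area under the curve. Tied access
values produce collinear Lorenz segments, so tie order is irrelevant —
a property the suite asserts — and the implementation is checked to
$10^{-12}$ against the independent pairwise-difference form
$G = \sum_{ij} p_i p_j |a_i - a_j| / (2 (\sum p)^2 \bar a_w)$ on random
weighted instances. All-zero access is defined as $G = 0$ with a note;
single-cell units are flagged.

The auxiliary index (`inequality_index()`) is half the
population-weighted relative mean absolute deviation, clipped to
[0, 1]: zero at perfect equality, approaching one as access mass
collapses onto a vanishing population share. It is a documented
stand-in with the correct endpoints and range, deliberately pluggable
(`inq_fun`), and nothing downstream depends on it.

## Classification

Per dimension, units below the 25th percentile are low (L), above the
75th high (H), medium (M) between. Values exactly equal to a threshold
are M — strict inequalities keep H and L as genuine quartile
exceedances; the convention is a package decision, documented because
either closure is defensible. The three labels joined in the fixed
order economic–social–environmental form 27 categories, grouped into
three general classes: Class I has no low dimension, Class II at least
one high *and* one low, Class III no high. Exhaustive enumeration shows
the rules partition the 27 categories into sizes 8/12/7, and that
raising any single dimension never demotes a Class I unit.

## Health-association models

At the country level, a health outcome (HALE in years; DALYs by
swapping the response column) is regressed on infrastructure access
and/or access-inequality covariates with log-population and log-GDP
controls and a random intercept for the Global North/South group:
Model I uses access covariates only, Model II inequality only,
Model III both. Estimation is REML via `lme4`.

Reporting conventions: a Kolmogorov–Smirnov test of the response
against a normal with estimated moments decides log-transformation
(applied only when KS $p < 0.05$); Levene's test on residuals across
groups decides whether heteroscedasticity-consistent standard errors
replace the model-based ones (when Levene $p < 0.05$). The sandwich is
HC1-style on the fixed effects — bread $(X'V^{-1}X)^{-1}$ with the
fitted marginal covariance $V$, meat
$X'V^{-1}\mathrm{diag}(e^2)V^{-1}X$ scaled by $n/(n-p)$ — computed in
the package because no installed routine accepts mixed-model objects;
on the ordinary-least-squares degenerate path it reproduces the
standard HC1 estimator exactly, which the test suite verifies against
an independent implementation. $R^2$ is reported as the squared
correlation between fitted and observed response (for a mixed model no
single definition is canonical; this one is stated in the output). All
p-values are two-sided and unadjusted.

A random intercept over only two groups is statistically fragile: its
variance is weakly identified and often estimated at the boundary, in
which case the fit degenerates to ordinary least squares (asserted by
test). The package emits a diagnostic and offers `group_as_fixed` as a
fallback. Two consequences for validation are worth stating. First,
the coefficient-recovery simulations check confidence-interval coverage
for the six slope coefficients, not the intercept: within any single
world the realized group intercepts are confounded with the global
intercept, so per-world coverage of $\beta_0$ is not a meaningful
quantity. Second, the robust-vs-model-based standard-error agreement
check runs on the fixed-group path, where residuals are iid by
construction; on the mixed path the two realized group offsets
contaminate the marginal residuals and the comparison mixes two sources
of noise that do not shrink with the country count.

Random-forest importance uses 500 trees per forest, refitted 100 times
under distinct derived seeds, collecting per-covariate distributions of
permutation mean-squared-error increase and node-purity increase. The
planted-signal test requires the informative covariate to rank first by
permutation importance in at least 95 of 100 runs.

Group comparisons follow the grouped-summary-table conventions:
two-sided pooled-variance t-tests with Cohen's d for North/South,
one-way ANOVA with Cohen's f ($\sqrt{\eta^2/(1-\eta^2)}$) across
regions, no multiplicity adjustment. Headline "x times higher"
statements are ratios of group means computed at printed (two-decimal)
precision by `group_mean_ratio()`.

## The synthetic world

`generate_world()` builds a fully synthetic study world with known
ground truth: a rectangular tiling into countries and counties;
log-normal population around per-country cluster centres; per-type
infrastructure counts drawn negative-binomially around
$\mathrm{abundance}_t \cdot (P/\bar P)^{\kappa}$, where the
concentration exponent $\kappa$ is the inequality knob ($\kappa = 0$
gives spatially uniform expected counts — the equality extreme — and
increasing $\kappa$ provably raises median within-country Gini in the
test suite); smooth rank-transformed ambient fields; night-time lights
as $e^{b}I'^{a}$ times log-normal noise with $(a, b) = (1.58, 5.03)$ by
default; and country health outcomes drawn from the full Model III
linear predictor with group random intercepts. Defaults — a 60 × 96
grid, 12 countries × 4 counties, abundance scales spanning 60–2000
facilities per type, negative-binomial size 20, residual sd 3 years,
random-intercept sd 2 years — were chosen once as plausible for
country-scale health panels and are not revisited per test. All
randomness is hierarchically seeded (world seed → fixed per-layer child
seeds), so regenerating one layer never perturbs another and equal
seeds give bit-identical worlds.

`generate_health_data()` is the fast path for repeated
coefficient-recovery simulation: it draws country tables directly from
the health law (covariates independent of group, intercepts realized
per call) without building grids. The recovery study in the acceptance
suite runs 500 replicates at 160 countries; the acceptance script
reports the same quantity from 300 replicates — sizes chosen to make
the Monte-Carlo error on a 95% coverage estimate about one percentage
point.

What the synthetic world does *not* emulate: real geography (country
shapes, coastlines), spatially structured mapping completeness bias,
travel-time accessibility, or human mobility. Passing tests demonstrate
that the estimators recover what this generator encodes — correct
formulas, correct weighting, nominal coverage — not that the empirical
conclusions of any real-world analysis are reproduced. Published
headline numbers derived from the real global rasters are shipped only
as reference inputs (`reference_group_summary()`,
`reference_model_coefficients()`) for ratio and worked-example
arithmetic, never as test oracles for the synthetic pipeline.

## Sensitivity remap

The literature does not classify water and waste systems consistently;
they are often treated as economic assets. The sensitivity variant
(`sensitivity_remap = TRUE`, or `--sensitivity-remap` on the command
line) moves water into the economic category and waste into the social
category — water networks being closer to utility/economic
infrastructure and waste services to public sanitation. With no
facility types left in the environmental category, the environmental
composite then consists of the ambient term alone. Only
category-dependent outputs change; simulated inputs are untouched
(asserted by a pipeline test).

## Pipeline and reproducibility

`run_pipeline()` executes
`simulate → build-layers → calibrate → exposure → inequality →
classify → regress → report`, exchanging plain-text artifacts (ESRI
ASCII grid rasters, CSV tables) under one output directory, with a JSON
manifest recording the config hash, seed and per-stage outputs. A stage
whose outputs are current under the same config hash is skipped; two
runs with identical config and seed produce byte-identical CSVs. All
decisions above — $\varepsilon$, percentile convention, boundary
closure, pooling, calibration sharing, missing-data handling — are
config-visible with the defaults stated here.

## Known limitations

- The auxiliary inequality index is a stand-in, not a reproduction of
  any published formula; conclusions should rest on the Gini.
- Rasters travel as single-band ESRI ASCII grids in geographic
  coordinates; arbitrary reprojection and non-integer resampling ratios
  are unsupported (alignment expects a shared origin and integer cell
  ratios).
- The two-group random intercept is retained for fidelity to the model
  specification, but with two groups it is close to a fixed offset;
  variance estimates for it should not be interpreted.
- Access is physical proximity weighted by residence; no travel-time,
  network, or mobility notion of accessibility is modelled.
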