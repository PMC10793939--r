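---
title: "Methods: mortality convergence clubs from abridged life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mortality convergence clubs from abridged life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortclubs)
```

This vignette documents the models, numerical conventions and design
choices behind `mortclubs`, in the spirit of a model-methods appendix. It
states no empirical result beyond what the package's test suite and
acceptance script compute.

## Data model

The unit of analysis is an **abridged mortality schedule**: per-age-group
death probabilities `q(x,n)` for one country, sex and 5-year period, on the
WPP-style grid — under 1, 1–4, then 5-year groups to 95–99 and an open
100+ group (22 groups). Periods are labelled by their lower endpoint
(1990–1995 is stored as 1990), sexes are analysed separately throughout
(no combined category), and the open group's probability is 1 by
construction. The one permitted imputation mirrors practice with WPP-style
extracts: a missing open-group value is copied from the 95–99 group
(`fill_terminal_group()`); a missing value anywhere else fails fast, since
no defensible single-cell rule exists for interior ages.

## Life-table construction

`life_table()` follows the standard abridged procedure. The only free
quantities are the `a` values (average years lived in the interval by those
dying in it): `a0 = 0.3`, `a(1-4) = 1.5`, `span/2` for other closed groups
and `a = 2.5` in the open group, so its person-years are `L = 2.5 l`. These
are the conventional constants for abridged tables; they are configurable
via `a_rules()` because sources differ and because the modal age and
percentile indicators in high-mortality populations are mildly sensitive to
them. The radix defaults to 100 000; every indicator is radix-invariant
(tested). An interior `q = 1` is tolerated: survivorship is zero-filled
below it and `e` is reported as 0 with a `defined = FALSE` flag rather than
`NaN`.

## The nine indicators and their conventions

All dispersion indicators are computed from one shared object, the
conditional distribution of age at death (`death_ages()`): a point mass per
age group at the representative death age `start + a`, weighted by the
group's share of deaths among survivors to the conditioning age. Two
conventions deserve explicit statement:

* **Point mass vs uniform spread.** Moments (modal age, Gini, SD) treat
  within-group deaths as a point mass at `start + a`, consistent with the
  `L` column; percentiles instead invert the survival curve with linear
  interpolation of `l` (deaths uniform within the group), consistent with
  the survival-curve definition of "the age by which a fraction p have
  died". The two readings differ by known closed-form terms — uniform
  spread adds `span²/12` to a variance and `span/3` to same-group pairwise
  differences — and the test suite verifies agreement with an independent
  fine-grid (0.01-year) simulation oracle *net of exactly those terms*.
* **Absolute ages for the Gini.** The Gini index conditional on surviving
  to 65 divides by twice the mean **absolute** age at death (not remaining
  years). Lifespan inequality is about length of life; the remaining-years
  variant would roughly triple `G65` and can be obtained with
  `gini_index(..., absolute = FALSE)`.

Modal age at death is the midpoint of the group with most life-table
deaths (representative age for the open group), ties broken toward the
youngest group so results are deterministic. The indicator is
**discontinuous** in the underlying schedule: as infant mortality grows,
the argmax jumps from the old-age peak to the infant group. This matters
for clustering (below).

A percentile whose crossing would fall inside the open group is returned
as the open group's representative age (102.5 under defaults) and flagged
censored — the abridged data carry no information beyond that point.

## Logit Lee–Carter fitting and extrapolation

The forecasting model is `logit q_{x,t} = α_x + β_x κ_t` with Σβ = 1 and
Σκ = 0, fitted per country and sex over the closed age groups only.
Estimation is Gaussian maximum likelihood on the logit scale, i.e. `α` is
the per-age mean logit and `(β, κ)` the leading singular component of the
centered logit matrix. Abridged WPP-style tables carry neither death counts
nor exposures, so a binomial likelihood cannot be weighted honestly;
Gaussian-on-logit is the defensible reading, and the rank-1 step is
verified against an independent power iteration and against random rank-1
candidates in the tests. Because each age row is centered, κ sums to zero
automatically (to machine precision); β is normalised to unit sum.
Probabilities are clamped to `[1e-7, 1 − 1e-7]` before the logit (zero `q`
in young ages of low-mortality populations would otherwise break the
link); clamp counts are recorded on the fit object.

κ is extrapolated by the centre of an ARIMA forecast. The candidate grid
is deliberately small — `p ∈ {0,1,2}`, `d ∈ {0,1}`, `q ∈ {0,1}` with
`p + q ≤ 1`, each with and without a drift/trend term — scored by AICc
(small-sample corrected AIC). Six observed periods cannot support order
selection at all, so series shorter than 8 points are forced to a random
walk with drift, the classical Lee–Carter extrapolation; a perfectly
linear κ then reproduces its trend exactly. Only central forecasts are
produced; prediction intervals are out of scope. Each population is fitted
and forecast independently — the package deliberately assumes each
population continues its own past experience separately, with no coherent
multi-population coupling.

## Convergence clubs

Clustering operates on the country × 9-indicator matrix for one period and
sex. Columns are z-score standardized by default: the indicators mix units
(years against [0,1] Gini values), and unstandardized Euclidean distance
would be dominated by the age-scaled columns. The procedure is
**hierarchical K-means**: average-linkage agglomerative clustering on
Euclidean distances is cut at `k`, its group centroids initialise Lloyd's
algorithm, and refinement runs to label convergence. The Lloyd loop is
implemented in-package so the within-SS trace is observable; the tests
assert monotone descent per iteration and exact agreement with
`stats::kmeans` started from the same centers. Determinism: given the
input row order the whole procedure is deterministic, cluster ids are
relabelled by descending centroid `e0` (club 1 = highest longevity), and
each club reports the member country with minimal Euclidean distance to
its centroid in standardized space.

The hierarchical initialisation is a heuristic. On small instances with
clear cluster structure it reliably attains the global within-SS optimum
(the acceptance suite verifies ≥95% against exhaustive partition search on
≤8 points with well-separated planted centers); on *unstructured* iid
Gaussian points the observed rate drops to roughly 60% — tiny unstructured
instances abound in local optima, and with unit noise the planted truth
itself is frequently not the WSS optimum. Conclusions from this package
therefore presuppose data with actual club structure, which is the use
case.

The number of clubs is chosen by majority vote of five indices: average
silhouette width (max), Calinski–Harabasz (max), Davies–Bouldin (min), the
Hartigan rule (smallest k with `H(k) ≤ 10`), and an elbow criterion (the
largest second difference of the within-SS curve). Ties go to the smaller
k; an index undefined on a given panel abstains. A winning silhouette
below 0.3 is flagged as weak structure. The elbow and Hartigan members are
deliberately conservative; on strongly clustered panels the vote is driven
by silhouette/CH/DB agreeing.

Cluster transitions between two periods are contingency counts over shared
countries; the greedy maximal-overlap alignment of target to source ids is
display labelling only and never feeds further computation.

## β- and σ-convergence

β-convergence is the classical growth-on-initial-level regression:
OLS of `log(y_t2 / y_t1)` on `log(y_t1)` with intercept, over countries
present in both periods, two-sided t-test on the slope. A significantly
negative slope is convergence, positive divergence, at each of the .01,
.05 and .10 levels. The term "β regression" in convergence analyses of
longevity is read here as this growth regression — not beta-distributed
response regression; the criterion "β < 0 means catching up" only makes
sense in the growth-regression reading. Non-positive indicator values are
dropped with a warning (their log is undefined) and fewer than 10 usable
countries is an error. The implementation is closed-form normal equations
(tested to 1e-10 against an independent oracle and against `lm`), with
exact degenerate handling: perfectly collinear growth yields p = 1 for a
zero slope, p = 0 otherwise. The full report grid attaches a Holm-adjusted
p-value column for transparency, but verdicts are per-cell, as is
conventional for these tables.

σ-convergence uses the cross-country coefficient of variation with the
**population** (divide-by-n) standard deviation; a male/female CV ratio is
attached per indicator and period because the sexes' dispersion is
routinely compared.

## The synthetic generator

`generate_panel()` draws a world of `n_regimes` latent mortality regimes
(default 5) with `countries_per_regime` countries each (default 30, so 150
countries at the scale of a global panel), two sexes and six 5-year periods
1990–2015, from exactly the generative model the Lee–Carter stage assumes:

```
logit q = α_x(regime) + u_country + sex_gap·[male] + β_x(regime)·κ_t(regime) + ε
```

with κ linear in time (regime-specific drifts, default −1.6…−0.8 per
period, faster improvement in low-mortality regimes), Σβ = 1, iid logit
noise (σ = 0.05) and country effects (σ = 0.1). Regime baselines are the
package's smooth human-like schedule — a Gompertz-type log-linear adult
rise plus an infant component decaying over childhood — shifted by
`regime_separation` (default 0.8 logit) between adjacent regimes. Because
the generator *is* the fitted model plus country effects, parameter
recovery by `lc_fit()` is a fair internal-consistency test, not evidence
about the realism of Lee–Carter for actual mortality; passing tests show
the code recovers planted structure, not that real data satisfy the model.

Two realism limitations are deliberate. First, the baseline constants keep
every regime's death distribution peaked at adult ages: the modal-age
indicator's infant/old-age discontinuity would otherwise let a single
regime straddle the flip (the sex gap and κ dynamics shift effective
levels by up to ~0.45 logit, so no flip placement between regimes is safe
across all periods and sexes), splitting one planted club in standardized
space. Real high-mortality populations *do* have infant-dominated death
distributions; the generator does not emulate them, nor crisis mortality
(HIV, conflict), cohort effects, or data-quality artefacts. Second,
regimes differ only by level shifts and drift, not age-pattern shape.
Cluster-recovery results on synthetic data are therefore best-case.

## Problem sizes and numerical choices

The test suite uses panels of 36–300 populations, 100-table oracle
batteries, 200-instance exhaustive clustering comparisons, 2000-replicate
type-I calibration and 400-replicate power checks; the full suite runs in
about two minutes on one core. Seeds are fixed in every stochastic test.
Tolerances: identity-level checks at 1e-9…1e-12, SVD/power-iteration
agreement at 1e-8, fine-grid oracle agreement at 0.5% or 0.25 years (net
of the stated convention terms), Monte-Carlo rates at the widths implied
by their binomial standard errors.
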