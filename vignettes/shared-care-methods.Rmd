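---
title: "Shared care areas, localization, and excess readmissions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared care areas, localization, and excess readmissions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedcare)
```

This vignette documents the models, parameter choices, numerical
conventions, and limitations of the pipeline. It is the place where design
decisions that were genuinely open are recorded with their rationale.

## The scientific setting

Hospitals are penalized under the Hospital Readmissions Reduction Program
when their excess readmission ratio (ERR) — risk-standardized predicted over
expected 30-day readmissions — exceeds 1. The pipeline asks whether a
hospital's ERR is associated with the *care geography* around it: shared
care areas (SCAs) are delineated from patient-flow data alone, and each
SCA's localization index (LI) measures how much of its residents' care stays
local. The analysis then relates hospital-year ERR to the LI of the
hospital's SCA, longitudinally.

## Discharge networks

Nodes are ZCTAs; the weight of the undirected edge between two ZCTAs is the
total number of ED discharges between residents of one and hospitals of the
other in a given year. Choices:

* **Undirected edges.** Flows are origin→hospital, but all three detection
  algorithms operate naturally on undirected weighted graphs, and the
  total-discharge interpretation of the link does not orient it. A directed
  network can be built (`build_network(directed = TRUE)`) for inspection,
  but detection runs on the undirected aggregation.
* **Self-loops are retained.** A patient admitted in their own ZCTA
  contributes internal weight to whatever community the ZCTA joins, and is
  trivially internal for the LI.
* **ZCTA codes are zero-padded 5-character strings** everywhere. Numeric
  round-trips through CSV readers silently drop leading zeros; every reader
  in the package normalizes on input.
* **Crosswalk strictness.** Unmapped zips are an error by default; the
  lenient mode drops them with a logged count. Silent drops would bias the
  LI denominator.

## Community detection

Three algorithms are implemented from first principles; a fourth
(degree-corrected stochastic block model) is deliberately absent, and
externally produced partitions can be injected via `read_partition()`
instead.

**Louvain** maximizes weighted modularity
$Q=\sum_c \left[w_c/W-\gamma\,(s_c/2W)^2\right]$ with resolution $\gamma=1$
by default. Local moves accept only strictly positive gains, so $Q$ is
non-decreasing over moves and levels; ties among best candidate communities
are broken by seeded uniform choice (staying put wins if it is among the
best, which guarantees termination).

**SLPA** runs speaker–listener label propagation for 100 rounds (memory
length = rounds + 1) with post-processing threshold 0.5. One deliberate
deviation from the textbook listener rule: heard labels are tallied
*weighted by edge weight* rather than by raw frequency. On discharge
networks a within-area link can carry ~20× the weight of a stray cross-area
link while the two count equally in an unweighted tally; the unweighted rule
collapses planted structure that the other two (weight-aware) algorithms
recover, so the weighted majority — the standard weighted-graph extension of
label propagation — is used. SLPA is intrinsically overlapping; the crisp
projection (highest retained memory frequency, seeded tie-break; fall back
to the overall mode if nothing clears the threshold) is required because the
LI needs disjoint SCAs.

**Two-level map equation** minimizes
$L(M)=q\,H(Q)+\sum_m (q_m+p_m)\,H(P_m)$ with strength-proportional visit
rates ($p_\alpha = k_\alpha/2W$, no teleportation), by the same greedy
local-move/aggregate scheme; only strictly improving moves are accepted, so
the codelength is non-increasing. With one module the codelength equals the
entropy of the visit rates.

All three process disconnected components independently (no move can merge
components profitably under any of the objectives); an isolated node is its
own SCA. Node visit order is a fresh seeded shuffle per pass and all
tie-breaks are seeded, so identical (network, parameters, seed) gives an
identical partition.

The test suite verifies the two objective-based searches against exhaustive
enumeration of all 4,140 set partitions of an 8-node planted graph, and all
three against planted partitions (adjusted Rand index 1) on assortative
synthetic networks. Note the map equation's known field-of-view effect: on a
small dense two-block graph with non-trivial cross-block weight, the
*globally optimal* two-level codelength can be the one-module partition —
the search is checked against the exhaustive optimum, not against an assumed
block structure.

## Localization index

For SCA $s$ in year $t$:
$LI(s,t)=\dfrac{\sum\{\text{count}: \text{origin}\in s,\ \text{hospital}\in s\}}
{\sum\{\text{count}: \text{origin}\in s\}}$.

* **Residence-based denominator** (discharges of the SCA's residents) is the
  default, the classical localization-index convention. The admission-based
  variant (denominator = discharges at the SCA's hospitals) is available via
  `admission_based = TRUE`; both phrasings of the index in the source
  literature are consistent with the residence-based reading.
* An SCA whose residents record no discharges carries an `NA` LI and its
  hospital-years are dropped (with a logged count) at panel assembly.
* Identity checked by tests: the resident-discharge-weighted mean of SCA LIs
  equals the global internal fraction, and refining a partition never
  increases that fraction.

## Panel assembly

* **Penalty definition**: ERR > 1, strict. An ERR of exactly 1 is not
  penalized.
* **Eligibility**: hospitals need at least 2 repeated measures
  (`min_years = 2`), the minimum for the longitudinal model.
* **Covariate aggregation**: SCA values are population-weighted means of
  member-ZCTA proportions (unweighted available by flag). Weighting is the
  natural choice when ZCTAs differ in population by orders of magnitude.
* Hospitals are retained when their SCA membership changes across years or
  algorithms; the SCA id is recorded per (hospital, year, algorithm).

## The GEE

Identity-link Gaussian marginal model, exchangeable working correlation,
clusters = hospitals. Numerical conventions, chosen to match the standard
moment-based GEE exactly (and verified against an independent reference
implementation to 1e-6 in the tests):

* scale $\hat\phi = \sum e_{it}^2/(N-p)$ (bias-corrected denominator);
* $\hat\alpha = \big(\sum_i \sum_{t<t'} e_{it}e_{it'} / \hat\phi\big) /
  (N_{pairs}-p)$, all within-cluster pairs; clusters of size 1 contribute
  only to the scale;
* convergence when $\max|\Delta\beta| < 10^{-8}$, at most 100 alternations;
  non-convergence sets `converged = FALSE` and warns;
* covariance is the cluster-robust sandwich $B^{-1}\!\left(\sum_i g_i
  g_i'\right)\!B^{-1}$ with $g_i = X_i'R(\hat\alpha)^{-1}r_i$; the
  model-based covariance is also stored;
* 95% CIs use the normal quantile (1.959964), matching Wald z inference;
* missing rows are dropped listwise with a logged count; rank-deficient
  designs and fewer than 2 clusters are hard errors.

A structural caveat surfaced by the synthetic design: covariates are drawn
once per SCA, so with $K$ SCAs the SCA-level covariates span at most a
$K$-dimensional space. With fewer than 6 SCAs the full 5-regressor adjusted
model is rank-deficient by construction; small-scale examples therefore fit
`li + pct_black` (the one covariate the analysis found significant), while
the full covariate set is exercised at the default 30-SCA configuration.

## Bootstrap and quartile conventions

* **Percentile bootstrap** (not BCa), 10,000 resamples and 95% level by
  default. Tests verify 92–98% empirical coverage for the median of n = 100
  normal samples at 1,000 resamples.
* **Quartile assignment** uses type-7 (R default) linear-interpolation
  cutpoints at the 25/50/75th percentiles and right-closed intervals
  (Q1 = [min, c25], Q2 = (c25, c50], ...), so values tied exactly at a
  cutpoint share the lower quartile and both extremes are included.
* **LI-change percentiles** use Hazen (type-5) midpoint interpolation,
  matching the worked hand-computation convention for these quantities; the
  negative group is labelled by magnitude (−q3 ≤ −q2 ≤ −q1 < 0), zeros are
  excluded from both sign groups, and differences are taken only between
  consecutive observed years.
* Quartile tables are computed within year by default (`per_year = TRUE`),
  with a pooled option.
* The bootstrap resamples hospital-year rows within a stratum; for the
  counterfactual table, shifted predictions are resampled (resampling before
  or after shifting coincides for the point median and differs only by
  resampling noise in the CI).

## Counterfactual predictions

Predictions are population-level linear predictions (GEE is a marginal
model; there is no cluster effect to condition on). Because the model is
linear in LI, predictions under a shift $s$ move by exactly
$\hat\beta_{li}\cdot s$, giving the affine identity
$\mathrm{median}(\text{shifted}) = \mathrm{median}(\text{baseline}) +
\hat\beta_{li}\, s$ — which is also what makes published prediction tables
desk-checkable from their printed baselines via `shifted_median()`. %Black
quartile boundaries are computed over distinct SCA-year rows and are
data-dependent, never hard-coded. Empty strata yield flagged (`n = 0`) rows.

## The synthetic generator: what it does and does not emulate

The generator plants: (i) block structure in flows — Poisson counts with
mean `within_rate` (default 20) inside a planted SCA and `between_rate`
(default 0.5) across, per (residence ZCTA, hospital) pair and year; (ii) a
linear ERR model with hospital random intercepts, using the *realized* LI
computed from the generated flows (never a shortcut), so coefficient
recovery is an honest end-to-end test; (iii) per-SCA covariates drawn
uniformly once from plausible ranges.

Defaults are the study conditions: 30 SCAs × 10 ZCTAs with 10 hospitals
each (300 hospitals), years 2012–2017, coefficients set to the adjusted
model's published values (β_li = −0.0474, β_black = 0.4128, ...), and
σ_b = σ_e = 0.05 so the exchangeable correlation is 0.5 at an ERR residual
spread comparable to published ERR standard deviations (~0.07). The %Black
range (0.002, 0.176) follows the published stratum range; the remaining
ranges are plausible state-wide spans.

What it does **not** emulate — and hence what passing tests do not show
about real data:

* hospital volume heterogeneity (hospitals are symmetric) and secular
  trends in flows or ERR;
* spatial contiguity: planted SCAs are purely combinatorial, while real
  ZCTA geography constrains flows;
* LI variation: under fixed Poisson rates the realized LI varies only by
  sampling noise (sd ≈ 0.01), far less than real LI spread — coefficient
  recovery is therefore a low-power, unbiasedness-style check, and the
  recovery criterion is interval coverage rather than point accuracy;
* the CMS ERR estimation model itself: ERR is generated directly at the
  hospital level and consumed as an input, as in the analysis.

## Problem sizes used by the tests

Chosen as the package's own test design: exhaustive searches at 8 nodes
(4,140 partitions), planted-recovery networks at 4 SCAs × 10 ZCTAs,
coefficient recovery at the full 300-hospital × 6-year study conditions over
100 seeded replicates, exchangeable-correlation consistency at 2,000
clusters, and bootstrap coverage at 500 outer replicates × 1,000 resamples.

## Known limitations

* Two-level (not hierarchical) map equation; no consensus clustering across
  algorithms — algorithms are reported separately.
* The GEE supports the Gaussian/identity/exchangeable case only — the case
  the analysis needs — with no small-sample SE corrections.
* Counterfactual tables are associational predictions, not causal effects.
* The pipeline does not model interactions between SCAs.
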