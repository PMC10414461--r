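# sharedcare

Delineation of **shared care areas** (SCAs) from hospital–patient discharge
networks, and longitudinal analysis of how the **localization index** of an
SCA relates to its hospitals' **excess readmission ratios** (ERR).

## Who this is for

Health-services researchers studying regional care coordination. Hospitals
under the Hospital Readmissions Reduction Program (HRRP) are penalized when
their ERR — predicted over expected 30-day readmissions — exceeds 1. Whether
a hospital's readmission performance reflects the *region* it is embedded in,
rather than only the hospital itself, is a question about patient-flow
geography. This package provides the full analytic pipeline:

1. **Flow networks** — yearly undirected weighted networks where nodes are
   ZCTAs (of patient residences and hospitals) and edge weights are total ED
   discharges between them (`read_flows()`, `apply_crosswalk()`,
   `build_network()`).
2. **SCA delineation** — three community detection algorithms implemented
   in-house: Louvain modularity maximization (resolution 1), speaker–listener
   label propagation (threshold 0.5), and two-level map-equation
   minimization (`louvain()`, `slpa()`, `mapeq_two_level()`,
   `detect_scas()`).
3. **Localization index** — for SCA *s*,
   `LI(s) = (discharges of s's residents at s's hospitals) / (all discharges of s's residents)`
   (`localization_index()`).
4. **Panel linkage** — hospital-year ERR joined to SCA membership, LI, and
   population-weighted SCA covariates (%Black, %Hispanic, %poverty, %private
   insurance), with a ≥2-repeated-measures eligibility rule
   (`build_panel()`).
5. **GEE** — an in-house Gaussian generalized estimating equation with
   exchangeable working correlation and cluster-robust sandwich errors,

   `ERR_it = β0 + β_li·LI_s(i),t + β_black·Black_s + β_pov·Pov_s + β_priv·Priv_s + β_hisp·Hisp_s + ε_it`,

   clusters = hospitals (`fit_gee()`, `wald_inference()`). Cross-checked in
   the test suite against an independent reference implementation to 1e-6.
6. **Quartile summaries** — median ERR and % penalized by LI / %Black
   quartiles with 10,000-resample percentile bootstrap CIs
   (`quartile_summary()`).
7. **Counterfactual prediction** — year-over-year LI-change percentiles
   (`li_change_quantiles()`) applied as shifts to the fitted model; because
   the model is linear, every prediction moves by exactly `β_li · shift`
   (`predict_shifted()`, `counterfactual_table()`).

A synthetic-data generator (`synthetic_config()`, `generate_flows()`,
`generate_panel()`, `write_synthetic_dataset()`) plants known SCA structure
(Poisson flows, within-rate ≫ between-rate) and known regression
coefficients, so every stage is testable without access to the restricted
OSHPD/HRRP/ACS extracts it emulates.

## Worked example

```r
library(sharedcare)

cfg <- synthetic_config(n_scas = 4, zctas_per_sca = 10,
                        hospitals_per_sca = 10, seed = 8)
gen <- generate_flows(cfg)
net <- build_network(gen$flows, 2012)
network_summary(net)
#> $n_nodes    40
#> $n_edges    610
#> $total_weight 8621

part <- louvain(net, seed = 17)
part
#> <sca_partition> 40 ZCTAs in 4 SCAs (algorithm=louvain, year=2012)

head(localization_index(gen$flows, part), 4)
#>   year sca_id        li resident_discharges internal_discharges
#> 1 2012      0 0.9361502                2130                1994
#> 2 2012      1 0.9252979                2182                2019
#> 3 2012      2 0.9238006                2126                1964
#> 4 2012      3 0.9280806                2183                2026
```

Louvain recovers the four planted SCAs exactly; about 93% of each area's
resident discharges stay inside it. Linking LI to the generated ERR panel
and fitting the GEE:

```r
li  <- localization_index(gen$flows, gen$partition)
pan <- generate_panel(cfg, gen$partition, li, gen$hospitals)$panel
fit <- fit_gee(pan, covariates = c("li", "pct_black"))
fit
#> Gaussian GEE, exchangeable working correlation (40 clusters, 240 obs)
#> alpha = 0.4802, scale = 0.004894, converged in 4 iteration(s)
#>             Coefficient     SE       z P value
#> (Intercept)      1.1233 0.6595  1.7034  0.0885
#> li              -0.1031 0.7068 -0.1459  0.8840
#> pct_black       -0.9862 0.6473 -1.5235  0.1280
```

The estimated exchangeable correlation (0.48) recovers the planted
within-hospital correlation of 0.5; at this small problem size the LI
coefficient is estimated with a wide interval that covers the planted value.
Counterfactual medians under LI shifts follow the affine identity
`median(shifted) = median(baseline) + β_li · shift` exactly — e.g. a
published baseline median ERR of 0.995 with `β_li = -0.0474` under an LI
drop of 0.167 gives

```r
shifted_median(0.995, -0.0474, -0.167)
#> [1] 1.002916   # printed as 1.003
```

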