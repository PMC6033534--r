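# tscmdyn

Mechanistic models of human stem cell-like memory T (TSCM) cell dynamics.

TSCM cells are hypothesised to maintain long-lived T-cell memory by
self-renewing and feeding downstream memory subsets. Whether their in-vivo
kinetics are compatible with that role is a quantitative question, and it
cannot be answered from stable-isotope labelling alone: very different
scenarios (replacement by naive-cell differentiation versus self-renewal)
produce similar label curves. `tscmdyn` implements a framework that
combines three data types in one inferential loop:

* **deuterium (heavy-water) labelling** of naive and TSCM cells — fractions
  of labelled DNA over ~300 days after a 7-week labelling period, driven by
  the measured body-water enrichment curve
  `U(t) = f_r (1 − e^{−δ_w t}) + β e^{−δ_w t}` (washing out after cessation);
* **telomere lengths** — the mean difference Θ (bp) between TSCM and naive
  pools counts excess divisions at δ = 50 bp/division, with telomerase
  compensation `C ∈ [0, k]`;
* **a vaccine cross-section** — antigen-specific TSCM frequencies 0.27–35
  years post-vaccination, modelled as the biexponential
  `F(t) = A [r e^{−αt} + (1 − r) e^{−βt}]`.

The label kinetics follow a linear naive → TSCM differentiation model with
clonal bursts of `2^k` cells per recruited naive cell. Three nested
variants are provided: *homogeneous* (labelled-DNA loss tied to the pool's
replacement rate), *implicit heterogeneity* (loss rate `d_s*` free), and
*explicit* two-subpopulation (fast and slow pools, fractions `1 − f` and
`f` of each burst). Key derived quantities are the clonal half-life
`ln 2 / (d − p)` — the duration of memory, not the population-replacement
half-life — and the degree of self-renewal `1 / (d − p)`.

The package provides:

* exact exponential-sum solutions of the label ODEs (C++-backed), with
  fixed-step Euler and `deSolve` oracles in the test suite;
* simultaneous multi-dataset least-squares fitting with seeded
  Latin-hypercube multi-start optimisation (`fit_model()`), nested-model
  F-tests (`test_homogeneity()`, `f_test_nested()`, `pool_pvalues()`),
  clonal-expansion scans (`k_scan()`), constrained fits
  (`constrained_fit()`), and parametric-bootstrap or profile confidence
  intervals (`confidence_intervals()`);
* exact Gillespie birth–death simulation of antigen-specific clones
  (`simulate_clone()`, `precursor_lifespan_distribution()`);
* a synthetic-study generator with known ground truth
  (`generate_study()`), closed-loop recovery and calibration experiments
  (`recovery_experiment()`, `homogeneity_type1_experiment()`,
  `ci_coverage_experiment()`), and a CSV pipeline
  (`read_study()`, `run_pipeline()`).

## Worked example

```r
library(tscmdyn)

study <- generate_study(default_truth(), study_design(), seed = 42)

fit_water(study$saliva)[1:2, ]
#> # A tibble: 2 × 8
#>   subject_id    f_r delta_w   beta_s   tau       rss n_points note
#> 1 S01        0.0475  0.0625 0.00361     49 0.0000402       12 ""
#> 2 S02        0.0430  0.0742 0.000454    49 0.0000673       12 ""
```

Per-subject body-water plateaus of ~4–5% enrichment with turnover ~0.06–0.07
per day. Is the TSCM pool kinetically homogeneous?

```r
fd <- study_subset(study, lineage = "CD8")
test_homogeneity(fd, fit_config(k = 2, n_starts = 8, seed = 1))$test
#> # A tibble: 1 × 4
#>       F   df1   df2   p_value
#> 1  32.0     1    16 0.0000355
```

Homogeneity is firmly rejected (p ≈ 3.6e-5): label uptake and loss rates
are inconsistent with a single-rate pool. Fitting the explicit
two-subpopulation model to labelling, telomere and vaccine data
simultaneously:

```r
fd3 <- study_subset(study, lineage = "CD8", include_yfv = TRUE)
fit <- fit_model(fd3, fit_config(variant = "explicit",
                                 datasets = c("label", "telomere", "yfv"),
                                 k = 2, n_starts = 30, seed = 1))
fit$derived
#> # A tibble: 1 × 5
#>   half_life_fast_years half_life_slow_years rel_size_slow fraction_from_naive
#> 1                0.454                 6.72         0.666               0.157
```

A fast subpopulation with a ~5-month clonal half-life coexists with a slow
one (half-life ~7 years here; the generating truth is 8.74) that makes up
about two thirds of the pool. Clonal stability of the slow subpopulation,
by exact Gillespie simulation of a clone seeded with
`1e11 × 2^k × Δ × f ≈ 2.3e5` cells:

```r
res <- precursor_lifespan_distribution(default_truth()$kinetics,
                                       mode = "long_lived",
                                       n_runs = 200, seed = 1)
res$summary[, c("median_half_life_days", "q25_half_life_days", "q75_half_life_days")]
#> # A tibble: 1 × 3
#>   median_half_life_days q25_half_life_days q75_half_life_days
#> 1                 3190.              3162.              3221.
```

Per-run population half-lives are tightly clustered around 3,190 days
(~8.7 years): the clone's fate is not dominated by stochasticity despite
its modest size.

See the vignette (`vignettes/tscm-dynamics.Rmd`) for the model equations,
weighting and identifiability discussion, and the design of the synthetic
data generator.

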