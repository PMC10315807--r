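# mrscreen

Two-sample Mendelian randomization (MR) screening of many GWAS-proxied
exposures — e.g. hundreds of blood metabolites — against a binary disease
outcome such as colorectal cancer, from summary statistics alone.

Observational metabolite–cancer associations are confounded by lifestyle,
medication and reverse causation. MR uses germline variants as instruments:
if SNPs that raise a metabolite also shift disease risk, and the usual
instrument assumptions hold, the ratio of the two genetic effects estimates
the causal effect of the metabolite (per SD) on disease log-odds. For
instruments *j* with exposure effects β<sub>Xj</sub> and outcome effects
β<sub>Yj</sub>, the primary estimator is random-effects inverse-variance
weighting over the Wald ratios β<sub>Yj</sub>/β<sub>Xj</sub> with weights
β²<sub>Xj</sub>/se²<sub>Yj</sub>, complemented by MR-Egger (directional
pleiotropy) and the weighted median (robust to <50% invalid weight).

The package covers the full screening workflow:

* **Data & harmonization** — canonical TSV summary-statistics tables,
  validation, allele alignment with palindrome/incompatibility handling
  and a complete drop audit.
* **Instrument selection** — p < 1e-5 exposure threshold, greedy LD
  clumping (r² > 0.1 within 500 kb), per-SNP R² and F ≥ 10 filters,
  outcome-association exclusion, confounder filtering.
* **Estimation** — Wald ratio, fixed/random IVW, MR-Egger, weighted
  median, odds-ratio conversion.
* **Sensitivity** — Cochran Q, iterated Radial-MR outlier removal,
  MR-PRESSO (global/outlier/distortion), leave-one-out, and the
  five-criterion candidate screen.
* **Follow-up** — replication IVW, DerSimonian–Laird meta-analysis,
  Steiger directionality, asymptotic power, lean LD-score regression
  (h², r<sub>g</sub>), multivariable MR (IVW + PRESSO), and Wakefield-ABF
  colocalization with the five-hypothesis posterior (PP.H4 > 0.8 rule).
* **Synthetic data** — generators for two-sample summary statistics with
  configurable pleiotropy, LD-structured regional signals, LD-score
  panels and confounder tables, all with known ground truth.

## Worked example

Simulate a small metabolite universe (two truly causal exposures, six
null) at realistic cohort sizes, and run the full screen:

```r
library(mrscreen)
uni <- simulate_metabolite_universe(n_exposures = 8,
                                    causal_theta = c(-0.5, 0.5),
                                    J = 20, seed = 7)
report <- run_pipeline(uni$exposures, uni$outcome_primary,
                       uni$outcome_replication,
                       config = pipeline_config(seed = 7))
report[, c("exposure", "n_snp", "or_ivw", "ci_low", "ci_high",
           "p_ivw", "retained", "p_meta", "final")]
```

```
       exposure n_snp or_ivw ci_low ci_high    p_ivw retained   p_meta final
1 metabolite_01    12  0.647  0.598   0.699 7.70e-28     TRUE 1.35e-09  TRUE
2 metabolite_02    16  1.633  1.519   1.755 2.66e-40     TRUE 1.78e-49  TRUE
3 metabolite_03    10  1.017  0.910   1.136 7.71e-01    FALSE       NA FALSE
4 metabolite_04    13  0.958  0.887   1.034 2.67e-01    FALSE       NA FALSE
...
```

The two planted causal metabolites are retained by the candidate screen
(IVW significance, direction agreement across the three estimators, no
heterogeneity, no Egger-intercept pleiotropy, leave-one-out stability),
replicate in the second cohort, and survive meta-analysis (`final`);
`or_ivw` is the causal odds ratio per SD of metabolite: 0.647 means a
protective effect (true θ = −0.5, exp(−0.5) ≈ 0.61), 1.633 a harmful one.
The nulls are dropped. Single estimators work on any harmonized set:

```r
s <- simulate_two_sample(sim_config(J = 20, theta = -0.7, seed = 3))
h <- harmonize_pair(s$exposure, s$outcome)
mr_ivw(h)
#> <mr_estimate> ivw_ra (J=20): beta=-0.6701 se=0.039 p=3.65e-66  OR 0.512 (0.474-0.552)
mr_egger(h)
#> <mr_estimate> egger (J=20): beta=-0.6342 se=0.09138 p=1.74e-06  OR 0.53 (0.438-0.643)
#>   egger intercept -0.004622 (se 0.0106, p 0.668)
mr_weighted_median(h, seed = 3)
#> <mr_estimate> weighted_median (J=20): beta=-0.6811 se=0.05751 p=2.34e-32  OR 0.506 (0.452-0.566)
```

All three recover the planted θ = −0.7 (OR ≈ 0.50) with a null Egger
intercept, as expected without pleiotropy.

See the vignette `vignettes/mr-screening-methods.Rmd` for the model,
assumptions, tuning parameters and design choices.

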