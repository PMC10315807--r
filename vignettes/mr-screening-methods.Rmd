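---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Circulating metabolites are plausible causal factors for colorectal and
other cancers, but observational associations are confounded by lifestyle,
medication and reverse causation. Two-sample Mendelian randomization (MR)
sidesteps this by using germline variants as instruments: SNP–metabolite
effects from one cohort and SNP–disease effects from another are combined
into an estimate of the causal effect of a standard-deviation change in the
metabolite on disease log-odds. `mrscreen` implements the full screening
workflow for hundreds of exposures at once — instrument selection, the
three standard estimators, the sensitivity battery, replication and
meta-analysis, directionality, power, genetic-correlation and
colocalization follow-up, and multivariable MR — together with generators
that produce summary statistics with known ground truth, so that every
stage can be validated by parameter recovery rather than by trust.

## Instrument selection

Candidate instruments are SNPs associated with the exposure at
`p_exposure` (default `1e-5`, the conventional relaxed threshold for
metabolite GWAS, which have modest genome-wide yield). Greedy LD clumping
(`clump_r2 = 0.1`, `clump_window_kb = 500`) retains the most significant
SNP of each correlated cluster; ties on p break by position then rsID so
the result is order-invariant. Instrument strength is measured by the
variance explained

$$R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,\mathrm{se}^2 N f(1-f)}
      = \frac{\beta^2}{\beta^2 + N\,\mathrm{se}^2},$$

whose frequency factor cancels — so $R^2$ is computable even without
allele frequencies — and by $F = \frac{N-k-1}{k}\frac{R^2}{1-R^2}$. The
filter is per SNP, so `k = 1` is used there (with the aggregate `k = J`
value also reported); SNPs with $F < 10$ are removed as weak. Harmonization
then aligns outcome effects to the exposure's effect allele, dropping
palindromic (A/T, G/C) variants outright — no frequency-based rescue — and
allele-incompatible pairs (e.g. A/G vs A/C). SNPs associated with the
outcome at `p_outcome_exclude = 1e-5` are excluded to protect the
exclusion-restriction assumption, and an exposure proceeds only with at
least `min_snps = 3` instruments ("more than two"). Every removal carries
a reason code; survivors plus removals always reconcile with the initial
significant count.

Indels, multi-allelic records and duplicate rsIDs are rejected at load
time rather than silently resolved. Matching is by rsID only; positions
are carried for clumping windows but never used for joins.

## Estimators

With per-SNP effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ and Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ (first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$):

* **IVW** combines ratios with weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$; the random-effects variant
  (the primary estimator) multiplies the fixed-effect SE by
  $\sqrt{\max(1, Q/(J-1))}$ — multiplicative overdispersion, floored so
  underdispersion never narrows the interval. Multiplicative rather than
  additive ($\tau^2$) random effects is the convention of the standard MR
  tooling and is what is implemented here.
* **MR-Egger** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with an
  intercept (weights $1/\sigma_{Yj}^2$) after orienting
  $\hat\beta_{Xj} \ge 0$; the intercept estimates directional pleiotropy,
  the slope the causal effect under InSIDE. SEs carry the floored
  dispersion $\sqrt{\max(1, Q_E/(J-2))}$ and p-values use $t_{J-2}$.
* **Weighted median** interpolates the ordered ratios at the midpoint of
  the normalized inverse-variance weights; it is consistent while valid
  instruments hold a majority of the weight. Its SE is a seeded parametric
  bootstrap (default 1000 draws).

Simple-median, mode-based, MR-RAPS and correlated-instrument variants are
deliberately out of scope: the screen uses exactly these three methods.

## Sensitivity battery and the candidate screen

Cochran's $Q$ (on $\chi^2_{J-1}$, or $\chi^2_{J-2}$ in the Egger context)
measures heterogeneity. Radial MR rewrites the IVW fit so that
$Q = \sum_j q_j$ decomposes exactly into per-SNP contributions, each
referred to $\chi^2_1$; flagged SNPs (at $\alpha = 0.05$, first-order
weights) are removed iteratively before the main analysis, stopping when
no new outlier emerges or fewer than three SNPs would remain. MR-PRESSO
simulates the null of its weighted leave-one-out residual sum of squares
(`n_sim` = 1000; the global p respects the add-one lower bound
$1/(n_\mathrm{sim}+1)$), Bonferroni-adjusts per-SNP empirical outlier
tests, and compares the raw-vs-corrected shift against a bootstrap of
random removals (distortion test). Note that the Bonferroni-adjusted
per-SNP test can only fall below $\alpha$ when
$n_\mathrm{sim} \gtrsim J/\alpha$. Leave-one-out refits flag exclusions
that flip the sign or lose nominal significance.

A candidate is **retained** only if all five hold: IVW $p < 0.05$; IVW,
Egger and weighted-median estimates agree in sign (the customary
"consistent direction and magnitude" wording is operationalized as sign
agreement only — magnitude agreement has no quantitative definition and
none is invented); $Q$ p > 0.05; Egger intercept p > 0.05; no leave-one-out sign
flip. Retained candidates are re-estimated in the replication cohort
(IVW only), pooled by DerSimonian–Laird random-effects meta-analysis on
the log-OR scale, and flagged **final** when the replication direction is
consistent and the pooled p < 0.05. No multiplicity correction enters the
primary screen — the design relies on replication and meta-analysis — but
Benjamini–Hochberg adjusted IVW p-values are emitted for transparency.

## Directionality, power, LDSC

The Steiger test sums per-SNP $R^2$ on each trait, converts to
correlations and compares Fisher transforms; for the binary outcome the
observed-scale $R^2$ with total N is used (no liability-scale correction
— a documented approximation). Power uses the asymptotic non-centrality
approximation
$\Phi\!\left(|\log \mathrm{OR}|\sqrt{n R^2 K(1-K)} - z_{1-\alpha/2}\right)$
for a binary outcome with case fraction $K$; the opposite-direction tail
is ignored, matching the standard online calculator. (A consequence worth
noting: as $\alpha \to 1$ this one-tailed expression tends to
$\Phi(\mathrm{ncp})$, not to 1; power is monotone in $n$, $R^2$, $|\log
\mathrm{OR}|$ and $\alpha$.)

The LD-score regression here is a deliberately lean single-component
implementation for synthetic-panel validation, not a replacement for
production LDSC: $\chi^2_j$ is regressed on the LD score $\ell_j$ with a
free intercept (absorbing uniform confounding inflation), standard
heteroskedasticity/over-counting weights evaluated at a first-pass OLS
estimate, and a delete-one-block jackknife (200 contiguous blocks,
auto-reduced with a warning on small panels) for SEs. Cross-trait
regression of $z_{1j} z_{2j}$ on $\ell_j$ yields the genetic covariance;
$r_g$ combines it with the two heritability fits and is clamped to
$[-1, 1]$, with the jackknife recomputing all three regressions per block
deletion.

## Multivariable MR and colocalization

MVMR inputs take the union of per-exposure instruments, jointly re-clump
ranking by the minimum p across exposures (so no exposure is privileged),
align everything to a common effect allele, and keep complete cases only
(audited). Direct effects come from no-intercept WLS of outcome effects on
the exposure-effect matrix with $1/\sigma_{Yj}^2$ weights, floored
multiplicative dispersion and $t_{J-m}$ p-values; rank deficiency is an
error naming the collinear columns. The multivariable PRESSO variant uses
multivariate leave-one-out fits for its expected values. Conditional
F-statistics are not computed (documented limitation).

Colocalization follows the single-causal-variant ABF framework: per-SNP
Wakefield log-Bayes-factors
$\tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$ with effect
priors $\sqrt{W} = 0.2$ (quantitative) or 0.15 (binary), the default
configuration priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, sums over
configurations in log space, the $H_3$ difference computed as a log-space
subtraction clamped at zero on cancellation (with a warning), and
PP.H4 > 0.8 as the shared-variant decision rule. Betas may be
reconstructed from z-scores via the $1/\sqrt{2p(1-p)n}$ SE approximation.
No multi-causal (SuSiE-style) extension is attempted.

## What the generators emulate — and what they do not

`simulate_two_sample()` draws per-SNP exposure effects
$\gamma_j \sim N(0.12, 0.06)$, frequencies uniform on (0.05, 0.95), and
summary statistics at the motivating study's scale (exposure N = 7,824;
outcome N = 32,072 with case fraction 0.62; replication N = 8,554 with
case fraction 0.52): $\mathrm{se}_X = 1/\sqrt{2Nf(1-f)}$ for a
unit-variance trait and $\mathrm{se}_Y = 1/\sqrt{2Nf(1-f)K(1-K)}$ on the
log-odds scale, with
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \mathrm{se}_Y)$.
Pleiotropy $\alpha_j$ is none, balanced (mean zero), directional
(positive mean) or InSIDE-violating (correlated with $\gamma_j$), applied
to a configurable fraction of SNPs. The wide effect-size spread matters:
MR-Egger's slope is identified only through variation in instrument
strength, and with $\mathrm{sd}(\gamma)$ comparable to
$\mathrm{se}_X \approx 0.018$ the slope is visibly regression-diluted.
Metabolite lead-SNP effects in real data span a wide range, which this
default reflects.

`simulate_metabolite_universe()` (the pipeline testbed: 20 exposures with
disjoint 30-SNP instrument sets, three causal at $\theta = -0.5, 0.5,
-0.4$) instead uses $\gamma_j \sim N(0.11, 0.03)$: instruments must clear
the exposure threshold (z ≈ 6) while the outcome-side effects
$\theta\gamma_j$ of causal exposures stay below the outcome-exclusion
threshold — the regime of a real metabolite screen, where per-variant
effects on disease are small. With a stronger law, selection itself
truncates the instruments of causal exposures, a pathology worth knowing
about but not the intended test condition.

Outcome effects are generated directly on the summary log-odds scale
(two-sample MR consumes nothing else) with no sample overlap between
cohorts and no LD between instruments (each sits on its own chromosome or
10 Mb away). Regional and LD-score generators add what those analyses
need: AR(1) LD with $z \sim \mathrm{MVN}(R\lambda\sqrt n, R)$ for
colocalization regions, and the bivariate generative identity
$\mathrm{Var}(z_t) = 1 + N_t h^2_t \ell_j/M$,
$\mathrm{Cov} = \sqrt{N_1 N_2}\, r_g \sqrt{h^2_1 h^2_2}\,\ell_j/M$ for
LDSC panels. Passing tests on these generators demonstrates correct
inference under the stated models; they do not probe allele-frequency
spectra, uneven LD, population stratification, or sample overlap, all of
which real data contain.

## Numerical and design choices

* **Recovery is judged against Monte-Carlo dispersion.** Validation
  checks assert $|\overline{\hat\theta} - \theta| < 3\,
  \mathrm{SD}(\hat\theta)$ across replicates. A stricter
  $3\,\mathrm{SD}/\sqrt{R}$ bound is not attainable for ratio estimators
  at these sample sizes: the Wald ratio carries second-order
  weak-instrument bias of order $(\mathrm{se}_X/\gamma)^2 \approx 1\%$,
  and the interpolated weighted median under one-sided contamination has
  a finite-precision bias of order
  $\mathrm{se}_\mathrm{ratio}\cdot\Phi^{-1}(0.5/w_\mathrm{valid})$. Both
  are real properties of the estimators, not implementation artifacts.
* **The floored dispersion makes the Egger intercept test conservative.**
  Exact calculation gives type-I rates of 1.6% (J = 10), 3.3% (J = 30)
  and 3.8% (J = 50) at nominal 5%. Calibration checks therefore run at
  J = 50; at small J the test trades power for never over-rejecting.
* Clumping's $r^2$ threshold is exclusive (removal requires
  $r^2 > 0.1$); a missing LD entry for an in-window pair is an error,
  never treated as independence. LD is an abstract provider (in-memory
  matrix or TSV reader); no reference-panel computation is in scope.
* Seeds: every stochastic routine takes an explicit seed;
  `run_pipeline()` derives per-exposure seeds from the master seed so a
  rerun reproduces the report byte for byte.
* Problem sizes used by the validation suite — 500-replicate recovery and
  calibration studies, 200-replicate outlier and colocalization studies,
  50,000-SNP LDSC panels, and a 20-exposure pipeline universe — were
  chosen so the whole suite completes in about a minute while leaving
  binomial error well inside the asserted bands.
* Confounder screening consumes a locally supplied association table
  (rsID, trait, p) standing in for a PhenoScanner export; no live queries.

## Known limitations

Binary-outcome $R^2$ uses the observed scale; LDSC-lite fits a single
component with an unconstrained intercept and is not meant for real
genome-wide panels; MVMR reports no conditional F; the weighted-median
bootstrap is parametric only; colocalization assumes at most one causal
variant per trait per region. Pathway enrichment of screened metabolites
and retrieval of external eQTL/pQTL or GWAS resources are outside the
package's scope by design.
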