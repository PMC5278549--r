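---
title: "Two-stage Mendelian randomization for longevity and frailty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Mendelian randomization for longevity and frailty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemr)
```

## The estimation problem

Observationally, higher serum triglyceride is associated with lower odds of
longevity and with higher frailty in elderly populations, but such
associations are open to confounding and reverse causation. Mendelian
randomization sidesteps both by using a genetic variant as an instrumental
variable: alleles are assigned at conception, before any confounder can act,
so a variant that (i) shifts triglyceride, (ii) is independent of
confounders, and (iii) affects the outcome only through triglyceride
identifies the causal effect.

`agemr` implements this for a single biallelic variant with additive coding
$G \in \{0, 1, 2\}$ (count of the triglyceride-raising C allele in the
*APOA5* promoter region). Stage 1 is OLS in the reference group:

$$\mathrm{TG}_i = \alpha + \beta_1 G_i + \varepsilon_i,$$

from which we report $\hat\beta_1$ (mmol/L per allele), the overall
regression F and $R^2$. Stage 2 substitutes the genetically predicted
exposure $\widehat{\mathrm{TG}}_i = \hat\alpha + \hat\beta_1 G_i$ into the
outcome model: logistic regression for binary outcomes (longevity; the
Fried frailty phenotype), OLS for the continuous frailty index. Because the
predicted exposure is an affine transform of $G$, the stage-2 test is
exactly the instrument-outcome test re-scaled, and for a continuous outcome
without covariates the two-stage estimate equals the Wald ratio
$\hat\beta_{GY} / \hat\beta_1$ to machine precision — the package tests this
identity at $10^{-8}$. On the odds-ratio scale the identity reads
$\mathrm{OR}_\text{causal} = \mathrm{OR}_\text{per-allele}^{1/\beta_1}$,
which `wald_ratio()` exposes as an explicit cross-check route.

### Assumptions and diagnostics

The three instrumental-variable assumptions are operationalised as:

* **Relevance** — the stage-1 F statistic, with the conventional F > 10
  weak-instrument gate reported on every `mr_stage1` object.
* **Independence from confounders** — `confounder_balance()` tests each
  measured covariate across the TT/TC/CC groups (χ² for categorical,
  Kruskal–Wallis for continuous); large p-values are supporting, never
  proving, evidence.
* **Exclusion restriction** — not testable with one instrument. The
  package reports the genotype–HDL-C association in its genotype–lipid
  table so a pleiotropy signal is at least visible, but does not model it;
  multi-instrument estimators (IVW, MR-Egger) are out of scope.

### Standard errors, the model ladder, and the bootstrap

Stage-2 standard errors are the naive second-stage regression SEs,
uncorrected for first-stage estimation — the convention behind standard
two-stage reporting. The corrective offered is the **joint-resampling
bootstrap** (`bootstrap_mr()`, model 4 of the ladder): subjects are
resampled with replacement (stratified by outcome class for binary
outcomes, preserving the case-control balance), both stages are re-fitted
per replicate, and a percentile 95% CI is taken over replicate estimates. A
percentile interval was chosen over a normal approximation because it is
assumption-light and exactly reproducible from the seed; replicates that
fail (no genotype variation, separation, non-convergence) are dropped and
counted, never silently imputed.

The adjustment ladder is fixed: model 1 unadjusted; model 2 sex (longevity
design) or age + sex (frailty design); model 3 additionally education,
marital status, smoking, drinking, BMI, systolic and diastolic blood
pressure; model 4 = bootstrap of model 2. Covariates adjust **stage 2
only** by default. Whether the original adjusted analyses refit stage 1 is
not determinable from the printed tables; adjusting the outcome model only
is the conservative reading and keeps the predicted exposure identical
across models, so differences between models isolate the effect of outcome
adjustment. `adjust_stage1 = TRUE` exposes the alternative. Missing data
are handled complete-case within each model's own variable set, so the
reported n legitimately varies across models.

Logistic fits use IRLS via `stats::glm` with tolerance $10^{-8}$ and at
most 100 iterations; non-convergence and (quasi-)separation (fitted
probabilities at the 0/1 boundary together with coefficient magnitudes
above 12) raise errors with diagnostics rather than returning unstable
estimates.

## Frailty scoring

The **frailty index** is the cumulative-deficit mean of 45 items each
scored in $[0,1]$: $\mathrm{FI} = \sum_j d_j / 45$ with complete data. The
published procedure divides by 45 and is silent on missing items; the
default policy here follows the standard cumulative-deficit convention of
rescaling the denominator to the number of observed items, but only when at
least 80% (36) are observed, returning `NA` otherwise; `policy = "strict"`
restores the literal /45 with any missingness voiding the score.
Polychotomous items default to equally spaced grades in $[0,1]$ when a
codebook lists labels without values. The exact 45-item inventory of the
motivating design is not public, so codebooks are user-supplied
(`read_deficit_codebook()`); the shipped
`deficit_codebook_synthetic.yaml` is a synthetic placeholder illustrating
the format, not any real inventory.

The **Fried phenotype** counts five criteria — unintentional weight loss,
exhaustion, low activity, weakness (self-report), and slowness — with frail
defined as ≥ 3 present. Slowness is gait speed below the 20th sex-specific
percentile, implemented on timed up-and-go *times*: a time above the
sex-specific 80th-percentile time is equivalent and avoids assuming any
particular speed transformation. The percentile is the empirical type-7
(linearly interpolated) quantile, and ties at the cutoff are non-slow —
the strict reading of "below the percentile". With missing components the
classification is decided whenever logically possible (≥ 3 observed-true ⇒
frail, ≥ 3 observed-false ⇒ non-frail, otherwise `NA`), preserving
decidability without imputation.

## What the synthetic cohorts emulate

The generator reproduces the *statistical couplings* the analysis rests on,
at the study's own scale, with every causal effect switchable:

* **Genotypes** are Hardy–Weinberg draws at C-allele frequency 0.291
  (longevity-arm comparison group, n = 2294 with 438 cases) or 0.281
  (ageing arm, n = 1750).
* **Exposure**: $\mathrm{TG} = 1.29 + 0.301\,G + N(0, \sigma^2)$, with
  $\sigma$ solved from the target instrument $R^2 = 0.040$ via
  $R^2 = \beta_1^2\,2q(1-q) / (\beta_1^2\,2q(1-q) + \sigma^2)$, giving
  $\sigma \approx 0.947$ mmol/L at the defaults. The ageing arm reuses the
  0.301 slope — a package choice, since no arm-specific value is published.
  The Gaussian form is kept exact (no truncation at zero) because the
  $R^2$ calibration and the parameter-recovery tests depend on it;
  occasional non-positive triglyceride values are a known unrealism.
* **Longevity cases** are drawn by exact exponential tilting of the
  control distribution: under a rare-outcome logistic model with slope $b$
  per mmol/L, the case genotype distribution is
  $\propto p_g e^{b\beta_1 g}$ and case triglyceride within genotype is
  $N(\mu_g + b\sigma^2, \sigma^2)$. This samples the implied case
  distribution exactly — no rejection step, no sampling budget — and makes
  the induced per-allele case-control OR exactly $e^{b\beta_1}$ (0.61^0.301
  ≈ 0.862 at the defaults, with the causal OR per mmol/L $e^b = 0.61$).
* **Deficits**: a latent frailty mean
  $m_i = 0.12 + \beta_\mathrm{FI}(\mathrm{TG}_i - \overline{\mathrm{TG}})$
  (default $\beta_\mathrm{FI} = 0.007$ FI units per mmol/L, the published
  observational slope) feeds a per-subject
  $\lambda_i \sim \mathrm{Beta}(m_i\phi, (1-m_i)\phi)$, $\phi = 30$; 36
  items are Bernoulli($\lambda_i$) and 9 are five-grade
  $\mathrm{Binomial}(4, \lambda_i)/4$. Item expectations equal
  $\lambda_i$, so scoring the items through `frailty_index()` recovers
  $\beta_\mathrm{FI}$ without attenuation — the generator exercises the
  scoring code end to end instead of drawing FI directly. The baseline FI
  of 0.12 and $\phi = 30$ are chosen as typical of community-dwelling
  elderly cohorts (mean FI near 0.1–0.15 with realistic overdispersion).
* **Fried components**: the four self-report indicators are Bernoulli with
  log-odds increasing by `causal_logOR_frailty` (default $\ln 1.91$) per
  mmol/L around plausible marginal frequencies (10%, 20%, 8%, 25%);
  up-and-go time is sex-specific log-normal, independent of triglyceride.
  Because the slope acts at the *component* level, the induced
  phenotype-level MR odds ratio is larger than the per-component value
  (≈ 2.9–3.0 per mmol/L at the defaults) — a consequence of requiring ≥ 3
  criteria, documented here rather than re-calibrated away.
* **Covariates** (age, sex, education, marital status, smoking, drinking,
  BMI, blood pressures) follow the published marginal profiles of each
  group and are drawn independently of genotype, encoding the
  independence assumption; consequently balance tests are null-calibrated
  by construction.

All streams derive from one integer seed; a fixed seed gives byte-identical
cohorts.

**What passing tests do not show.** The generator uses Gaussian exposure
noise (real triglyceride is right-skewed), independent covariates (real
cohorts have correlated socio-demographics and possibly dynastic or
population-structure effects), no genotyping error or informative
missingness, and exact logistic/linear outcome links. Calibration results
on these cohorts therefore validate the estimator's arithmetic and its
sampling behaviour under the stated model — not robustness to the ways real
cohort data depart from it.

## Numerical choices and degenerate inputs

* HWE: 1-df χ² goodness of fit with allele frequency estimated by gene
  counting, **no continuity correction** — this convention reproduces the
  published p = 0.744 from the genotype counts, whereas a Yates-corrected
  test does not. Monomorphic input degenerates to p = 1 with a warning.
* Grouped-summary reconstruction: count-weighted OLS of per-genotype means
  on allele count is algebraically identical to individual-level OLS
  because the predictor takes three values. Within-group variance is
  pooled as $\sum n_g s_g^2 / N$ by default (population convention, which
  reproduces the published $R^2 = 0.040$); `within = "sample"` uses
  $(n_g - 1)$ weights and matches individual-level $R^2$ and F exactly.
  $F = (N-2)R^2/(1-R^2)$. The F reconstructed from the rounded published
  summaries is ~96.2 vs the printed 95.3 — consistent with the published
  regression using slightly fewer subjects (lipid missingness) than the
  genotype table; both values are reported, the discrepancy documented and
  not resolved.
* A constant exposure in stage 1 returns $\beta = 0$, $R^2 = 0$, $F = 0$
  rather than NaN; no genotype variation raises a singular-design error; a
  constant predicted exposure in stage 2 is a no-estimate error.
* Zero cells in the allelic 2×2 table get the Haldane–Anscombe 0.5
  correction, flagged in the output.
* Bootstrap B = 1 yields the degenerate CI equal to the single replicate,
  by construction of the percentile interval.

## Problem sizes in the test suite

The suite validates calibration at the study's own scale where that is the
point — stage-1 recovery uses 200 replicates of n = 2294 — and smaller
sizes where only the property matters: type-I error of the stage-2 test at
400 null replicates of a 150/450 case-control draw, bootstrap coverage at
B = 200 over 200 replicates of an n = 600 ageing cohort, FI-slope recovery
over 40 replicates at n = 1750. Acceptance-style bands are 3 Monte-Carlo
(or binomial) standard errors around the target, fixed in advance of the
runs.

## Known limitations

* One instrument: no pleiotropy modelling, no IVW/MR-Egger/median
  estimators, no LD handling.
* Significance is reported at two-sided 0.05 with no multiple-testing
  correction across the model ladder, matching conventional reporting for
  this design; treat the ladder as sensitivity analysis, not independent
  confirmations.
* Naive stage-2 SEs understate uncertainty when the instrument is weak;
  the F > 10 gate and the bootstrap are mitigations, not fixes.
* The frailty-phenotype arm of the generator has no parameter-recovery
  guarantee at the phenotype level (see above); only the FI path does.
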