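---
title: "Methods: MoM normalization, Gaussian likelihood-ratio risk and screening evaluation"
author: "momscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MoM normalization, Gaussian likelihood-ratio risk and screening evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momscreen)
```

## The screening model

Second-trimester serum screening asks, for each pregnancy, how strongly a
panel of maternal serum analytes supports a fetal trisomy relative to a
euploid pregnancy. `momscreen` implements the classical Gaussian
(binormal) formulation for a four-analyte panel — AFP, free β-hCG, uE3 and
sHLA-G — in three stages.

**1. MoM normalization.** AFP, free β-hCG and uE3 change systematically
across gestational weeks 15–19, so raw concentrations are not comparable
between subjects. Each level is divided by the median of unaffected
pregnancies at the same completed week, giving a multiple of the median
(MoM). sHLA-G shows no association with gestational age, so it is
normalized against a single overall control median (106.3 U/ml in the
bundled reference parameters). Concentration units cancel, which is why
the triple-test analytes can be carried in whatever unit the assay
reports.

**2. Gaussian likelihood ratio.** Within each group g the log10 MoM vector
is modelled as Gaussian with mean vector $m_g$, SD vector $s_g$ and
correlation matrix $R_g$. The evidence carried by a profile $x$ is the
density ratio $LR(x) = \phi(x; m_A, \Sigma_A) / \phi(x; m_U, \Sigma_U)$
with $\Sigma_g = D_g R_g D_g$. Markers with small SDs and well-separated
group means dominate the ratio; for trisomy 18 all four markers are
shifted downward, and sHLA-G (mean log10 MoM −0.3269 vs 0.0455 in
controls, SDs ≈ 0.22) is, by this criterion, as informative as free β-hCG
despite the latter's larger mean shift, because its SD is less than half
as large. The posterior risk is the odds-form Bayes update,
`posterior odds = prior odds × LR`.

**3. Evaluation.** Markers and risk scores are compared by empirical ROC
analysis (trapezoidal AUC, DeLong 95 % CI and z-test against 0.5),
Youden-index cutoffs with the full confusion table, and the operational
summary used by screening programmes: the detection rate when the cutoff
is placed so that a fixed fraction (default 5 %) of unaffected pregnancies
screens positive. A multivariate logistic regression (age, weight and the
four MoMs) provides the complementary risk-factor view with Wald CIs on
Exp(B).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| group sizes | 797 / 139 / 83 | subjects | reference case-control population (control / T21 / T18) |
| group means, SDs, correlations | bundled `params_table2.json` | log10 MoM | published distribution parameters of the reference cohort |
| control sHLA-G median | 106.3 | U/ml | published control median; flat across weeks |
| T18 prior | 1/5000 | probability | live-birth prevalence of trisomy 18 |
| T21 prior | 1/700 | probability | screening-literature convention; not taken from the reference cohort |
| `useCorrelations` | `FALSE` | — | printed correlations are rounded and partly non-significant; the independence product is the more conservative default |
| `targetFpr` | 0.05 | rate | the standard 5 % false-positive protocol |
| weight model | identity | — | see below |

The **maternal-weight correction** follows the screening-literature
convention: expected MoM is regressed on reciprocal weight in controls
(`fitWeightModel`) and each subject's MoM divided by the expectation at
her weight. How the reference analysis combined maternal weight with the
analyte evidence is not published, so the identity model (no correction)
is the default everywhere, and the reciprocal model is an explicit opt-in;
a multiplicative weight-prior hook was deliberately not implemented.
Likewise the **maternal-age risk** is configurable (flat or age-table)
because no age-risk curve is published with the reference parameters; all
shipped defaults use flat priors. Logistic-regression covariates accept
either linear or log10 MoM coding; the pipeline feeds linear MoM, and
neither coding is asserted to be the reference study's choice.

## What the simulator does and does not emulate

`generateCohort()` draws log10 MoM vectors from the per-group multivariate
normal (correlations taken as Pearson on the log10 scale), reconstructs
raw concentrations through the configured median curve, and attaches
demographics: age uniform on [18, 35) years, weight lognormal with median
54.5 kg and sdlog 0.14 (spanning roughly 37–93 kg in a cohort of 800,
matching the reported range), gestational week uniform on {15, …, 19}.
The per-week median anchors for AFP/β-hCG/uE3 are log-linear in week with
fixed, essentially arbitrary values — every MoM-scale quantity is
invariant to them, which is also why they could not be estimated from
published summaries. Levels are rounded to 4 decimals (age 2, weight 1) at
generation so that cohort CSVs round-trip byte-identically; the induced
log10 MoM perturbation (≤ ~10⁻⁴) is far below every tolerance used in
estimation.

The simulator deliberately emulates only the distributional skeleton of a
real screening population. It does **not** model assay noise or batch
effects, gestational-age dating error, the age–risk association (age is
drawn independently of group), weight–MoM trends (unless you inject one),
twin pregnancies or IVF conceptions. Consequently, passing parameter
recovery and performance tests on simulated cohorts demonstrates internal
consistency of the estimators and the risk engine under the stated
Gaussian model — not that real cohorts meet those assumptions. Indeed the
reference study's empirical AUC for sHLA-G in trisomy 18 (0.915) exceeds
the binormal value implied by its own printed means and SDs (≈ 0.88),
which is only possible if the real distributions deviate from
log-Gaussianity; empirical dataset results of that kind are therefore not
reproduction targets for this package.

## Numerical and convention choices

- **Medians** use the lower-middle convention for even n (the lower of the
  two central order statistics), so fitted medians are observed values and
  the control median MoM is exactly 1 in every stratum of the fitting
  cohort.
- **Covariance repair:** published correlations are rounded to 3 decimals,
  so D R D can in principle leave the positive-definite cone; eigenvalues
  are then clipped at 1e−10 with a warning (`groupCovariance`). The three
  bundled matrices are positive definite as printed, so the repair is a
  safeguard only.
- **ROC cutoffs** sit at midpoints of adjacent distinct scores; the Youden
  maximizer breaks ties toward higher sensitivity. Score polarity is
  inferred from the sign of the case–control mean difference unless forced
  (for trisomy 18 all four markers are "lower is positive"; for trisomy 21
  free β-hCG and sHLA-G flip).
- **Fixed-FPR cutoffs** use the empirical step-function convention: the
  smallest observed cutoff whose control positive fraction does not exceed
  the target, so the achieved FPR is always ≤ the target.
- **Mann-Whitney U** is computed with midrank ties; the p-value is exact
  for small tie-free samples and a tie-corrected normal approximation with
  continuity correction otherwise.
- **Logistic regression** is IRLS (via `glm`) with convergence at 1e−8 or
  100 iterations; quasi-separation (fitted probabilities numerically 0/1)
  flags the fit as unconverged rather than reporting explosive Wald CIs as
  trustworthy.
- **Degenerate inputs:** zero-variance markers yield SD 0 and missing
  correlations rather than errors; single-class ROC inputs, empty
  rank-sum samples, non-positive levels/weights and out-of-range priors
  raise informative errors.

## Problem sizes used in the shipped checks

Statistical tests in the suite use the smallest sizes at which their
tolerances are meaningful: parameter recovery runs at n = 100,000 per
group (mean tolerance 3·SD/√n, correlation tolerance ±0.01), logistic
recovery at n = 50,000 with 100 replicates of n = 10,000 for CI coverage,
and distributional spot checks at n = 20,000–50,000. Exact structural
identities (AUC–U equivalence, round trips, Youden-vs-brute-force) run on
many small random instances instead, where exactness, not power, is the
point.

## Known limitations

- The bundled parameters are summary statistics of a single retrospective
  case-control cohort; risks computed from them are illustrative, not
  clinically validated.
- The discrepancy between two published values of the sHLA-G specificity
  (87.7 % in text vs 88.7 % in the operating-point table) is carried as
  printed in the table — whose column is internally consistent with its
  predictive values — and not reconciled.
- No first-trimester markers, NIPT modelling, or sequential screening
  protocols; no sample-size machinery.
- The age-table prior is a lookup hook; no published age-risk curve ships
  with the package.
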