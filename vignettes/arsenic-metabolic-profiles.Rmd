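---
title: "Methods: modeling urinary arsenic metabolic profiles under left censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling urinary arsenic metabolic profiles under left censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmet)
```

## The problem

In populations chronically exposed to inorganic arsenic (iAs) through
drinking water, the urinary profile of iAs and its mono- (MMA) and
di-methylated (DMA) metabolites reflects both exposure and the individual's
methylation capacity. Two features make the statistical analysis
non-trivial. First, a large fraction of speciated measurements fall below
analytical detection limits (LODs) — in the cohort this package emulates,
iAs(V) was undetectable in roughly two thirds of urine samples — so naive
substitution (LOD/2, LOD/sqrt(2)) would distort both levels and
correlations. Second, urinary concentrations remain positive even at
negligible water arsenic, because diet and other background sources
contribute dose that a plain `log10(water As)` term cannot represent.

`asmet` addresses both: proper multiple imputation from left-censored
log-normal models, and a dose–response model whose water term is
`log10(beta_offset + WaterAs)` with the offset estimated from the data.

## The final model

For each of nine dependent variables — log10 TiAs, MMA, DMA, USAs; logit
%TiAs, %MMA, %DMA; log10 PMI, SMI — the model is

$$
Y = \alpha_{DWS} + \beta_{DWS}\,\log_{10}(10^{\alpha_{LogOffset}} + \mathrm{WaterAs})
 + \beta_Q \log_{10} Q + \beta_C \log_{10} C + \beta_F F
 + \beta_B \log_{10} B + \beta_A \log_{10} A + \beta_S \log_{10} S + \beta_R R
$$

with separate intercepts and slopes for the four drinking-water source
categories (untreated tap, filtered tap, other in-home treatment, bottled).
$Q$ is daily tap-water consumption (L/day; reported zeroes recoded to 0.06
L/day — one quarter cup — before the log), $C$ urinary creatinine (mg/dL,
entering as a covariate rather than as a correction of the concentrations),
$F$ a female indicator, $B$ BMI (kg/m²), $A$ age (years), $S$ urinary
cotinine (µg/L, a biomarker of smoking intensity) and $R$ a 0/1 indicator of
fish or shellfish consumption in the previous 48 h. The offset is
parameterized on the log10 scale ($\beta_{offset} = 10^{\alpha_{LogOffset}}$,
µg/L) so it stays positive during optimization. For the relative-level and
methylation-index outcomes the offset term is dropped (it is weakly
identified when the water slope itself is near zero) and the water term is
plain `log10(WaterAs)` on completed, positive values.

**Assumptions.** Concentrations are log-normal given covariates; residuals
are homoscedastic on the transformed scale; censoring is purely a
detection-limit mechanism (left truncation of the observation process, not
of the underlying biology); records are independent.

### Fitting

For fixed $\alpha_{LogOffset}$ the model is linear, so
`fit_offset_model()` profiles the sum of squared errors over
$\alpha_{LogOffset}$: the SSE is evaluated on the multi-start grid
{−1, 0, 0.5, 1, 1.5}, refined by golden-section/parabolic search (tolerance
1e-10) in a ±0.75 window around the best grid point, then polished by up to
four Newton steps on the profiled SSE with central finite differences
(h = 1e-5). The linear coefficients at the optimum are the exact
least-squares solution, and the covariance is the Gauss–Newton
approximation $\hat\sigma^2 (J^\top J)^{-1}$ with the Jacobian including the
offset column $\partial \hat Y_i/\partial \alpha = \beta_{DWS(i)}\,
10^\alpha / (10^\alpha + W_i)$. Consequences verified by the test suite:
with the offset disabled the fit reproduces an independent `lm()` oracle to
1e-8 (coefficients and standard errors), and on noiseless synthetic data
all 16 parameters are recovered to better than 1e-6. The profiled SSE is
checked to be unimodal near the optimum, and fits are invariant to row
order.

## Censored imputation

`fit_censored_lognormal()` fits a Tobit-type model — normal on log10
concentrations, left-censored observations contributing
$\Phi((\log_{10}\mathrm{LOD}-\mu_i)/\sigma)$ — through
`survival::survreg(dist = "gaussian")`, the same likelihood SAS LIFEREG
maximizes. With no censoring this coincides with the complete-data ML fit
(OLS coefficients, variance with divisor n).

`impute_nondetects()` completes the cohort `m` times (default 20) in a
fixed sequential order: water arsenic (intercept-only) → missing BMI,
creatinine, cotinine (normal regressions on gender and log10 age) → DMA →
MMA → iAs(III) → iAs(V) → toenail arsenic. Each analyte's conditional model
includes water arsenic, gender, log10 age, log10 BMI, water source, log10
creatinine and the log10 values of analytes completed earlier in the order,
which is what preserves inter-analyte correlations in the completed data
(verified: completed-data correlations within 0.1 of the pre-censoring
values at n = 2000, including the two-thirds-censored iAs(V)). Imputation
order runs from the least-censored analyte (DMA) to the most, so the
strongest conditioning variables are mostly observed.

Two design choices deserve a note:

- **Properness.** Before each imputation, `(coefficients, log sigma)` are
  drawn from their asymptotic normal distribution (and for the ordinary
  regressions, $\sigma^2$ from its scaled inverse chi-square), so
  between-imputation variance reflects parameter uncertainty. Without this,
  Rubin's rules under-state standard errors.
- **Fixed-parameter sequential fits.** The Tobit models are fitted once, on
  the observed cohort, with censored conditioning values entered at their
  LOD proxy, rather than refitted inside each imputation as fully chained
  equations would. This keeps the procedure fast and deterministic; the
  LOD-proxy approximation is benign for the conditioning variables that
  matter (DMA, 10% censored at the defaults) and its residual effect is
  covered by the correlation-preservation and coverage checks.

Truncated draws use the inverse CDF,
$x = 10^{\mu_i + \sigma \Phi^{-1}(u)}$ with
$u \sim U(0, \Phi((\log_{10}\mathrm{LOD}-\mu_i)/\sigma))$, clamped so
imputed values are strictly inside (0, LOD) even when the censoring
probability underflows.

## Pooling and inference

`rubin_pool()` implements the classic combining rules: pooled estimate
$\bar q$, within-variance $W$, between-variance $B$, total
$T = W + (1+1/m)B$, large-sample degrees of freedom
$\nu = (m-1)(1 + W/((1+1/m)B))^2$ ($\nu = \infty$ when $B = 0$, normal
reference), two-sided p from the t distribution. The small-sample
Barnard–Rubin correction is deliberately not applied: at n = 904 with
m = 10–20 the difference is negligible, and the uncorrected rules match the
classic MIANALYZE-style behavior this pipeline mirrors. The implementation
is pinned to an independent brute-force oracle at 1e-12 on 1000 random
inputs, and full-chain calibration (generate → impute → fit → pool) yields
95% CI coverage of the untreated-source slope inside [90%, 99%] over 100
seeded cohorts.

Because `USAs = TiAs + MMA + DMA` is a sum of log-normals, it is not exactly
log-linear in the covariates, so no finite-sample "true" coefficient exists
for it. The coverage check therefore targets the pseudo-true value — the
large-sample limit of the same fit, computed on an uncensored cohort of
n = 100,000 — the standard M-estimation view of a mildly misspecified model.
The linear imputation models approximate the non-linear truth, which costs a
small bias in the slope; the coverage band absorbs it, and this is the main
reason coverage sits slightly below the nominal 95%.

## Stepwise selection across imputations

`run_stepwise()` runs bidirectional stepwise selection for every
dependent-variable × imputation combination (9 × 20 = 180 runs at full
scale) and tallies selections per candidate; `retain_predictors()` keeps
candidates selected in strictly more than 25 of 180 runs;
`revise_selection()` applies the post-hoc rules (cotinine over the
categorical smoking variable when both are retained, collapse of
water-related candidates into the source × transformed-TAs structure,
forced inclusion of the fish indicator).

The default step criterion is the Schwarz Bayesian criterion (SBC), the
default of the stepwise machinery this procedure mirrors; a classical
p-value mode (entry/stay 0.15) is available via `criterion = "p"`. The SBC
default is also what makes the retention rule a meaningful null filter: at
α = 0.15 a pure-noise candidate ends up selected in roughly 15% of runs,
i.e. an expected tally of about 27/180 — *above* the threshold — whereas the
SBC entry bar (roughly p < 0.01 at n = 904) keeps null tallies low. Because
the nine dependent variables are transforms of the same three species, runs
are strongly dependent: a chance association tends to appear in blocks of
~20 runs (one dependent across all imputations). Calibration is therefore
stated per candidate: over 100 null cohorts at full scale, each candidate's
tally stays below the threshold in at least 90% of tallies. Candidate
groups that do not increase the design rank (perfect collinearity) are
never entered, and interactions are considered only while both main effects
are in the model.

## Survey comparison

`reweight_reference()` post-stratifies reference-survey weights over gender
× race (white/other) × age bands (40–49, 50–59, 60–69, 70–79, 80+) so cell
weight shares match the cohort's participant shares, preserving total
weight. `censored_weighted_gm()` estimates geometric means by weighted
left-censored ML on log10 values — equivalent to the log-normal
survival-analysis formulation — and `compare_cohort_to_reference()` reports
GM ratios plus non-detect percentages and mean LODs on both sides. No
design-based variances are attempted for these ratios (strata and PSUs are
out of scope); with very heavy censoring (>90%) of a skewed mixture the
censored-normal GM can drift by a few percent, which is why the shift-
recovery test uses a null-truth reference whose marginals are exactly
log-normal.

## The synthetic cohort generator

`cohort_config()`/`generate_cohort()` produce cohorts with the structural
features the analysis needs, not a replica of any real population's joint
distribution. Emulated: n = 904 older adults (age ≥ 45, 59% female), the
four water-source categories, water arsenic from a log10-normal truncated
at 1850 µg/L with LOD 3 µg/L, urinary LODs 0.5/1/0.5/1 µg/L for
iAs(III)/iAs(V)/MMA/DMA, 93/904 zero water consumers, 59/904 missing
toenail records and one missing BMI/cotinine/creatinine each, smoker
fraction 16% expressed through a bimodal cotinine distribution, and
species generated from the offset model itself with correlated residuals
(default pairwise 0.5) on the log10 scale.

Choices the underlying study leaves open, fixed here once and exposed as
config:

- **TiAs split.** iAs(III) gets a Beta-distributed share of TiAs (mean
  0.65, concentration 10), which gives iAs(V) — the smaller share with the
  higher LOD — the much higher non-detect rate, matching the qualitative
  ordering (about two thirds vs one third).
- **Ground-truth coefficients** default to the published pooled estimates
  for log10 TiAs/MMA/DMA, with the four per-source intercepts shifted by one
  per-species constant so the implied geometric means under the default
  covariate distributions equal the published overall geometric means
  (`center_truth()`, deterministic: quadrature for the water term, closed
  forms elsewhere). Without centering, those slopes combined with any
  plausible covariate scales put the species far above their LODs and the
  censoring machinery would go unexercised; the real cohort's covariate
  joint distribution is not public.
- **Residual SDs** (0.45/0.40/0.30 log10 units for TiAs/MMA/DMA) were chosen
  so the default cohort's non-detect pattern is structurally similar to the
  published one (heaviest for iAs(V), lightest for DMA).
- **Smoking cutoff** for the categorical variable: 100 ng cotinine per mg
  creatinine (a conventional active-smoking threshold); the study does not
  state its cutoff.
- **Logit clipping** at [0.1%, 99.9%] keeps completed-data percentages
  finite without affecting realistic values.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: measurement error in the speciation assay,
arsenobetaine and other seafood arsenicals, within-person temporal
variability, household clustering, informative missingness, or any
departure of real residuals from log-normality. Results on synthetic data
validate the *procedures* (estimator correctness, calibration, identities),
not the published substantive estimates, which depend on the unreleased
cohort data.

## Numerical and scale choices

Degenerate inputs are rejected with explicit errors: all-censored panels,
non-positive LODs or concentrations, creatinine ≤ 0, groups with fewer than
two members, empty post-stratification cells (listing the cells), unknown
water-source categories. Stepwise ties resolve to the first-best candidate
in roster order; an SBC move must improve by more than 1e-10 to count,
preventing cycling.

Problem sizes in the test suite and acceptance script are the package's
own balance of precision against runtime: coverage uses 100 cohorts of
n = 904 with m = 10 imputations; selection calibration uses 100 null
cohorts at the full 180-run scale; moment and correlation checks use
n = 2000 with m = 10; property loops use 100 seeds or 1000 random draws.
The full default pipeline (n = 904, m = 20, all nine outcomes, selection
and comparison stages) runs in a few minutes on one CPU.

## Known limitations

- The fixed-parameter sequential imputation is an approximation to fully
  chained equations; with much heavier censoring of the conditioning
  variables than the defaults produce, refitting per imputation would be
  preferable.
- The Gauss–Newton covariance ignores curvature beyond the Jacobian; near
  a weakly identified offset (flat water slope) the offset SE is
  optimistic, which is one reason the offset is dropped for relative-level
  outcomes.
- Pseudo-true targets for aggregate outcomes (USAs) are simulation-based
  limits, not closed-form truths.
- The survey comparison reports point ratios only; no design-based
  uncertainty.
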