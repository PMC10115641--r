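---
title: "Landmark survival modeling of longitudinal ctDNA kinetics"
author: "ctdnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark survival modeling of longitudinal ctDNA kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnakit)
```

## The problem

Circulating tumor DNA (ctDNA) — the tumor-derived fraction of plasma
cell-free DNA, identified through somatic mutations — falls rapidly in
patients who respond to therapy and rises in patients who progress. Serial
plasma collections during the first treatment cycles therefore carry an
early survival signal that radiographic response assessment may miss.
`ctdnakit` implements the full analysis chain for exploiting that signal in
a randomized oncology trial:

1. post-processing of per-variant read counts into censored, PBMC-corrected
   allele fractions and a per-sample burden (mean tumor molecules per mL,
   MTM);
2. derivation of per-visit level and change metrics and assembly of landmark
   feature matrices;
3. a landmark-rebaselined elastic-net Cox model with leave-one-out
   cross-validation (LOOCV), nested penalty selection, and
   retention/next-door feature ranking;
4. molecular response calling (mPD / mSD / mResp) from two data-derived
   score thresholds; and
5. simulation of early go/no-go trial operating characteristics with
   false-go calibration.

Because the real trial data this kind of analysis targets sit behind
controlled access, the package ships a synthetic cohort generator whose
output has the statistical structure the downstream stages assume. All tests
run against generated data.

## Assay post-processing

The variant allele fraction (VAF) of a tracked mutation is estimated from
consensus read counts as `NRv / (NRv + NRr)`; equivocal reads are excluded
from numerator and denominator, and a zero informative denominator yields a
missing value rather than zero. Observed VAFs are classified against a
presumed-normal panel: *positive* requires at least 2 variant-supporting
reads and a VAF above the panel maximum; *negative* requires a VAF below the
panel's 0.95 quantile; anything else is *equivocal*. When a degenerate panel
makes both rules fire, positive takes precedence because it is the stricter,
read-count-backed condition. Both per-locus and pooled panels are supported,
since presumed-normal comparisons can be run either way.

Reported allele fractions below the limit of quantitation (LOQ, default
0.5%) are censored to LOQ/2, and those below the limit of detection (LOD,
default 0.1%) to LOQ/4. A zero AF denotes an unreported variant and stays 0:
censoring applies to *reported* mutations only. The map is idempotent and
order-preserving, which the test suite verifies as a property.

Variants positive in matched PBMCs are presumed germline or CHIP-derived and
removed before burden computation (kept in an audit channel). The per-sample
burden is

$$\mathrm{MTM} = \overline{\mathrm{AF}}_{\text{somatic, positive}} \times
\frac{[\mathrm{cfDNA}]\ (\mathrm{ng/mL})}{0.0033\ \mathrm{ng\ per\ haploid\ genome}}$$

No published formula pins MTM down exactly; this definition (mean censored
somatic AF times haploid genome equivalents per mL, 3.3 pg per genome,
configurable) was chosen because it reproduces the tight rank correlation
between MTM and mean AF that is observed in practice, which the suite
asserts at Spearman ≥ 0.8.

## Feature engine

A `metric_catalog()` is a named list of level metrics (functions of one
sample) and change metrics (functions of the baseline sample, one
on-treatment sample, and the history). The defaults cover the families that
matter in this setting — detection indicator, mutation counts (total and
pathogenic), AF summaries, MTM and log10(MTM+1), cfDNA concentration, and
per-visit absolute/percent/log-fold changes, clearance (MTM < 1), the
time-weighted MTM AUC and the on-treatment maximum. Published feature lists
of this kind run to ~19–23 level and ~55–59 change metrics; the exact
membership is supplementary material we treat as configuration, so the
catalog is extensible and every structural test derives expected counts from
the catalog itself rather than hard-coding them. The log fold change is
shifted, `log10((x+1)/(y+1))`, so it is defined for zero burden on either
side; the unshifted percent change is missing when the baseline is zero.

Landmark assembly includes one row per patient with a collection *record* at
the landmark visit — a QC-failed sample keeps its row with missing ctDNA
cells, because earlier visits may still carry signal — and columns for every
visit up to the landmark. Missing cells are median-imputed; imputation
medians and the interquartile-range (IQR) scalers are fit on the training
population only and frozen for test/external application. All quantiles in
the package (panel 0.95, IQR, threshold percentiles, go-cutoff calibration)
use linear interpolation between order statistics (R type 7), stated once
here and used everywhere.

## Landmark survival model

To remove immortal-time bias, patients with events at or before the
landmark collection day are excluded and times re-measured from that day;
the boundary is strict (rebaselined time must be positive). The elastic-net
Cox model uses an equal mix of lasso and ridge penalties (alpha = 0.5).
Within every leave-one-out fold the penalty is chosen by 5-fold nested
cross-validation of the partial-likelihood deviance, repeated 10 times with
the error-minimizing lambda averaged across repeats; imputation and scaling
are refit inside each fold so no held-out information can leak (a property
the suite checks by perturbing a held-out row and asserting the fold
scalers are unchanged). Penalized fits use the software's standard tie
approximation; descriptive two-group Cox models use the exact tie method.

Feature importance combines *retention* (the fraction of folds selecting
the feature) with a *next-door gain*: the worsening of the fold's
partial-likelihood deviance when the feature is forced out and the model
refit at the same penalty, averaged over selecting folds. A full inner
cross-validation per fold-and-feature would multiply the cost of an already
quadratic procedure beyond usefulness, so the gain is evaluated on the
fold's training deviance; this is the one place where the package
deliberately substitutes a cheaper statistic for an exactly-specified one,
and it preserves the sign behavior that matters (removing an informative
feature worsens the fit).

The final model is an unpenalized Cox fit of the top features (retention ≥
0.5 and positive gain) on the full training set — plain coefficients
transfer to external cohorts — with a ridge-stabilized fallback for
degenerate designs. Higher score means higher risk.

### Thresholds and molecular response

Two thresholds bin the continuous score. The high-risk (mPD) threshold is
chosen within the week-6 radiographic SD and PR subgroups separately: the
candidate grid is the observed scores restricted to the interior 10–90%
quantile range (avoiding degenerate tails), the optimum maximizes the
log-rank chi-square of the induced split with ties broken toward the
smaller threshold, and the final threshold is the mean of the two subgroup
optima. Choosing "the optimal split" could also be done visually; log-rank
maximization is the reproducible operationalization adopted here. The
low-risk threshold is the p-th percentile of the training scores, where p is
the fraction of at-risk training patients with observed survival of at
least 36 months; "durable" means the observed time reaches the horizon,
whether the patient was censored afterwards or died afterwards — patients
censored before the horizon do not count as durable. By construction the
training mResp fraction equals p to within one order-statistic rank.

Calls: score ≥ mPD threshold → mPD; score < mResp threshold → mResp;
otherwise mSD. Boundaries belong to the higher-risk side, matching the
half-open reference binning (e.g. thresholds 0.036/0.298 used as frozen
reference constants in the tests).

### Concordance machinery

Harrell's c-index is computed by direct pair enumeration: a pair is usable
when the ordering of the survival times is certain under censoring, and
tied predictions count 1/2. The standard error comes from the linearized
variance of the ratio-of-U-statistics form of Somers' Dxy, the p-value
tests against 0.5 under asymptotic normality, and two predictors on shared
data are compared through the variance of their per-subject influence
differences (a paired U-statistic). The estimate agrees exactly with an
independent brute-force enumeration and with `survival::concordance` on
tie-free data; the SE is validated by simulation (empirical sd 0.039 vs
mean reported SE 0.040 at n = 100) and by the uniformity of null p-values.

A caveat the package documents rather than hides: the pooled LOOCV c-index
of a *null* model is not exactly 0.5 on average. Leave-one-out estimation
noise is slightly anti-correlated with the held-out outcome, which biases
the pooled estimate downward by roughly 0.02 at n = 200 with 20 null
features, with a seed-to-seed spread of about ±0.05 (the sampling sd of any
noise predictor's c-index at that size). The null-calibration checks
therefore run against a fixed null dataset.

## Trial operating characteristics

Early-phase go/no-go simulation resamples 30 patients per arm with
replacement (2,000 simulated trials). Endpoints near week 6: molecular
response counts (one-sided Fisher exact test, implemented as the exact
hypergeometric tail), radiographic response counts (same test), early PFS
(one-sided log-rank from the signed statistic's normal tail), and min-p
combinations of ctDNA with either radiographic endpoint. Small p favors the
active arm; a zero statistic gives p = 0.5, and p = 1 is reserved for
undefined tests (no events or zero variance).

The go cutoff for an endpoint is the 15% (target false-go) percentile of
the p-values from 2,000 null control-vs-control trials; Go means p <
cutoff. Combined endpoints are calibrated on the null distribution of the
min-p statistic itself — the only reading consistent with a fixed false-go
design, since a naive per-test cutoff inflates the combined rate (both
behaviors are demonstrated in the tests). True and false go rates are then
measured on independent active-vs-control and null simulation sets.

Follow-up rules: under instantaneous enrollment every patient's PFS is
administratively censored at day 56 (the C3D1 visit day 42 plus a 14-day
assay turnaround — the horizon mirrors the ramp-up logic and is
configurable, since "week-6 PFS" could also be censored at day 42). Under
ramp-up enrollment the calendar cutoff is the last enrolled patient's C3D1
day plus turnaround, each patient's follow-up is truncated at cutoff minus
their own enrollment day, and resampled patient sets must have enrollment
days within 12 months of each other (enforced per resampled arm by
rejection sampling with a bounded retry budget).

## The synthetic cohort generator

The generator emulates a three-arm (~1:1:1) first-line trial with plasma at
baseline and days 21/42/63/147 of a 21-day cycle. Its defaults are the
study conditions the rest of the package is tested under:

* **Baseline positivity 0.85**; positive patients carry 1 + Poisson(3)
  somatic variants with lognormal allele fractions centred so the median
  per-patient mean AF is near 1.4%, and cfDNA concentrations (lognormal,
  median 15 ng/mL) put the median positive baseline burden near 64 MTM.
* **Latent response class** (CR/PR 45%, SD 40%, PD 15% in the control arm;
  active arms shift probability into CR/PR — +0.15 and +0.05 by default — so
  treatment benefit reaches the early molecular and radiographic endpoints,
  not just the hazard offsets) drives the
  cumulative on-treatment multiplier of the true tumor AF (e.g. CR/PR 0.27
  at C3D1, tuned so the mean C3D1 MTM reduction in responders is near
  −70%), with lognormal noise (sdlog 0.5) shared by all of a patient's
  somatic variants. CHIP variants stay flat and appear in the matched PBMC
  calls.
* **Observation layer**: read support is binomial at Poisson-distributed
  depth (mean 5,400×), which produces natural limit-of-detection behavior
  for small allele fractions; cfDNA has a patient-level random effect
  (between-sd 0.5, within-sd 0.3 on the log scale) so within-patient
  concentration ratios are stable — without it, per-visit concentration
  noise of that size would wash out the trajectory signal in MTM ratios.
* **Survival** is exponential proportional hazards on log10(baseline MTM+1)
  and the log10 C3D1 burden fold change (inverse-transform sampling;
  closed form makes parameter-recovery oracles easy), with per-arm
  log-hazard offsets, medians 19 months (OS) and 8 months (PFS) at the
  covariate centre, and uniform administrative censoring at 30–45 months.
* **Radiology**: the latent class plus the patient's realized trajectory
  deviation drive the week-6 SLD percent change (class means −42/−8/+28),
  RECIST categories follow the standard cut-offs (≤ −30% CR/PR, ≥ +20% PD),
  and baseline SLD is correlated with log baseline burden at ~0.37 through
  a shared normal factor.
* **Missingness**: samples scheduled after progression are not collected;
  5% of collected samples fail QC and keep their collection record with no
  variant data, exercising the imputation path.

What the generator does **not** emulate: real mutational signatures or
genomic coordinates (variant ids are opaque tokens with a gene label),
sequencing chemistry or error correction, informative censoring,
post-study treatment effects on OS (reported as largely unobservable in
this setting, so the generator ignores them), and any correlation structure
among features beyond what the shared latent class induces. Tests passing
on this cohort therefore demonstrate that the pipeline's statistics behave
as designed under a known generative model — not that the model would
achieve any particular accuracy on real trial data.

## Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation everywhere.
* Events exactly on the landmark day are excluded (strict positivity).
* Zero informative reads → missing VAF, never zero.
* All-constant feature matrices: empty selection, constant predictions,
  c-index 0.5 by the tie convention.
* mPD split ties break toward the smaller threshold; subgroups need ≥ 10
  at-risk patients.
* Fisher p-values use the exact tail, no mid-p correction.
* Ramp-up resampling retries are bounded (default 10,000) and then error.
* LOOCV refuses fewer than 20 at-risk patients; non-convergent folds are
  flagged and excluded from pooling rather than silently dropped.

## Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: cohort-structure checks use 1,000–
2,000 patients where a proportion is being estimated and 25–150 otherwise;
the LOOCV null-calibration check runs once at n = 200 with 20 features; the
parameter-recovery check runs 10 seeds at n = 150 with 10 features; the
false-go calibration uses the full 2 × 2,000 + 2,000 simulated trials at 30
patients per arm; coverage simulations use 100–200 replicates. A
smoke-scale null-calibration property (3 seeds, n = 60) runs in the unit
suite; the full-size check lives with the acceptance tests.
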