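# ctdnakit

Longitudinal circulating tumor DNA (ctDNA) kinetics carry an early survival
signal in randomized oncology trials: tumor-derived mutant allele fractions
in plasma fall within one or two treatment cycles in patients who go on to
do well, and rise in patients who progress. `ctdnakit` implements the full
analysis chain for turning serial plasma variant read counts into early
trial decisions, for biostatisticians and translational scientists working
with liquid-biopsy data:

* **Assay post-processing** — variant allele fractions from consensus read
  counts (`VAF = NRv/(NRv + NRr)`), classification against a presumed-normal
  panel, censoring of sub-quantitation fractions (below LOQ → LOQ/2, below
  LOD → LOQ/4), germline/CHIP removal via matched PBMC calls, and the
  per-sample burden `MTM = mean somatic AF × cfDNA genome equivalents/mL`.
* **Feature engine** — a configurable catalog of per-visit ctDNA level and
  change metrics, landmark feature matrices (all visits up to the landmark),
  train-population median imputation and IQR scaling.
* **Landmark survival model** — rebaselined survival (patients with events
  at or before the landmark are excluded, times re-measured), an elastic-net
  Cox model (alpha = 0.5) under leave-one-out cross-validation with 10-fold-
  repeated nested penalty selection, feature ranking by retention and
  next-door gain, a final unpenalized Cox fit, and molecular response calls
  (mResp / mSD / mPD) from two data-derived score thresholds. Harrell's
  c-index with asymptotic standard errors and paired model comparison.
* **Trial simulation** — resampled 30-per-arm early-phase trials, one-sided
  Fisher / log-rank early endpoints and min-p combinations, go cutoffs
  calibrated to a target false-go rate on null trials, instantaneous and
  ramp-up enrollment.
* **Synthetic cohort generator** — a three-arm randomized cohort with
  response-class-driven ctDNA trajectories, proportional-hazards survival
  linked to ctDNA burden, week-6 radiology, CHIP contamination,
  progression-driven dropout and QC failures, so the whole chain is testable
  without access to controlled trial data.

The model at the core is a landmark Cox risk score
`s(x) = sum_j beta_j x_j` on IQR-scaled ctDNA features, with
molecular-response bins `mResp: s < t_lo`, `mSD: t_lo <= s < t_hi`,
`mPD: s >= t_hi`, where `t_hi` maximizes the log-rank split within week-6
radiographic SD and PR subgroups (mean of the two optima) and `t_lo` is the
score percentile matching the durable (36-month) survival proportion.

## Worked example

```r
library(ctdnakit)

res <- run_pipeline(
  cohort_cfg = cohort_config(n_patients = 240, seed = 7),
  control    = enet_control(nested_repeats = 3, seed = 7),
  trial_cfg  = trial_sim_config(n_sims = 1000, endpoints = c("mresp", "recist")),
  seed = 7)

res$loocv
res$model
res$go_rates
```

```
LOOCV elastic-net Cox model: 108 folds (0 flagged)
  pooled c-index 0.566 (se 0.037, p vs 0.5 = 0.0732)
  top features by retention:
    C3D1:log10_mtm               retention 1.00  gain +1.92
    C2D1_change:mtm_change       retention 0.86  gain +0.79
    C3D1:n_mut                   retention 0.66  gain +0.11
    C3D1_change:cfdna_conc_change retention 0.21  gain +0.13
    C3D1:n_path_mut              retention 0.21  gain +0.09

ctDNA landmark risk model (3 features, n = 108)
  C3D1:log10_mtm                 +0.4623
  C2D1_change:mtm_change         -0.0334
  C3D1:n_mut                     +0.0926
  training c-index 0.653
  thresholds: mResp < 0.5638 <= mSD < 0.7698 <= mPD

  active_arm endpoint    cutoff true_go_rate false_go_rate n_sims
1        ACP    mresp 0.2109877        0.071         0.156   1000
2        ACP   recist 0.2147846        0.433         0.158   1000
3       ABCP    mresp 0.2109877        0.023         0.156   1000
4       ABCP   recist 0.2147846        0.523         0.158   1000
```

Reading the output: the pooled LOOCV c-index (0.566) estimates out-of-sample
rank concordance between the risk score and landmark overall survival; the
top features are dominated by C3D1 burden (log10 MTM), the early MTM change
and the mutation count, and the final training fit on the three retained
features reaches c = 0.653. The two score thresholds split the scores into
molecular response groups, and the trial simulation reports, per active arm
and endpoint, the probability of an early Go decision at a cutoff calibrated
so that a null comparison triggers Go 15% of the time (realized 15.6–15.8%
here on independent null trials). In this synthetic configuration the
treatment benefit expresses itself mostly through radiographic response
(true go up to 0.52), while the ctDNA-model endpoint carries little
arm-level signal at this test-set size — with only ~35 held-back patients
per arm, the frozen resampling pool makes per-arm molecular-response rates
noisy. The vignette discusses what the synthetic cohort does and does not
emulate about real trial data.

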