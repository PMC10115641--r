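# Shared fixture builders. Everything is generated in code at test time.

small_cohort <- function(n = 60, seed = 42, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

processed_cohort <- function(n = 60, seed = 42, ...) {
  process_assay(small_cohort(n = n, seed = seed, ...))
}

# Simulated survival with p independent-normal features; optionally one
# informative feature with the given log hazard ratio per unit (features are
# unit-scale so per-IQR effects are set via the coefficient).
sim_survival_matrix <- function(n, p, beta = rep(0, p), seed = 1,
                                censor_prob = 0.3, base_time = 500) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%04d", seq_len(n)),
                              sprintf("F%02d", seq_len(p))))
  lp <- drop(x %*% beta)
  tt <- rexp(n, rate = exp(lp) / base_time)
  ev <- rbinom(n, 1, 1 - censor_prob) == 1
  list(x = x,
       data = data.frame(patient_id = rownames(x), time = tt, event = ev,
                         stringsAsFactors = FALSE))
}

# A minimal processed plasma-sample object for metric tests.
mk_sample <- function(afs = numeric(0), pathogenic = rep(TRUE, length(afs)),
                      cfdna = 10, qc_pass = TRUE, mtm = NULL, day = 0,
                      classification = rep("positive", length(afs))) {
  if (is.null(mtm))
    mtm <- if (length(afs)) mean(afs) * cfdna / 0.0033 else 0
  list(visit = "BL", day = day, cfdna_ng_ml = cfdna, qc_pass = qc_pass,
       mtm = mtm,
       obs = data.frame(censored_af = afs, pathogenic = pathogenic,
                        classification = classification,
                        stringsAsFactors = FALSE))
}
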