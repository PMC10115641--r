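#' Configuration for the synthetic randomized ctDNA cohort generator
#'
#' Builds and validates the parameter set that [generate_cohort()] consumes.
#' Defaults emulate a three-arm first-line NSCLC chemo-immunotherapy trial with
#' plasma collected at baseline and on a 21-day dosing cycle, ~85% baseline
#' ctDNA positivity, response-class-dependent on-treatment ctDNA trajectories,
#' progression-driven sample dropout, and survival times linked to ctDNA burden
#' and early trajectory through a proportional-hazards mechanism.
#'
#' @param n_patients Number of patients to simulate.
#' @param arm_labels Three arm labels; the first is the control arm.
#' @param arm_probs Randomization probabilities (must sum to 1).
#' @param visit_days Named integer vector of plasma collection days from
#'   randomization. Must start at `BL = 0` and be strictly increasing.
#' @param baseline_positivity Probability a patient carries at least one
#'   baseline somatic (tumor-derived) variant.
#' @param response_mix Probabilities of the latent radiographic response
#'   classes `CRPR`, `SD`, `PD` (must sum to 1) in the control arm.
#' @param arm_response_boost Named per-arm increase of the CR/PR probability
#'   (taken proportionally from SD and PD), the mechanism through which
#'   treatment benefit reaches the early ctDNA and radiographic endpoints.
#'   Control must be 0.
#' @param class_multipliers Matrix (rows `CRPR`, `SD`, `PD`; columns the
#'   on-treatment visits) of cumulative multiplicative change in true tumor
#'   allele fraction relative to baseline.
#' @param traj_sdlog Lognormal sd of per-patient-visit noise around the class
#'   trajectory multiplier.
#' @param hazard_coefficients Named log-hazard weights: `os_burden`, `os_traj`,
#'   `pfs_burden`, `pfs_traj`. Burden enters as log10(true baseline MTM + 1)
#'   and trajectory as log10 of the realized C3D1 burden fold change.
#' @param arm_effects_os,arm_effects_pfs Named per-arm log-hazard offsets
#'   (control should be 0).
#' @param mutation_count_mean Mean of the Poisson count of additional somatic
#'   variants beyond the first, for ctDNA-positive patients.
#' @param chip_rate Probability a patient carries PBMC-shared (CHIP) variants.
#' @param read_depth Mean consensus sequencing depth per variant.
#' @param af_meanlog,af_sdlog_between,af_sdlog_within Lognormal parameters of
#'   baseline somatic allele fractions: patient-level centre spread
#'   (`between`) and variant-level spread (`within`). The default centre
#'   `log(0.014)` puts the median per-patient mean AF near 1.4%.
#' @param cfdna_meanlog,cfdna_sdlog_between,cfdna_sdlog_within Lognormal
#'   parameters of plasma cfDNA concentration in ng/mL: a patient-level
#'   random effect (`between`) plus per-sample variation (`within`), so
#'   concentrations are correlated within a patient across visits.
#' @param os_median_days,pfs_median_days Baseline-hazard medians (exponential)
#'   for overall and progression-free survival at the centred covariate value.
#' @param followup_days Length-2 range (days) of the administrative censoring
#'   time, drawn uniformly per patient.
#' @param sld_burden_cor Target correlation between log baseline tumor size
#'   (SLD) and log10 baseline ctDNA burden.
#' @param dropout_rule If `TRUE`, plasma samples scheduled after a patient's
#'   progression (or death) are not collected.
#' @param qc_fail_rate Probability a collected plasma sample fails ctDNA assay
#'   QC (collection record kept, no variant data).
#' @param enrollment_window_days Span of the uniform staggered-enrollment
#'   window.
#' @param seed Integer seed; [generate_cohort()] is deterministic given it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 240,
                          arm_labels = c("BCP", "ABCP", "ACP"),
                          arm_probs = c(1, 1, 1) / 3,
                          visit_days = c(BL = 0, C2D1 = 21, C3D1 = 42,
                                         C4D1 = 63, C8D1 = 147),
                          baseline_positivity = 0.85,
                          response_mix = c(CRPR = 0.45, SD = 0.40, PD = 0.15),
                          arm_response_boost = c(BCP = 0, ABCP = 0.15,
                                                 ACP = 0.05),
                          class_multipliers = default_class_multipliers(),
                          traj_sdlog = 0.5,
                          hazard_coefficients = c(os_burden = 0.4, os_traj = 0.9,
                                                  pfs_burden = 0.3, pfs_traj = 1.1),
                          arm_effects_os = c(BCP = 0, ABCP = -0.3, ACP = -0.15),
                          arm_effects_pfs = c(BCP = 0, ABCP = -0.35, ACP = -0.2),
                          mutation_count_mean = 3,
                          chip_rate = 0.25,
                          read_depth = 5400,
                          af_meanlog = log(0.014),
                          af_sdlog_between = 1.0,
                          af_sdlog_within = 0.7,
                          cfdna_meanlog = log(15),
                          cfdna_sdlog_between = 0.5,
                          cfdna_sdlog_within = 0.3,
                          os_median_days = 578,
                          pfs_median_days = 244,
                          followup_days = c(1065, 1460),
                          sld_burden_cor = 0.37,
                          dropout_rule = TRUE,
                          qc_fail_rate = 0.05,
                          enrollment_window_days = 365,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, arm_labels = arm_labels, arm_probs = arm_probs,
    visit_days = visit_days, baseline_positivity = baseline_positivity,
    response_mix = response_mix, arm_response_boost = arm_response_boost,
    class_multipliers = class_multipliers,
    traj_sdlog = traj_sdlog, hazard_coefficients = hazard_coefficients,
    arm_effects_os = arm_effects_os, arm_effects_pfs = arm_effects_pfs,
    mutation_count_mean = mutation_count_mean, chip_rate = chip_rate,
    read_depth = read_depth, af_meanlog = af_meanlog,
    af_sdlog_between = af_sdlog_between, af_sdlog_within = af_sdlog_within,
    cfdna_meanlog = cfdna_meanlog, cfdna_sdlog_between = cfdna_sdlog_between,
    cfdna_sdlog_within = cfdna_sdlog_within,
    os_median_days = os_median_days, pfs_median_days = pfs_median_days,
    followup_days = followup_days, sld_burden_cor = sld_burden_cor,
    dropout_rule = dropout_rule, qc_fail_rate = qc_fail_rate,
    enrollment_window_days = enrollment_window_days, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_class_multipliers <- function() {
  # Cumulative fold change of true tumor AF relative to baseline; the CRPR row
  # is tuned so the mean on-treatment MTM reduction at C3D1 is near -70%.
  rbind(
    CRPR = c(C2D1 = 0.45, C3D1 = 0.27, C4D1 = 0.18, C8D1 = 0.10),
    SD   = c(C2D1 = 0.90, C3D1 = 0.80, C4D1 = 0.75, C8D1 = 0.65),
    PD   = c(C2D1 = 1.40, C3D1 = 1.80, C4D1 = 2.20, C8D1 = 2.80)
  )
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients))
    stop_config("n_patients", "must be a positive integer")
  if (length(cfg$arm_labels) != 3L || anyDuplicated(cfg$arm_labels))
    stop_config("arm_labels", "must be 3 distinct labels (control first)")
  check_prob(cfg$arm_probs, "arm_probs")
  if (abs(sum(cfg$arm_probs) - 1) > 1e-12)
    stop_config("arm_probs", "must sum to 1")
  vd <- cfg$visit_days
  if (is.null(names(vd)) || names(vd)[1] != "BL" || vd[[1]] != 0)
    stop_config("visit_days", "must be named and start at BL = 0")
  if (any(diff(vd) <= 0))
    stop_config("visit_days", "must be strictly increasing")
  check_prob(cfg$baseline_positivity, "baseline_positivity")
  check_prob(cfg$response_mix, "response_mix")
  if (abs(sum(cfg$response_mix) - 1) > 1e-12)
    stop_config("response_mix", "must sum to 1")
  if (!setequal(names(cfg$response_mix), c("CRPR", "SD", "PD")))
    stop_config("response_mix", "classes must be CRPR, SD, PD")
  if (!all(cfg$arm_labels %in% names(cfg$arm_response_boost)))
    stop_config("arm_response_boost", "must name every arm")
  boost <- cfg$arm_response_boost[cfg$arm_labels]
  if (boost[[1]] != 0)
    stop_config("arm_response_boost", "control arm boost must be 0")
  if (any(boost < 0) || any(cfg$response_mix[["CRPR"]] + boost >= 1))
    stop_config("arm_response_boost", "boosted CR/PR probability outside [0, 1)")
  cm <- cfg$class_multipliers
  if (!is.matrix(cm) || !setequal(rownames(cm), c("CRPR", "SD", "PD")) ||
      !all(names(vd)[-1] %in% colnames(cm)))
    stop_config("class_multipliers",
                "must be a CRPR/SD/PD x on-treatment-visit matrix")
  if (any(cm <= 0)) stop_config("class_multipliers", "must be positive")
  hc <- cfg$hazard_coefficients
  if (!all(c("os_burden", "os_traj", "pfs_burden", "pfs_traj") %in% names(hc)))
    stop_config("hazard_coefficients",
                "must name os_burden, os_traj, pfs_burden, pfs_traj")
  for (f in c("arm_effects_os", "arm_effects_pfs"))
    if (!all(cfg$arm_labels %in% names(cfg[[f]])))
      stop_config(f, "must name every arm")
  if (cfg$read_depth <= 0) stop_config("read_depth", "must be > 0")
  check_prob(cfg$chip_rate, "chip_rate")
  check_prob(cfg$qc_fail_rate, "qc_fail_rate")
  if (cfg$mutation_count_mean < 0)
    stop_config("mutation_count_mean", "must be >= 0")
  if (length(cfg$followup_days) != 2L || any(cfg$followup_days <= 0) ||
      diff(cfg$followup_days) < 0)
    stop_config("followup_days", "must be an increasing positive range")
  if (cfg$os_median_days <= 0 || cfg$pfs_median_days <= 0)
    stop_config("os_median_days", "survival medians must be > 0")
  if (abs(cfg$sld_burden_cor) >= 1)
    stop_config("sld_burden_cor", "must be in (-1, 1)")
  if (cfg$enrollment_window_days < 0)
    stop_config("enrollment_window_days", "must be >= 0")
  check_flag(cfg$dropout_rule, "dropout_rule")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ctDNA cohort configuration\n")
  cat(sprintf("  patients: %d  arms: %s\n", x$n_patients,
              paste(x$arm_labels, collapse = "/")))
  cat(sprintf("  visits: %s\n",
              paste(sprintf("%s=%d", names(x$visit_days), x$visit_days),
                    collapse = " ")))
  cat(sprintf("  baseline positivity: %.2f  chip rate: %.2f  depth: %d\n",
              x$baseline_positivity, x$chip_rate, round(x$read_depth)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
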