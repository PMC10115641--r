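#' Generate a synthetic randomized trial cohort with longitudinal ctDNA
#'
#' Draws a cohort whose statistical structure matches what the downstream
#' analysis assumes: a latent radiographic response class drives both the
#' on-treatment ctDNA trajectory and the week-6 tumor size change through a
#' shared factor; survival times follow an exponential proportional-hazards
#' model on log10 baseline ctDNA burden and the log10 C3D1 burden fold change;
#' observed read support is binomial at the configured consensus depth, which
#' creates natural limit-of-detection behaviour; CHIP variants are shared
#' between plasma and PBMC and do not respond to therapy; plasma samples
#' scheduled after progression are not collected; QC-failed samples keep the
#' collection record but carry no variant data.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `ctdna_cohort`: a list of data frames
#'   `patients`, `samples`, `variants`, `pbmc`, `recist`, plus the `config`.
#'   `patients` carries the latent class and the true (noise-free) baseline
#'   burden used by the survival mechanism, which downstream code never reads.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 40, seed = 11))
#' table(coh$patients$arm)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  vd <- config$visit_days
  visits <- names(vd)
  on_tx <- visits[-1]

  patient_id <- sprintf("PT%04d", seq_len(n))
  arm <- sample(config$arm_labels, n, replace = TRUE, prob = config$arm_probs)
  enrollment_day <- floor(stats::runif(n, 0, config$enrollment_window_days))
  # latent class by inverse CDF so the mix can differ by arm: the active-arm
  # CR/PR boost is taken proportionally from SD and PD
  mix <- config$response_mix[c("CRPR", "SD", "PD")]
  boost <- config$arm_response_boost[arm]
  p_crpr <- mix[["CRPR"]] + boost
  rest <- (1 - p_crpr) / (mix[["SD"]] + mix[["PD"]])
  u <- stats::runif(n)
  latent_class <- ifelse(u < p_crpr, "CRPR",
                   ifelse(u < p_crpr + mix[["SD"]] * rest, "SD", "PD"))

  # baseline covariates
  age <- pmax(25, round(stats::rnorm(n, 63, 9)))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  ecog <- stats::rbinom(n, 1, 0.55)
  smoker <- sample(c("y", "n"), n, replace = TRUE, prob = c(0.8, 0.2))
  n_met_sites <- 1L + stats::rpois(n, 1.2)

  # somatic variant truth
  positive <- stats::rbinom(n, 1, config$baseline_positivity) == 1
  n_somatic <- ifelse(positive, 1L + stats::rpois(n, config$mutation_count_mean), 0L)
  chip_carrier <- stats::rbinom(n, 1, config$chip_rate) == 1
  n_chip <- ifelse(chip_carrier, sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3)), 0L)
  patient_meanlog <- stats::rnorm(n, config$af_meanlog, config$af_sdlog_between)

  somatic_genes <- c("TP53", "KRAS", "STK11", "EGFR", "KEAP1", "PIK3CA",
                     "BRAF", "MET", "NF1", "ARID1A")
  somatic_gene_w <- c(52, 23, 13, 10, 8, 6, 4, 4, 3, 3)
  chip_genes <- c("DNMT3A", "TET2", "ASXL1", "PPM1D", "CHEK2", "JAK2")

  var_list <- vector("list", n)
  for (i in seq_len(n)) {
    ns <- n_somatic[i]; nc <- n_chip[i]
    if (ns + nc == 0L) next
    af_som <- if (ns > 0)
      pmin(exp(stats::rnorm(ns, patient_meanlog[i], config$af_sdlog_within)), 0.45)
    else numeric(0)
    af_chip <- if (nc > 0) pmin(stats::rlnorm(nc, log(0.01), 0.7), 0.35) else numeric(0)
    var_list[[i]] <- data.frame(
      patient_id = patient_id[i],
      variant_id = sprintf("%s_v%02d", patient_id[i], seq_len(ns + nc)),
      gene = c(if (ns > 0) sample(somatic_genes, ns, TRUE, somatic_gene_w),
               if (nc > 0) sample(chip_genes, nc, TRUE)),
      pathogenic = c(if (ns > 0) stats::rbinom(ns, 1, 0.7) == 1,
                     if (nc > 0) rep(FALSE, nc)),
      is_chip = rep(c(FALSE, TRUE), c(ns, nc)),
      af_bl = c(af_som, af_chip),
      stringsAsFactors = FALSE
    )
  }

  # realized per-patient trajectory multipliers (tumor-wide, shared by all
  # somatic variants of a patient; CHIP variants stay flat)
  mult <- matrix(1, n, length(visits), dimnames = list(patient_id, visits))
  for (v in on_tx)
    mult[, v] <- config$class_multipliers[latent_class, v] *
      stats::rlnorm(n, 0, config$traj_sdlog)

  # true baseline burden and hazard covariates
  mean_af_bl <- vapply(seq_len(n), function(i) {
    vi <- var_list[[i]]
    if (is.null(vi) || !any(!vi$is_chip)) 0 else mean(vi$af_bl[!vi$is_chip])
  }, numeric(1))
  cf_meanlog <- stats::rnorm(n, config$cfdna_meanlog, config$cfdna_sdlog_between)
  cfdna_true <- stats::rlnorm(n, cf_meanlog, config$cfdna_sdlog_within)
  true_mtm_bl <- mean_af_bl * cfdna_true / 0.0033
  z_burden <- log10(true_mtm_bl + 1)
  z_traj <- log10(mult[, "C3D1"])
  # centring constants chosen at the typical cohort values so the configured
  # survival medians hold near the centre of the covariate distribution
  hc <- config$hazard_coefficients
  lp_os <- hc[["os_burden"]] * (z_burden - 1.8) +
    hc[["os_traj"]] * (z_traj - (-0.15)) +
    config$arm_effects_os[arm]
  lp_pfs <- hc[["pfs_burden"]] * (z_burden - 1.8) +
    hc[["pfs_traj"]] * (z_traj - (-0.15)) +
    config$arm_effects_pfs[arm]

  t_os <- stats::rexp(n, rate = log(2) / config$os_median_days * exp(lp_os))
  t_prog <- stats::rexp(n, rate = log(2) / config$pfs_median_days * exp(lp_pfs))
  cens <- stats::runif(n, config$followup_days[1], config$followup_days[2])
  os_time <- pmin(t_os, cens)
  os_event <- t_os <= cens
  pfs_raw <- pmin(t_prog, t_os)
  pfs_time <- pmin(pfs_raw, cens)
  pfs_event <- pfs_raw <= cens

  # baseline SLD correlated with log burden through a shared normal factor
  zb_std <- as.numeric(scale(z_burden))
  if (any(!is.finite(zb_std))) zb_std[!is.finite(zb_std)] <- 0
  rho <- config$sld_burden_cor
  latent_sld <- rho * zb_std + sqrt(1 - rho^2) * stats::rnorm(n)
  sld_bl <- round(exp(log(80) + 0.45 * latent_sld), 1)

  # week-6 SLD change: class mean plus coupling to the patient's realized
  # ctDNA trajectory deviation, plus independent noise
  class_mean_pct <- c(CRPR = -42, SD = -8, PD = 28)
  traj_dev <- z_traj - log10(config$class_multipliers[latent_class, "C3D1"])
  sld_pct <- class_mean_pct[latent_class] + 25 * traj_dev + stats::rnorm(n, 0, 10)
  sld_pct <- pmax(sld_pct, -100)
  week6_cat <- ifelse(sld_pct <= -99.5, "CR",
                ifelse(sld_pct <= -30, "PR",
                 ifelse(sld_pct >= 20, "PD", "SD")))
  week6_day <- unname(vd["C3D1"])
  week6_cat[pfs_event & pfs_time <= week6_day] <- "PD"
  has_week6 <- !(os_event & os_time < week6_day)

  patients <- data.frame(
    patient_id = patient_id, arm = arm, latent_class = latent_class,
    enrollment_day = enrollment_day, age = age, sex = sex, ecog = ecog,
    smoker = smoker, n_met_sites = n_met_sites, sld_bl = sld_bl,
    n_somatic_bl = n_somatic,
    os_time = round(os_time, 2), os_event = os_event,
    pfs_time = round(pfs_time, 2), pfs_event = pfs_event,
    true_mtm_bl = true_mtm_bl, stringsAsFactors = FALSE
  )

  recist <- data.frame(
    patient_id = patient_id[has_week6], week = 6L,
    sld = round(sld_bl[has_week6] * (1 + sld_pct[has_week6] / 100), 1),
    sld_pct_change = round(sld_pct[has_week6], 2),
    category = week6_cat[has_week6], stringsAsFactors = FALSE
  )

  # sample collection: dropout after progression/death, QC failures
  samp <- expand.grid(patient_id = patient_id, visit = visits,
                      stringsAsFactors = FALSE)
  samp <- samp[order(match(samp$patient_id, patient_id),
                     match(samp$visit, visits)), , drop = FALSE]
  samp$day <- vd[samp$visit]
  idx <- match(samp$patient_id, patient_id)
  collected <- samp$day == 0 |
    (samp$day <= os_time[idx] &
       (!config$dropout_rule | !(pfs_event[idx] & samp$day > pfs_time[idx])))
  samp <- samp[collected, , drop = FALSE]
  samp$cfdna_ng_ml <- round(stats::rlnorm(nrow(samp),
                                          cf_meanlog[match(samp$patient_id,
                                                           patient_id)],
                                          config$cfdna_sdlog_within), 3)
  # anchor baseline concentration at the value the survival mechanism used
  bl_rows <- samp$visit == "BL"
  samp$cfdna_ng_ml[bl_rows] <- round(cfdna_true[match(samp$patient_id[bl_rows],
                                                      patient_id)], 3)
  samp$qc_pass <- stats::rbinom(nrow(samp), 1, 1 - config$qc_fail_rate) == 1
  rownames(samp) <- NULL

  # observed read support for every tracked variant at every QC-passing sample
  all_vars <- do.call(rbind, var_list[!vapply(var_list, is.null, logical(1))])
  if (is.null(all_vars))
    all_vars <- data.frame(patient_id = character(), variant_id = character(),
                           gene = character(), pathogenic = logical(),
                           is_chip = logical(), af_bl = numeric())
  obs_samp <- samp[samp$qc_pass, c("patient_id", "visit")]
  vrows <- merge(obs_samp, all_vars, by = "patient_id", sort = FALSE)
  if (nrow(vrows)) {
    vrows <- vrows[order(match(vrows$patient_id, patient_id),
                         match(vrows$visit, visits), vrows$variant_id), ,
                   drop = FALSE]
    af_true <- vrows$af_bl *
      ifelse(vrows$is_chip, 1,
             mult[cbind(match(vrows$patient_id, patient_id),
                        match(vrows$visit, visits))])
    depth <- stats::rpois(nrow(vrows), config$read_depth)
    nrv <- stats::rbinom(nrow(vrows), depth, pmin(af_true, 1))
    nre <- stats::rpois(nrow(vrows), 0.005 * config$read_depth)
    variants <- data.frame(
      patient_id = vrows$patient_id, visit = vrows$visit,
      variant_id = vrows$variant_id, gene = vrows$gene,
      pathogenic = vrows$pathogenic, nrv = nrv, nrr = depth - nrv, nre = nre,
      stringsAsFactors = FALSE
    )
  } else {
    variants <- data.frame(patient_id = character(), visit = character(),
                           variant_id = character(), gene = character(),
                           pathogenic = logical(), nrv = integer(),
                           nrr = integer(), nre = integer())
  }
  rownames(variants) <- NULL

  pbmc <- all_vars[all_vars$is_chip, c("patient_id", "variant_id")]
  rownames(pbmc) <- NULL

  structure(list(patients = patients, samples = samp, variants = variants,
                 pbmc = pbmc, recist = recist, config = config),
            class = "ctdna_cohort")
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ctDNA cohort: %d patients, %d plasma samples, %d variant rows\n",
              nrow(x$patients), nrow(x$samples), nrow(x$variants)))
  print(table(arm = x$patients$arm))
  invisible(x)
}
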