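#' Configuration for early-endpoint trial operating-characteristic simulation
#'
#' @param n_per_arm Patients resampled per arm (default 30).
#' @param n_sims Number of simulated trials (default 2000).
#' @param target_false_go Desired false-go rate; the go cutoff is calibrated
#'   at this percentile of the null p-value distribution (default 0.15).
#' @param endpoints Subset of `"mresp"`, `"recist"`, `"pfs"`,
#'   `"mresp+recist"`, `"mresp+pfs"`; combined endpoints use the smaller of
#'   the two p-values.
#' @param enrollment_mode `"instantaneous"` (all patients share the early
#'   follow-up horizon) or `"ramp_up"` (calendar cutoff follows the last
#'   enrolled patient's C3D1 day plus assay turnaround).
#' @param turnaround_days Expected ctDNA assay turnaround (default 14).
#' @param enrollment_window_days Resampled patient sets must have enrollment
#'   days within this span (default 365; ramp-up mode only).
#' @param early_pfs_horizon_days Administrative censoring horizon for the
#'   early PFS endpoint under instantaneous enrollment; the default, C3D1 day
#'   42 plus 14-day turnaround = 56, mirrors the ramp-up logic.
#' @param c3d1_day Day of the C3D1 visit from enrollment.
#' @param max_retries Bound on rejection sampling of enrollment-feasible
#'   patient sets in ramp-up mode.
#' @param seed Integer seed.
#' @return A list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_per_arm = 30, n_sims = 2000,
                             target_false_go = 0.15,
                             endpoints = c("mresp", "recist", "pfs",
                                           "mresp+recist", "mresp+pfs"),
                             enrollment_mode = c("instantaneous", "ramp_up"),
                             turnaround_days = 14,
                             enrollment_window_days = 365,
                             early_pfs_horizon_days = 42 + 14,
                             c3d1_day = 42,
                             max_retries = 10000,
                             seed = 1L) {
  if (n_per_arm < 2) stop_config("n_per_arm", "must be >= 2")
  if (n_sims < 100) stop_config("n_sims", "must be >= 100")
  if (target_false_go <= 0 || target_false_go >= 1)
    stop_config("target_false_go", "must be in (0, 1)")
  known <- c("mresp", "recist", "pfs", "mresp+recist", "mresp+pfs")
  if (!all(endpoints %in% known))
    stop_config("endpoints", paste("must be among", paste(known, collapse = ", ")))
  structure(list(n_per_arm = n_per_arm, n_sims = n_sims,
                 target_false_go = target_false_go, endpoints = endpoints,
                 enrollment_mode = match.arg(enrollment_mode),
                 turnaround_days = turnaround_days,
                 enrollment_window_days = enrollment_window_days,
                 early_pfs_horizon_days = early_pfs_horizon_days,
                 c3d1_day = c3d1_day, max_retries = max_retries,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Apply the enrollment-mode follow-up rule to a resampled trial
#'
#' Instantaneous enrollment: every patient's PFS is administratively censored
#' at the early horizon. Ramp-up enrollment: the calendar cutoff is the
#' latest enrolled patient's C3D1 day plus the assay turnaround; each
#' patient's follow-up is truncated at cutoff minus their own enrollment day.
#' With all enrollments on day 0, ramp-up reduces to instantaneous.
#'
#' @param pfs_time,pfs_event Resampled PFS data (days from randomization).
#' @param enrollment_day Per-patient enrollment days (ramp-up mode).
#' @param config A [trial_sim_config()].
#' @return List with truncated `time` and `event`.
#' @export
apply_enrollment_mode <- function(pfs_time, pfs_event, enrollment_day = NULL,
                                  config = trial_sim_config()) {
  if (config$enrollment_mode == "instantaneous") {
    horizon <- rep(config$early_pfs_horizon_days, length(pfs_time))
  } else {
    if (is.null(enrollment_day))
      stop("ramp-up mode needs per-patient enrollment days", call. = FALSE)
    cutoff <- max(enrollment_day + config$c3d1_day) + config$turnaround_days
    horizon <- cutoff - enrollment_day
  }
  list(time = pmin(pfs_time, horizon),
       event = as.logical(pfs_event) & pfs_time <= horizon)
}

# Resample one arm (indices into df rows), honoring the ramp-up rule that the
# chosen patients' enrollment days span at most the configured window.
resample_arm <- function(rows, df, config) {
  if (config$enrollment_mode == "instantaneous")
    return(sample(rows, config$n_per_arm, replace = TRUE))
  for (r in seq_len(config$max_retries)) {
    idx <- sample(rows, config$n_per_arm, replace = TRUE)
    if (diff(range(df$enrollment_day[idx])) <= config$enrollment_window_days)
      return(idx)
  }
  stop("no enrollment-feasible patient set found within retry bound",
       call. = FALSE)
}

#' Simulate resampled early-phase trials and compute endpoint p-values
#'
#' Each simulated trial draws `n_per_arm` patients per arm with replacement
#' (from the active and control arms; pass the control arm twice for null
#' trials), applies the enrollment-mode follow-up rule, and computes one
#' one-sided p-value per requested endpoint: Fisher's exact test on molecular
#' response counts (`mresp`) or radiographic response counts (`recist`), a
#' one-sided log-rank test on early PFS (`pfs`), and for combined endpoints
#' the smaller of the two component p-values. Small p-values favor the active
#' arm.
#'
#' @param df Per-patient data frame with columns `mresp` (logical),
#'   `recist_response` (logical), `pfs_time`, `pfs_event`, `enrollment_day`,
#'   and `arm`.
#' @param active_arm,control_arm Arm labels to resample from.
#' @param config A [trial_sim_config()].
#' @return Matrix `n_sims` x endpoints of p-values.
#' @export
simulate_trials <- function(df, active_arm, control_arm,
                            config = trial_sim_config()) {
  need <- list(mresp = "mresp", recist = "recist_response",
               pfs = c("pfs_time", "pfs_event"))
  base_eps <- unique(unlist(strsplit(config$endpoints, "+", fixed = TRUE)))
  for (ep in base_eps) {
    miss <- setdiff(need[[ep]], names(df))
    if (length(miss))
      stop(sprintf("endpoint '%s' needs column(s): %s", ep,
                   paste(miss, collapse = ", ")), call. = FALSE)
    if (any(is.na(df[need[[ep]]])))
      stop(sprintf("endpoint '%s' has missing data", ep), call. = FALSE)
  }
  act_rows <- which(df$arm == active_arm)
  ctl_rows <- which(df$arm == control_arm)
  if (!length(act_rows) || !length(ctl_rows))
    stop("empty arm", call. = FALSE)

  set.seed(config$seed)
  out <- matrix(NA_real_, config$n_sims, length(config$endpoints),
                dimnames = list(NULL, config$endpoints))
  n <- config$n_per_arm
  for (s in seq_len(config$n_sims)) {
    ia <- resample_arm(act_rows, df, config)
    ic <- resample_arm(ctl_rows, df, config)
    p <- c()
    if ("mresp" %in% base_eps)
      p["mresp"] <- fisher_one_sided(sum(df$mresp[ia]), n,
                                     sum(df$mresp[ic]), n)
    if ("recist" %in% base_eps)
      p["recist"] <- fisher_one_sided(sum(df$recist_response[ia]), n,
                                      sum(df$recist_response[ic]), n)
    if ("pfs" %in% base_eps) {
      idx <- c(ia, ic)
      fu <- apply_enrollment_mode(df$pfs_time[idx], df$pfs_event[idx],
                                  df$enrollment_day[idx], config)
      p["pfs"] <- logrank_one_sided(fu$time, fu$event,
                                    rep(c(TRUE, FALSE), each = n))
    }
    for (ep in config$endpoints) {
      parts <- strsplit(ep, "+", fixed = TRUE)[[1]]
      out[s, ep] <- min(p[parts])
    }
  }
  out
}

#' Calibrate the go cutoff at the target false-go percentile
#'
#' The cutoff is the target percentile (linear interpolation) of the null
#' (control-vs-control) p-value sample; a Go decision is `p < cutoff`.
#' Combined min-p endpoints are calibrated on the null distribution of the
#' min-p statistic itself, which preserves the target false-go rate where a
#' naive per-test cutoff would inflate it.
#'
#' @param null_pvalues Numeric vector (or one column of a
#'   [simulate_trials()] result) of null-trial p-values.
#' @param target_false_go Target false-go rate.
#' @return The go cutoff.
#' @export
calibrate_go_cutoff <- function(null_pvalues, target_false_go = 0.15) {
  if (!length(null_pvalues)) stop("empty null p-value sample", call. = FALSE)
  quantile7(null_pvalues, target_false_go)
}

#' Realized go rates at a calibrated cutoff
#'
#' @param active_pvalues P-values from active-vs-control trials.
#' @param null_pvalues_independent P-values from an independent set of null
#'   trials (not the calibration set).
#' @param cutoff Calibrated go cutoff.
#' @return List of class `go_rates` with `cutoff`, `true_go_rate`,
#'   `false_go_rate`.
#' @export
compute_go_rates <- function(active_pvalues, null_pvalues_independent, cutoff) {
  structure(list(cutoff = cutoff,
                 true_go_rate = mean(active_pvalues < cutoff),
                 false_go_rate = mean(null_pvalues_independent < cutoff)),
            class = "go_rates")
}

#' @export
print.go_rates <- function(x, ...) {
  cat(sprintf("go cutoff %.4g: true go %.1f%%, false go %.1f%%\n",
              x$cutoff, 100 * x$true_go_rate, 100 * x$false_go_rate))
  invisible(x)
}

#' Full operating-characteristic assessment for one active arm
#'
#' Runs the calibration-then-evaluation procedure per endpoint: 2 x `n_sims`
#' independent null (control-vs-control) trial sets — one to calibrate the go
#' cutoff at the target false-go percentile, one to measure the realized
#' false-go rate — and `n_sims` active-vs-control trials for the true go
#' rate.
#'
#' @param df Per-patient endpoint data (see [simulate_trials()]).
#' @param active_arm,control_arm Arm labels.
#' @param config A [trial_sim_config()].
#' @return Data frame: endpoint, cutoff, true_go_rate, false_go_rate.
#' @export
assess_operating_characteristics <- function(df, active_arm, control_arm,
                                             config = trial_sim_config()) {
  cfg_cal <- config; cfg_cal$seed <- config$seed
  cfg_nul <- config; cfg_nul$seed <- config$seed + 1L
  cfg_act <- config; cfg_act$seed <- config$seed + 2L
  p_cal <- simulate_trials(df, control_arm, control_arm, cfg_cal)
  p_nul <- simulate_trials(df, control_arm, control_arm, cfg_nul)
  p_act <- simulate_trials(df, active_arm, control_arm, cfg_act)
  rows <- lapply(config$endpoints, function(ep) {
    cut <- calibrate_go_cutoff(p_cal[, ep], config$target_false_go)
    gr <- compute_go_rates(p_act[, ep], p_nul[, ep], cut)
    data.frame(endpoint = ep, cutoff = cut, true_go_rate = gr$true_go_rate,
               false_go_rate = gr$false_go_rate, n_sims = config$n_sims,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
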