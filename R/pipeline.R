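#' Run the full ctDNA landmark analysis chain
#'
#' Orchestrates the stages end to end: cohort simulation (or a supplied
#' cohort), assay post-processing, landmark feature assembly, a stratified
#' train/test split, fold-safe imputation and IQR scaling, the LOOCV
#' elastic-net survival model, feature ranking, the final model with
#' molecular-response thresholds, test-set calls, and the early-endpoint
#' trial operating-characteristic simulation. Every stage derives its seed
#' from `seed`, so a configuration runs reproducibly.
#'
#' @param cohort A `ctdna_cohort`, or `NULL` to generate one from
#'   `cohort_cfg`.
#' @param cohort_cfg A [cohort_config()] (used when `cohort` is `NULL`).
#' @param landmark Landmark visit label.
#' @param endpoint `"os"` or `"pfs"` for the model endpoint.
#' @param catalog A [metric_catalog()].
#' @param control An [enet_control()].
#' @param trial_cfg A [trial_sim_config()] or `NULL` to skip the simulation.
#' @param train_fraction Fraction of patients assigned to training,
#'   stratified by arm.
#' @param out_dir If non-`NULL`, write `model.json`, `predictions.csv`,
#'   `go_rates.csv` and `summary.json` there.
#' @param seed Master seed.
#' @return A list with every intermediate object (`cohort`, `features`,
#'   `split`, `loocv`, `ranking`, `model`, `test_calls`, `go_rates`,
#'   `summary`).
#' @export
run_pipeline <- function(cohort = NULL, cohort_cfg = cohort_config(),
                         landmark = "C3D1", endpoint = "os",
                         catalog = metric_catalog(),
                         control = enet_control(),
                         trial_cfg = trial_sim_config(),
                         train_fraction = 0.5, out_dir = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(cohort)) {
    cohort_cfg$seed <- seed
    cohort <- generate_cohort(cohort_cfg)
  }
  proc <- process_assay(cohort)
  fm <- assemble_feature_matrix(proc, landmark, catalog)

  # stratified train/test split by arm, performed once
  set.seed(seed + 1L)
  ids <- rownames(fm$x)
  arm <- proc$patients$arm[match(ids, proc$patients$patient_id)]
  train_ids <- unlist(lapply(split(ids, arm), function(g)
    sample(g, round(train_fraction * length(g)))), use.names = FALSE)
  test_ids <- setdiff(ids, train_ids)

  lm_days <- landmark_days_for(proc, landmark)
  ld <- landmark_rebaseline(proc$patients, lm_days, endpoint)

  control$seed <- seed + 2L
  fm_train <- fm; fm_train$x <- fm$x[train_ids, , drop = FALSE]
  fm_train$mask <- fm$mask[train_ids, , drop = FALSE]
  loocv <- loocv_enet_cox(fm_train, ld, control)
  ranking <- rank_features(loocv)
  top <- ranking$feature[ranking$top]
  if (!length(top)) top <- utils::head(ranking$feature, 3)

  fm_imp <- impute_missing(fm, fit_rows = train_ids)
  scalers <- iqr_fit(fm_imp, fit_rows = train_ids)
  fm_sc <- iqr_apply(fm_imp, scalers)

  model <- fit_final_model(fm_sc$x[train_ids, , drop = FALSE], ld, top)
  recist_cat <- stats::setNames(proc$recist$category, proc$recist$patient_id)
  model <- set_thresholds(model, recist_cat, ld)

  test_scores <- predict(model, fm_sc$x[test_ids, , drop = FALSE])
  test_calls <- call_molecular_response(test_scores, model)

  go_rates <- NULL
  if (!is.null(trial_cfg)) {
    p <- proc$patients[match(test_ids, proc$patients$patient_id), ]
    rc <- recist_cat[test_ids]
    trial_df <- data.frame(
      patient_id = test_ids, arm = p$arm, enrollment_day = p$enrollment_day,
      pfs_time = p$pfs_time, pfs_event = p$pfs_event,
      mresp = test_calls == "mResp",
      recist_response = !is.na(rc) & rc %in% c("CR", "PR"),
      stringsAsFactors = FALSE
    )
    trial_cfg$seed <- seed + 3L
    control_arm <- cohort$config$arm_labels[1] %||% unique(p$arm)[1]
    active <- setdiff(unique(p$arm), control_arm)
    go_rates <- do.call(rbind, lapply(active, function(a) {
      g <- assess_operating_characteristics(trial_df, a, control_arm, trial_cfg)
      cbind(active_arm = a, g)
    }))
  }

  out <- list(configs = list(cohort = cohort$config, control = control,
                             trial = trial_cfg,
                             train_fraction = train_fraction),
              cohort = proc, features = fm_sc,
              split = list(train = train_ids, test = test_ids),
              landmark_data = ld, loocv = loocv, ranking = ranking,
              model = model,
              test_scores = test_scores, test_calls = test_calls,
              go_rates = go_rates, seed = seed)
  out$summary <- list(
    pooled_cindex = loocv$pooled_cindex$estimate,
    train_cindex = model$train_cindex$estimate,
    thresholds = c(mresp = model$mresp_threshold, mpd = model$mpd_threshold),
    test_call_rates = as.list(prop.table(table(test_calls)))
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# md5 of the serialized object, for config provenance in output metadata
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

# Landmark day per patient: the collection day of the landmark-visit sample.
landmark_days_for <- function(cohort, landmark) {
  s <- cohort$samples[cohort$samples$visit == landmark, ]
  stats::setNames(s$day, s$patient_id)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "ctdnakit",
               version = as.character(utils::packageVersion("ctdnakit")),
               seed = res$seed, config_hash = hash_object(res$configs))
  m <- res$model
  jsonlite::write_json(
    list(meta = meta, features = m$features,
         coefficients = as.list(m$coefficients),
         mpd_threshold = m$mpd_threshold, mresp_threshold = m$mresp_threshold,
         train_cindex = m$train_cindex$estimate),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(patient_id = names(res$test_scores),
               score = unname(res$test_scores),
               call = as.character(res$test_calls)),
    file.path(out_dir, "predictions.csv"), row.names = FALSE)
  if (!is.null(res$go_rates))
    utils::write.csv(res$go_rates, file.path(out_dir, "go_rates.csv"),
                     row.names = FALSE)
  fx <- res$features
  utils::write.csv(data.frame(patient_id = rownames(fx$x), fx$x,
                              check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(meta = meta, iqr = as.list(fx$scalers$iqr),
         constant = as.list(fx$scalers$constant),
         medians = as.list(fx$medians)),
    file.path(out_dir, "scalers.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(meta, res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
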