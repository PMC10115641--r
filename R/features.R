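#' Assemble the landmark feature matrix
#'
#' One row per patient with a plasma-collection record at the landmark visit
#' (QC-failed samples still anchor a row; their ctDNA cells are missing and
#' later imputed). Columns are the catalog's level metrics for every visit up
#' to and including the landmark, qualified as `VISIT:metric`, plus the change
#' metrics for every on-treatment visit up to the landmark, qualified as
#' `VISIT_change:metric`, plus (optionally) baseline clinical covariates and,
#' for landmarks at or after C3D1, the week-6 radiographic measurements.
#' The column set depends only on the catalog and the landmark visit, never on
#' the data content.
#'
#' @param cohort A processed cohort (see [process_assay()]).
#' @param landmark_visit Visit label, e.g. `"C3D1"`.
#' @param catalog A [metric_catalog()].
#' @param include_clinical Add clinical covariate columns.
#' @return An object of class `ctdna_features`: list with the numeric matrix
#'   `x` (rownames = patient ids), the missingness `mask`, the landmark visit,
#'   and empty slots for imputation medians and IQR scalers.
#' @export
assemble_feature_matrix <- function(cohort, landmark_visit,
                                    catalog = metric_catalog(),
                                    include_clinical = FALSE) {
  if (!isTRUE(cohort$processed))
    stop("cohort must be processed with process_assay() first", call. = FALSE)
  vd <- visit_day_map(cohort)
  if (!landmark_visit %in% names(vd))
    stop(sprintf("unknown visit '%s'", landmark_visit), call. = FALSE)
  visits <- names(vd)[vd <= vd[landmark_visit]]
  on_tx <- setdiff(visits, "BL")

  s <- cohort$samples
  row_ids <- s$patient_id[s$visit == landmark_visit]
  row_ids <- cohort$patients$patient_id[cohort$patients$patient_id %in% row_ids]

  somatic <- cohort$variants[!cohort$variants$pbmc_positive, , drop = FALSE]
  get_sample <- function(pid, v) {
    r <- which(s$patient_id == pid & s$visit == v)
    if (!length(r)) return(NULL)
    list(visit = v, day = s$day[r], cfdna_ng_ml = s$cfdna_ng_ml[r],
         qc_pass = s$qc_pass[r], mtm = s$mtm[r],
         obs = somatic[somatic$patient_id == pid & somatic$visit == v, ,
                       drop = FALSE])
  }

  lev_names <- as.vector(outer(names(catalog$level), visits,
                               function(m, v) paste0(v, ":", m)))
  chg_names <- if (length(on_tx))
    as.vector(outer(names(catalog$change), on_tx,
                    function(m, v) paste0(v, "_change:", m)))
  else character(0)
  cols <- c(lev_names, chg_names)

  x <- matrix(NA_real_, length(row_ids), length(cols),
              dimnames = list(row_ids, cols))
  for (pid in row_ids) {
    levs <- list()
    hist_df <- data.frame(day = numeric(0), mtm = numeric(0))
    for (v in visits) {
      sm <- get_sample(pid, v)
      levs[[v]] <- derive_level_metrics(sm, catalog)
      x[pid, paste0(v, ":", names(catalog$level))] <- levs[[v]]
      if (!is.null(sm))
        hist_df <- rbind(hist_df, data.frame(day = sm$day, mtm = sm$mtm))
      if (v != "BL") {
        ch <- derive_change_metrics(levs[["BL"]], levs[[v]], hist_df, catalog)
        x[pid, paste0(v, "_change:", names(catalog$change))] <- ch
      }
    }
  }

  if (include_clinical) {
    p <- cohort$patients[match(row_ids, cohort$patients$patient_id), ]
    clin <- cbind(
      `clin:age` = p$age, `clin:sex_m` = as.numeric(p$sex == "M"),
      `clin:ecog` = p$ecog, `clin:smoker` = as.numeric(p$smoker == "y"),
      `clin:n_met_sites` = p$n_met_sites, `clin:sld_bl` = p$sld_bl
    )
    if (visit_day_map(cohort)[landmark_visit] >= visit_day_map(cohort)["C3D1"] &&
        nrow(cohort$recist)) {
      rc <- cohort$recist[match(row_ids, cohort$recist$patient_id), ]
      clin <- cbind(clin,
        `clin:week6_sld` = rc$sld,
        `clin:week6_sld_change` = rc$sld - p$sld_bl,
        `clin:week6_sld_pct_change` = rc$sld_pct_change)
    }
    rownames(clin) <- row_ids
    x <- cbind(x, clin)
  }

  structure(list(x = x, mask = is.na(x), landmark = landmark_visit,
                 medians = NULL, scalers = NULL, population = NULL),
            class = "ctdna_features")
}

visit_day_map <- function(cohort) {
  if (!is.null(cohort$config)) return(cohort$config$visit_days)
  v <- unique(cohort$samples[, c("visit", "day")])
  stats::setNames(v$day, v$visit)[order(stats::setNames(v$day, v$visit))]
}

#' @export
print.ctdna_features <- function(x, ...) {
  cat(sprintf("ctDNA feature matrix: %d patients x %d features (landmark %s)\n",
              nrow(x$x), ncol(x$x), x$landmark))
  cat(sprintf("  missing cells: %d (%.1f%%)  imputed: %s  scaled: %s\n",
              sum(x$mask), 100 * mean(x$mask),
              if (is.null(x$medians)) "no" else "yes",
              if (is.null(x$scalers)) "no" else "yes"))
  invisible(x)
}

#' Median-impute missing feature cells
#'
#' Missing cells are replaced by the per-feature median computed on the fit
#' population (by default all rows; pass the training rows to freeze medians
#' without leakage, or supply frozen `medians` directly for test/external
#' application). Observed cells are left bit-identical; the missingness mask
#' is retained.
#'
#' @param fm A `ctdna_features` object.
#' @param fit_rows Row names (or logical/integer index) of the fit population.
#' @param medians Optional frozen named median vector overriding `fit_rows`.
#' @return The imputed `ctdna_features` with `medians` recorded.
#' @export
impute_missing <- function(fm, fit_rows = NULL, medians = NULL) {
  x <- fm$x
  if (is.null(medians)) {
    xf <- if (is.null(fit_rows)) x else x[fit_rows, , drop = FALSE]
    if (!nrow(xf)) stop("empty fit population", call. = FALSE)
    all_miss <- colnames(x)[colSums(!is.na(xf)) == 0]
    if (length(all_miss))
      stop(sprintf("feature(s) missing for the entire fit population: %s",
                   paste(all_miss, collapse = ", ")), call. = FALSE)
    medians <- apply(xf, 2, stats::median, na.rm = TRUE)
  } else {
    if (!all(colnames(x) %in% names(medians)))
      stop("frozen medians do not cover all features", call. = FALSE)
    medians <- medians[colnames(x)]
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[[j]]
  }
  fm$x <- x
  fm$medians <- medians
  fm
}

#' Interquartile-range scalers
#'
#' `iqr_fit()` computes per-feature IQRs (linear-interpolation quartiles) on
#' the fit population — fit on training data only. `iqr_apply()` divides every
#' feature by its training IQR; constant features (IQR 0) pass through
#' unscaled and are flagged with a warning at fit time. After applying, the
#' non-constant training features have IQR exactly 1.
#'
#' @param fm A `ctdna_features` object (imputed).
#' @param fit_rows Fit-population rows (default: all).
#' @param scalers A scaler object from `iqr_fit()`.
#' @return `iqr_fit()`: a list of class `iqr_scalers` with `iqr` and
#'   `constant`; `iqr_apply()`: the scaled `ctdna_features`.
#' @export
iqr_fit <- function(fm, fit_rows = NULL) {
  x <- if (is.null(fit_rows)) fm$x else fm$x[fit_rows, , drop = FALSE]
  iqr <- apply(x, 2, function(col)
    diff(quantile7(col[!is.na(col)], c(0.25, 0.75))))
  constant <- iqr == 0 | is.na(iqr)
  if (any(constant))
    warning(sprintf("constant feature(s) left unscaled: %s",
                    paste(colnames(fm$x)[constant], collapse = ", ")),
            call. = FALSE)
  iqr[constant] <- 1
  structure(list(iqr = iqr, constant = constant), class = "iqr_scalers")
}

#' @rdname iqr_fit
#' @export
iqr_apply <- function(fm, scalers) {
  if (!inherits(scalers, "iqr_scalers")) stop("need iqr_fit() scalers", call. = FALSE)
  fm$x <- sweep(fm$x, 2, scalers$iqr[colnames(fm$x)], "/")
  fm$scalers <- scalers
  fm
}
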