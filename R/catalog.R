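#' Catalog of per-visit ctDNA level and change metrics
#'
#' The catalog is the configurable list of metric functions from which landmark
#' feature matrices are assembled. Level metrics are functions of one plasma
#' sample; change metrics are functions of the baseline sample, one
#' on-treatment sample, and the sample history up to that visit. The defaults
#' cover the metric families used in practice — allele-fraction summaries,
#' MTM burden, time-weighted MTM AUC, mutation counts, cfDNA concentration,
#' detection and clearance indicators — and can be extended or pruned to any
#' desired count.
#'
#' A plasma-sample object (as built by [assemble_feature_matrix()]) is a list
#' with `mtm`, `cfdna_ng_ml`, `qc_pass` and `obs`, the latter a data frame of
#' PBMC-corrected observations with `censored_af`, `classification` and
#' `pathogenic` columns.
#'
#' @param level Named list of functions of one sample.
#' @param change Named list of functions `(bl_levels, tx_levels, history)`
#'   where the first two are the level-metric vectors of the baseline and
#'   on-treatment sample and `history` is a data frame with `day` and `mtm`
#'   for all samples up to the visit.
#' @return A list of class `metric_catalog`.
#' @export
metric_catalog <- function(level = default_level_metrics(),
                           change = default_change_metrics()) {
  if (anyDuplicated(c(names(level), names(change))))
    stop_config("metric names", "must be unique across level and change metrics")
  structure(list(level = level, change = change), class = "metric_catalog")
}

pos_afs <- function(sample) {
  o <- sample$obs
  if (is.null(o) || !nrow(o)) return(numeric(0))
  o$censored_af[o$classification == "positive" & !is.na(o$censored_af)]
}

#' @rdname metric_catalog
#' @export
default_level_metrics <- function() {
  list(
    detected   = function(s) as.numeric(length(pos_afs(s)) > 0),
    n_mut      = function(s) length(pos_afs(s)),
    n_path_mut = function(s) {
      o <- s$obs
      if (is.null(o) || !nrow(o)) return(0)
      sum(o$classification == "positive" & o$pathogenic, na.rm = TRUE)
    },
    mean_af    = function(s) { a <- pos_afs(s); if (length(a)) mean(a) else 0 },
    median_af  = function(s) { a <- pos_afs(s); if (length(a)) stats::median(a) else 0 },
    max_af     = function(s) { a <- pos_afs(s); if (length(a)) max(a) else 0 },
    sum_af     = function(s) sum(pos_afs(s)),
    mtm        = function(s) s$mtm,
    log10_mtm  = function(s) log10(s$mtm + 1),
    cfdna_conc = function(s) s$cfdna_ng_ml
  )
}

#' @rdname metric_catalog
#' @export
default_change_metrics <- function() {
  base <- c("mean_af", "mtm", "n_mut", "cfdna_conc")
  out <- list()
  for (m in base) {
    local({
      mm <- m
      out[[paste0(mm, "_change")]] <<- function(bl, tx, h) tx[[mm]] - bl[[mm]]
      out[[paste0(mm, "_pct_change")]] <<- function(bl, tx, h) {
        if (is.na(bl[[mm]]) || is.na(tx[[mm]])) return(NA_real_)
        if (bl[[mm]] == 0) return(NA_real_)
        100 * (tx[[mm]] - bl[[mm]]) / bl[[mm]]
      }
      # shifted log fold change, defined for zero burden on either side
      out[[paste0(mm, "_logfc")]] <<- function(bl, tx, h)
        log10((tx[[mm]] + 1) / (bl[[mm]] + 1))
    })
  }
  out$clearance <- function(bl, tx, h) as.numeric(tx[["mtm"]] < 1)
  out$auc_mtm <- function(bl, tx, h) {
    h <- h[!is.na(h$mtm), , drop = FALSE]
    if (nrow(h) < 2) return(NA_real_)
    h <- h[order(h$day), , drop = FALSE]
    span <- diff(range(h$day))
    if (span == 0) return(NA_real_)
    # time-weighted average MTM to date (trapezoid AUC / elapsed days)
    sum(diff(h$day) * (utils::head(h$mtm, -1) + utils::tail(h$mtm, -1)) / 2) / span
  }
  out$max_mtm_on_tx <- function(bl, tx, h) {
    h <- h[h$day > 0 & !is.na(h$mtm), , drop = FALSE]
    if (!nrow(h)) return(NA_real_)
    max(h$mtm)
  }
  out
}

#' Derive level metrics for one plasma sample
#'
#' @param sample A plasma-sample object (see [metric_catalog()]).
#' @param catalog A [metric_catalog()].
#' @return Named numeric vector, one value per level metric; all `NA` for a
#'   QC-failed sample (the imputation path fills these later).
#' @export
derive_level_metrics <- function(sample, catalog = metric_catalog()) {
  nm <- names(catalog$level)
  if (is.null(sample) || !isTRUE(sample$qc_pass))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  vapply(catalog$level, function(f) as.numeric(f(sample)), numeric(1))
}

#' Derive on-treatment change metrics relative to baseline
#'
#' @param bl_levels,tx_levels Level-metric vectors of the baseline and
#'   on-treatment sample (from [derive_level_metrics()]).
#' @param history Data frame with `day` and `mtm` for all samples from
#'   baseline up to the on-treatment visit.
#' @param catalog A [metric_catalog()].
#' @return Named numeric vector of change metrics. Ratio-type metrics are
#'   `NA` when the baseline value is 0; absolute changes are still computed.
#' @export
derive_change_metrics <- function(bl_levels, tx_levels, history,
                                  catalog = metric_catalog()) {
  nm <- names(catalog$change)
  if (all(is.na(tx_levels)))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  vapply(catalog$change,
         function(f) as.numeric(f(bl_levels, tx_levels, history)), numeric(1))
}
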