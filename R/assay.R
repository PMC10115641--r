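#' Variant allele fraction from consensus read support
#'
#' VAF is the fraction of informative consensus reads supporting the variant:
#' `nrv / (nrv + nrr)`. Equivocal reads (`nre`) carry no discriminating value
#' and are excluded from both numerator and denominator. When no informative
#' reads exist the VAF is undefined and `NA` is returned (not zero).
#'
#' @param nrv,nrr,nre Counts of variant-supporting, reference-supporting and
#'   equivocal consensus reads (vectors recycle as usual).
#' @return Numeric vector of allele fractions, `NA` where `nrv + nrr == 0`.
#' @examples
#' estimate_vaf(5, 95, 12)   # 0.05
#' estimate_vaf(0, 0, 30)    # NA
#' @export
estimate_vaf <- function(nrv, nrr, nre = 0) {
  if (any(c(nrv, nrr, nre) < 0, na.rm = TRUE))
    stop("read counts must be non-negative", call. = FALSE)
  denom <- nrv + nrr
  ifelse(denom > 0, nrv / denom, NA_real_)
}

#' Assay detection limits
#'
#' @param lod Limit of detection (allele fraction, default 0.1%).
#' @param loq Lower limit of quantitation (allele fraction, default 0.5%).
#' @return A list of class `assay_limits`.
#' @export
assay_limits <- function(lod = 0.001, loq = 0.005) {
  if (!(0 < lod && lod < loq && loq < 1))
    stop_config("lod/loq", "need 0 < lod < loq < 1")
  structure(list(lod = lod, loq = loq), class = "assay_limits")
}

#' Censor sub-quantitation allele fractions
#'
#' Reported allele fractions below the limit of quantitation are censored to
#' `loq/2`; below the limit of detection, to `loq/4`. A zero AF denotes an
#' unreported/absent variant and passes through as 0. Values at or above the
#' LOQ are unchanged, so the map is idempotent and order-preserving on
#' `{0} U [lod, 1]`.
#'
#' @param af Allele fraction(s) in `[0, 1]`.
#' @param limits An [assay_limits()] object.
#' @return Censored allele fractions. `NA` input stays `NA`.
#' @examples
#' censor_af(c(0.003, 0.0005, 0.012))  # 0.0025 0.00125 0.012
#' @export
censor_af <- function(af, limits = assay_limits()) {
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele fraction outside [0, 1]", call. = FALSE)
  out <- af
  out[!is.na(af) & af > 0 & af < limits$lod] <- limits$loq / 4
  out[!is.na(af) & af >= limits$lod & af < limits$loq] <- limits$loq / 2
  out
}

#' Presumed-normal VAF panel
#'
#' Collection of allele fractions observed for a locus (or pooled across loci)
#' in presumed-normal samples, against which observed VAFs are classified.
#'
#' @param afs Numeric vector of presumed-normal allele fractions in `[0, 1]`.
#' @param min_supporting_reads Minimum variant-supporting reads for a positive
#'   call (default 2).
#' @return A list of class `normal_panel` carrying the panel values, their
#'   maximum and their 0.95 quantile (linear interpolation).
#' @export
normal_panel <- function(afs, min_supporting_reads = 2L) {
  if (!length(afs)) stop_config("afs", "presumed-normal panel must be non-empty")
  check_prob(afs, "afs")
  structure(list(afs = afs, max = max(afs), q95 = quantile7(afs, 0.95),
                 min_supporting_reads = as.integer(min_supporting_reads)),
            class = "normal_panel")
}

#' Classify an observed VAF against the presumed-normal panel
#'
#' Positive: at least `min_supporting_reads` variant-supporting reads and VAF
#' greater than the panel maximum. Negative: VAF below the panel 0.95
#' quantile. Equivocal: neither. When a degenerate panel makes both rules
#' fire, positive takes precedence (it is the stricter, read-count-backed
#' condition).
#'
#' @param vaf Observed allele fraction(s); `NA` classifies as equivocal.
#' @param nrv Variant-supporting read count(s).
#' @param panel A [normal_panel()].
#' @return Character vector in `{"positive", "negative", "equivocal"}`.
#' @export
classify_variant <- function(vaf, nrv, panel) {
  if (!inherits(panel, "normal_panel"))
    stop_config("panel", "must be a normal_panel object")
  pos <- !is.na(vaf) & nrv >= panel$min_supporting_reads & vaf > panel$max
  neg <- !is.na(vaf) & vaf < panel$q95
  ifelse(pos, "positive", ifelse(neg, "negative", "equivocal"))
}

#' Remove PBMC-positive (germline/CHIP) variants from plasma observations
#'
#' Variants classified positive in matched PBMCs are presumed germline or
#' CHIP-derived and are excluded from tumor-burden analyses. Removed rows are
#' retained in an audit attribute with `pbmc_positive = TRUE`. The operation
#' is idempotent and never increases the observation count.
#'
#' @param plasma_obs Data frame of variant observations with a `variant_id`
#'   column.
#' @param pbmc_positive_ids Character vector of PBMC-positive variant ids.
#' @return The somatic subset of `plasma_obs` (with `pbmc_positive = FALSE`),
#'   carrying the removed observations in `attr(, "removed")`.
#' @export
subtract_pbmc <- function(plasma_obs, pbmc_positive_ids) {
  hit <- plasma_obs$variant_id %in% pbmc_positive_ids
  removed <- plasma_obs[hit, , drop = FALSE]
  if (nrow(removed)) removed$pbmc_positive <- TRUE
  kept <- plasma_obs[!hit, , drop = FALSE]
  if (nrow(kept)) kept$pbmc_positive <- FALSE
  rownames(kept) <- NULL
  attr(kept, "removed") <- removed
  kept
}

#' Mean tumor molecules per mL plasma
#'
#' Tumor burden summary combining the mean censored somatic allele fraction
#' with the plasma cfDNA concentration converted to haploid genome
#' equivalents: `MTM = mean(censored AF over positive somatic observations) *
#' cfdna_ng_ml / (mass_per_genome / 1000)`, with 3.3 pg per haploid genome by
#' default. With no positive somatic observations the burden is 0.
#'
#' @param censored_afs Censored allele fractions of the positive somatic
#'   observations for the sample (may be empty).
#' @param cfdna_ng_ml Plasma cfDNA concentration in ng/mL.
#' @param mass_per_genome Mass of one haploid genome in picograms.
#' @return MTM per mL plasma (scalar).
#' @examples
#' compute_mtm(0.01, 10)  # 30.30303
#' @export
compute_mtm <- function(censored_afs, cfdna_ng_ml, mass_per_genome = 3.3) {
  if (is.na(cfdna_ng_ml) || cfdna_ng_ml < 0)
    stop("cfDNA concentration must be non-negative", call. = FALSE)
  if (!length(censored_afs) || all(is.na(censored_afs))) return(0)
  mean_af <- mean(censored_afs, na.rm = TRUE)
  genomes_per_ml <- cfdna_ng_ml / (mass_per_genome / 1000)
  mean_af * genomes_per_ml
}

#' Run the full assay post-processing over a cohort
#'
#' For every QC-passing plasma sample: estimate VAFs from read support,
#' classify against the presumed-normal panel, censor sub-LOQ fractions,
#' subtract PBMC-positive variants, and compute the per-sample MTM burden
#' over positive somatic observations.
#'
#' @param cohort A `ctdna_cohort`.
#' @param limits An [assay_limits()].
#' @param panel A [normal_panel()] used as a pooled (variant-agnostic) panel,
#'   or a named list of per-variant panels keyed by `variant_id` with an
#'   optional `pooled` element as fallback for variants without their own
#'   panel. The default pools a weak background distribution appropriate for
#'   the synthetic assay (max 0.08% AF).
#' @param gene_blocklist Optional character vector of genes to drop before
#'   analysis (e.g. known CHIP genes when no matched PBMC data exist).
#' @param mass_per_genome Picograms per haploid genome for MTM.
#' @return The cohort with `variants` replaced by a processed table (columns
#'   `vaf`, `censored_af`, `classification`, `pbmc_positive` added) and
#'   `samples` gaining an `mtm` column (`NA` for QC-failed samples).
#' @export
process_assay <- function(cohort, limits = assay_limits(),
                          panel = normal_panel(c(0, 2e-4, 5e-4, 8e-4)),
                          gene_blocklist = NULL,
                          mass_per_genome = 3.3) {
  v <- cohort$variants
  if (!is.null(gene_blocklist) && nrow(v))
    v <- v[!v$gene %in% gene_blocklist, , drop = FALSE]
  if (nrow(v)) {
    v$vaf <- estimate_vaf(v$nrv, v$nrr, v$nre)
    if (inherits(panel, "normal_panel")) {
      v$classification <- classify_variant(v$vaf, v$nrv, panel)
    } else {
      v$classification <- vapply(seq_len(nrow(v)), function(r) {
        pan <- panel[[v$variant_id[r]]] %||% panel$pooled
        if (is.null(pan))
          stop(sprintf("no panel for variant '%s' and no pooled fallback",
                       v$variant_id[r]), call. = FALSE)
        classify_variant(v$vaf[r], v$nrv[r], pan)
      }, character(1))
    }
    v$censored_af <- censor_af(ifelse(is.na(v$vaf), NA, v$vaf), limits)
    v$pbmc_positive <- v$variant_id %in% cohort$pbmc$variant_id
  } else {
    v$vaf <- numeric(0); v$classification <- character(0)
    v$censored_af <- numeric(0); v$pbmc_positive <- logical(0)
  }
  somatic <- v[!v$pbmc_positive, , drop = FALSE]

  s <- cohort$samples
  if (any(!is.na(s$cfdna_ng_ml) & s$cfdna_ng_ml < 0))
    stop("cfDNA concentration must be non-negative", call. = FALSE)
  pos <- somatic$classification == "positive" & !is.na(somatic$censored_af)
  mean_af <- if (any(pos))
    tapply(somatic$censored_af[pos],
           paste(somatic$patient_id, somatic$visit, sep = "\r")[pos], mean)
  else numeric(0)
  m <- unname(mean_af[paste(s$patient_id, s$visit, sep = "\r")])
  m[is.na(m)] <- 0
  s$mtm <- ifelse(s$qc_pass, m * s$cfdna_ng_ml / (mass_per_genome / 1000),
                  NA_real_)
  out <- cohort
  out$variants <- v
  out$samples <- s
  out$processed <- TRUE
  out
}

#' Write the processed assay tables
#'
#' Emits `processed_variants.tsv` (read counts plus `vaf`, `censored_af`,
#' `classification`, `pbmc_positive`) and `samples_mtm.tsv` (collection
#' records plus `mtm`) to `path`.
#'
#' @param cohort A cohort processed with [process_assay()].
#' @param path Output directory (created if absent).
#' @export
write_processed_assay <- function(cohort, path) {
  if (!isTRUE(cohort$processed))
    stop("cohort must be processed with process_assay() first", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$variants,
                     file.path(path, "processed_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$samples, file.path(path, "samples_mtm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
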