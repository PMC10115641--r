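#' Write / read a cohort as tab-delimited tables
#'
#' On-disk layout: `patients.tsv`, `samples.tsv`, `variants.tsv`, `pbmc.tsv`,
#' `recist.tsv` in `path` (one row per record, header row, UTF-8, missing
#' values as empty fields). `read_cohort()` validates visit labels against the
#' configured visit map and reports the offending line on failure.
#'
#' @param cohort A `ctdna_cohort` (or a compatible list of the five tables).
#' @param path Directory to write to / read from (created if absent).
#' @param visit_labels Valid visit labels for validation on read.
#' @return `read_cohort()` returns a `ctdna_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("patients", "samples", "variants", "pbmc", "recist")) {
    df <- cohort[[tab]]
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(z) ifelse(is.na(z), NA, format(z, digits = 15)))
    utils::write.table(df, file.path(path, paste0(tab, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, visit_labels = c("BL", "C2D1", "C3D1", "C4D1", "C8D1")) {
  read_tab <- function(name) {
    f <- file.path(path, paste0(name, ".tsv"))
    if (!file.exists(f)) stop(sprintf("missing cohort table: %s", f), call. = FALSE)
    utils::read.delim(f, stringsAsFactors = FALSE, na.strings = "")
  }
  patients <- read_tab("patients")
  samples <- read_tab("samples")
  variants <- read_tab("variants")
  pbmc <- read_tab("pbmc")
  recist <- read_tab("recist")

  check_visits <- function(df, name) {
    if (!nrow(df)) return(invisible())
    bad <- which(!df$visit %in% visit_labels)
    if (length(bad))
      stop(sprintf("parse error in %s.tsv line %d: unknown visit label '%s'",
                   name, bad[1] + 1L, df$visit[bad[1]]), call. = FALSE)
  }
  check_visits(samples, "samples")
  check_visits(variants, "variants")

  for (col in c("os_event", "pfs_event"))
    if (col %in% names(patients)) patients[[col]] <- as.logical(patients[[col]])
  if ("qc_pass" %in% names(samples)) samples$qc_pass <- as.logical(samples$qc_pass)
  if ("pathogenic" %in% names(variants))
    variants$pathogenic <- as.logical(variants$pathogenic)

  structure(list(patients = patients, samples = samples, variants = variants,
                 pbmc = pbmc, recist = recist, config = NULL),
            class = "ctdna_cohort")
}
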