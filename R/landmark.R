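#' Landmark-rebaseline survival records
#'
#' To remove immortal-time bias, patients whose event or censoring occurred at
#' or before the landmark (sample-collection) day are excluded, and the
#' remaining times are re-measured from the landmark day. The boundary rule is
#' strict: a rebaselined time must be positive, so an event exactly on the
#' landmark day is excluded. Patients without a known landmark day are
#' excluded with reason `"no collection"`.
#'
#' @param records Data frame with `patient_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event` (times in days from randomization).
#' @param landmark_days Named numeric vector (names = patient ids) of landmark
#'   days; patients absent from it are excluded.
#' @param endpoint `"os"` or `"pfs"`.
#' @return A list of class `landmark_data`: `data` (included patients with
#'   rebaselined `time` and `event`), and `excluded` (patient ids with
#'   reasons).
#' @examples
#' rec <- data.frame(patient_id = c("a", "b"), os_time = c(30, 400),
#'                   os_event = c(TRUE, FALSE), pfs_time = c(30, 200),
#'                   pfs_event = c(TRUE, TRUE))
#' landmark_rebaseline(rec, c(a = 42, b = 42), "os")  # a excluded
#' @export
landmark_rebaseline <- function(records, landmark_days, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  ld <- unname(landmark_days[records$patient_id])
  no_lm <- is.na(ld)
  early <- !no_lm & records[[tcol]] <= ld
  keep <- !no_lm & !early

  excluded <- data.frame(
    patient_id = records$patient_id[!keep],
    reason = ifelse(no_lm[!keep], "no collection",
                    "event or censoring at/before landmark"),
    stringsAsFactors = FALSE
  )
  data <- data.frame(
    patient_id = records$patient_id[keep],
    landmark_day = unname(ld[keep]),
    time = records[[tcol]][keep] - unname(ld[keep]),
    event = records[[ecol]][keep],
    stringsAsFactors = FALSE
  )
  stopifnot(all(data$time > 0))
  structure(list(data = data, excluded = excluded, endpoint = endpoint),
            class = "landmark_data")
}

#' @export
print.landmark_data <- function(x, ...) {
  cat(sprintf("Landmark %s dataset: %d at risk (%d events), %d excluded\n",
              toupper(x$endpoint), nrow(x$data), sum(x$data$event),
              nrow(x$excluded)))
  invisible(x)
}
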