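#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, header row, one patient per row, columns named
#' as in [validate_patient_records()]; booleans may be `{0,1}`, `{no,yes}`
#' or `{false,true}` (case-insensitive).
#'
#' @param path file path.
#' @return Validated patient data.frame.
#' @export
read_cohort_csv <- function(path) {
  validate_patient_records(read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Read an intraoperative-findings CSV
#'
#' Same dialect as [read_cohort_csv()], columns as in
#' [validate_intraop_records()].
#'
#' @param path file path.
#' @return Validated intraoperative data.frame.
#' @export
read_intraop_csv <- function(path) {
  validate_intraop_records(read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent); writes `cohort.csv`
#'   and `intraop.csv`.
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop("'cohort' must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             intraop = file.path(dir, "intraop.csv"))
  write.csv(cohort$patients, paths["cohort"], row.names = FALSE)
  write.csv(cohort$intraop, paths["intraop"], row.names = FALSE)
  invisible(paths)
}
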