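#' @name intraop_grading
#' @title Grading operative difficulty from intraoperative findings
#'
#' @description
#' Operative difficulty is graded from four objective criteria:
#'
#' | criterion   | easy    | difficult      | very difficult |
#' |-------------|---------|----------------|----------------|
#' | time (min)  | <60     | 60-120         | >120           |
#' | spillage    | no      | bile or stone  | bile or stone  |
#' | injury      | none    | duct or artery | both           |
#' | conversion  | no      | no             | yes            |
#'
#' The overall grade is the maximum severity attained by any criterion: a
#' single very-difficult marker (e.g. conversion to open surgery) makes
#' the whole case very difficult regardless of the others.  Boundary
#' minutes fall in the middle band: exactly 60 and exactly 120 minutes both
#' grade difficult, making the bands `[0,60)`, `[60,120]`, `(120,Inf)`
#' exhaustive.  An isolated artery injury grades difficult (same severity
#' as an isolated duct injury); simultaneous duct and artery injury grades
#' very difficult.
NULL

#' Validate a table of intraoperative records
#'
#' @param records data.frame with columns `patient_id`, `duration_min`
#'   (non-negative minutes), `bile_spillage`, `stone_spillage` (booleans),
#'   `injury` (one of none/duct_only/artery_only/both), and
#'   `conversion_to_open` (boolean).
#' @return The normalized data.frame.
#' @export
validate_intraop_records <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$patient_id))
    records$patient_id <- seq_len(nrow(records))
  required <- c("duration_min", "bile_spillage", "stone_spillage",
                "injury", "conversion_to_open")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("intraop records are missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (f in c("bile_spillage", "stone_spillage", "conversion_to_open"))
    records[[f]] <- as_flag(records[[f]], f)
  records$injury <- tolower(trimws(as.character(records$injury)))
  if (!all(records$injury %in% injury_levels))
    stop("'injury' must be one of: ", paste(injury_levels, collapse = ", "),
         call. = FALSE)
  if (any(is.na(records$duration_min)) || any(records$duration_min < 0))
    stop("'duration_min' must be non-negative minutes", call. = FALSE)
  records
}

#' Grade operative difficulty
#'
#' @param records data.frame of intraoperative records (see
#'   [validate_intraop_records()]).
#' @return A data.frame of class `difficulty_grade` with `patient_id`,
#'   `grade` (ordered factor easy < difficult < very_difficult) and
#'   `triggered` (comma-separated names of the criteria attaining the
#'   overall grade).
#' @examples
#' grade_operation(data.frame(duration_min = 70, bile_spillage = TRUE,
#'                            stone_spillage = FALSE, injury = "none",
#'                            conversion_to_open = FALSE))
#' @export
grade_operation <- function(records) {
  records <- validate_intraop_records(records)
  sev_time <- ifelse(records$duration_min < 60, 0L,
                     ifelse(records$duration_min <= 120, 1L, 2L))
  sev_spill <- ifelse(records$bile_spillage | records$stone_spillage, 1L, 0L)
  sev_injury <- c(none = 0L, duct_only = 1L, artery_only = 1L, both = 2L)[records$injury]
  sev_conv <- ifelse(records$conversion_to_open, 2L, 0L)
  sev <- cbind(operative_time = sev_time, spillage = sev_spill,
               injury = sev_injury, conversion = sev_conv)
  overall <- apply(sev, 1L, max)
  triggered <- vapply(seq_len(nrow(sev)), function(i) {
    paste(colnames(sev)[sev[i, ] == overall[i]], collapse = ",")
  }, character(1))
  out <- data.frame(patient_id = records$patient_id,
                    grade = factor(grade_levels[overall + 1L],
                                   levels = grade_levels, ordered = TRUE),
                    triggered = triggered, stringsAsFactors = FALSE)
  class(out) <- c("difficulty_grade", "data.frame")
  out
}

#' Collapse the difficulty grade to the binary outcome
#'
#' Difficult and very difficult cases form a single "difficult" group for
#' the validation analyses (a binary outcome is required for ROC analysis,
#' and very difficult cases are too few for separate treatment).
#'
#' @param grade a `difficulty_grade` table or (ordered) factor of grades.
#' @return Logical vector, `TRUE` = observed difficult.
#' @export
dichotomize_grade <- function(grade) {
  g <- if (is.data.frame(grade)) grade$grade else grade
  if (is.null(g)) stop("'grade' must be a difficulty_grade table or factor")
  if (!is.factor(g)) g <- factor(g, levels = grade_levels, ordered = TRUE)
  if (any(is.na(g))) stop("invalid grade value")
  g >= "difficult"
}
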