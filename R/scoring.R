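#' @name scoring
#' @title The nine-parameter preoperative difficulty score
#'
#' @description
#' The score aggregates nine preoperative findings into an integer total
#' between 0 and 12: three historical parameters (age, sex, prior
#' hospitalization for cholecystitis), three clinical parameters (BMI,
#' palpable gallbladder, abdominal scar) and three ultrasonographic
#' parameters (gallbladder wall thickness > 4 mm, impacted stone,
#' pericholecystic collection).  Point values per parameter:
#'
#' | parameter                   | levels and points                          | max |
#' |-----------------------------|--------------------------------------------|-----|
#' | age                         | <=50 years: 0; >50 years: 1                | 1   |
#' | sex                         | female: 0; male: 1                         | 1   |
#' | hospitalization             | no: 0; yes: 1                              | 1   |
#' | bmi                         | <25: 0; 25-27.5: 1; >27.5: 2 (kg/m^2)      | 2   |
#' | palpable_gallbladder        | no: 0; yes: 1                              | 1   |
#' | abdominal_scar              | none: 0; infraumbilical: 1; supraumbilical: 2 | 2 |
#' | gb_wall                     | thin: 0; >4 mm: 2                          | 2   |
#' | impacted_stone              | no: 0; yes: 1                              | 1   |
#' | pericholecystic_collection  | no: 0; yes: 1                              | 1   |
#'
#' Boundary conventions (configurable where noted): BMI exactly 25 scores 1
#' (closed lower bound of the middle band) and exactly 27.5 scores 1 (the
#' top band is strictly ">27.5"); age exactly 50 scores 0 (the high band is
#' strictly ">50"), flip with `age_inclusive = TRUE`.
NULL

#' Names of the nine score parameters
#'
#' @return Character vector of the parameter names accepted by
#'   [score_component()], in table order.
#' @export
score_parameters <- function() {
  c("age", "sex", "hospitalization", "bmi", "palpable_gallbladder",
    "abdominal_scar", "gb_wall", "impacted_stone",
    "pericholecystic_collection")
}

scar_levels <- c("none", "infraumbilical", "supraumbilical")
injury_levels <- c("none", "duct_only", "artery_only", "both")
grade_levels <- c("easy", "difficult", "very_difficult")

#' Validate and normalize a table of patient records
#'
#' Checks the cohort schema (one row per patient), coerces boolean columns
#' from `{0,1}`, `{no,yes}`, `{false,true}` (case-insensitive), lowercases
#' enums, and enforces the study's domain invariants: `age_years >= 18`,
#' `10 < bmi < 80`, `sex` in `{female, male}`, `abdominal_scar` in
#' `{none, infraumbilical, supraumbilical}`.  If a `gb_wall_mm` column is
#' present and `gb_wall_thickened` is absent, the flag is derived as
#' strictly `> 4` mm.
#'
#' @param records data.frame with columns `patient_id`, `age_years`, `sex`,
#'   `prior_hospitalization`, `bmi`, `palpable_gallbladder`,
#'   `abdominal_scar`, `gb_wall_thickened`, `impacted_stone`,
#'   `pericholecystic_collection`, and optionally `hypertension`,
#'   `diabetes`, `gb_wall_mm`.
#' @return The normalized data.frame.
#' @export
validate_patient_records <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$patient_id))
    records$patient_id <- seq_len(nrow(records))
  if ("gb_wall_mm" %in% names(records) &&
      !("gb_wall_thickened" %in% names(records))) {
    records$gb_wall_thickened <- records$gb_wall_mm > 4.0
  }
  required <- c("age_years", "sex", "prior_hospitalization", "bmi",
                "palpable_gallbladder", "abdominal_scar",
                "gb_wall_thickened", "impacted_stone",
                "pericholecystic_collection")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("patient records are missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  flags <- c("prior_hospitalization", "palpable_gallbladder",
             "gb_wall_thickened", "impacted_stone",
             "pericholecystic_collection",
             intersect(c("hypertension", "diabetes"), names(records)))
  for (f in flags) records[[f]] <- as_flag(records[[f]], f)

  records$sex <- tolower(trimws(as.character(records$sex)))
  records$abdominal_scar <- tolower(trimws(as.character(records$abdominal_scar)))

  check_row <- function(ok, what) {
    if (any(!ok)) {
      bad <- records$patient_id[!ok]
      stop("invalid ", what, " for patient_id: ",
           paste(head(bad, 5), collapse = ", "),
           if (sum(!ok) > 5) " ..." else "", call. = FALSE)
    }
  }
  for (f in c(required, "patient_id")) {
    check_row(!is.na(records[[f]]), paste0("(missing) '", f, "'"))
  }
  check_row(records$sex %in% c("female", "male"), "'sex'")
  check_row(records$abdominal_scar %in% scar_levels, "'abdominal_scar'")
  check_row(records$age_years >= 18, "'age_years' (adults >= 18 only)")
  check_row(records$bmi > 10 & records$bmi < 80, "'bmi' (must be in (10, 80))")
  if (anyDuplicated(records$patient_id))
    stop("duplicated patient_id values", call. = FALSE)
  records
}

#' Point contribution of a single score parameter
#'
#' @param parameter one of [score_parameters()].
#' @param record data.frame of validated patient records (one or more rows).
#' @param age_inclusive if `TRUE`, age exactly 50 scores 1; default `FALSE`
#'   (the high-age band is strictly "> 50 years").
#' @return Integer vector of per-patient point values for that parameter.
#' @examples
#' rec <- data.frame(age_years = 55, sex = "female",
#'                   prior_hospitalization = TRUE, bmi = 26,
#'                   palpable_gallbladder = FALSE,
#'                   abdominal_scar = "infraumbilical",
#'                   gb_wall_thickened = TRUE, impacted_stone = FALSE,
#'                   pericholecystic_collection = FALSE)
#' score_component("bmi", rec)   # 1
#' @export
score_component <- function(parameter, record, age_inclusive = FALSE) {
  if (length(parameter) != 1L || !parameter %in% score_parameters())
    stop("unknown parameter '", paste(parameter, collapse = ","),
         "'; valid parameters: ", paste(score_parameters(), collapse = ", "),
         call. = FALSE)
  record <- validate_patient_records(record)
  out <- switch(parameter,
    age = if (age_inclusive) record$age_years >= 50 else record$age_years > 50,
    sex = record$sex == "male",
    hospitalization = record$prior_hospitalization,
    bmi = ifelse(record$bmi < 25, 0L, ifelse(record$bmi <= 27.5, 1L, 2L)),
    palpable_gallbladder = record$palpable_gallbladder,
    abdominal_scar = match(record$abdominal_scar, scar_levels) - 1L,
    gb_wall = 2L * record$gb_wall_thickened,
    impacted_stone = record$impacted_stone,
    pericholecystic_collection = record$pericholecystic_collection)
  as.integer(out)
}

#' Compute the preoperative difficulty score
#'
#' @inheritParams score_component
#' @param records data.frame of patient records (see
#'   [validate_patient_records()] for the schema).
#' @return A data.frame of class `preop_score` with `patient_id`, one
#'   integer column per parameter, and `total` (0-12).
#' @examples
#' coh <- fixture_150()
#' sc <- compute_preop_score(coh$patients)
#' table(sc$total)
#' @export
compute_preop_score <- function(records, age_inclusive = FALSE) {
  records <- validate_patient_records(records)
  comps <- vapply(score_parameters(), score_component, integer(nrow(records)),
                  record = records, age_inclusive = age_inclusive)
  if (nrow(records) == 1L) comps <- matrix(comps, nrow = 1,
                                           dimnames = list(NULL, score_parameters()))
  out <- data.frame(patient_id = records$patient_id, comps,
                    total = as.integer(rowSums(comps)),
                    stringsAsFactors = FALSE)
  class(out) <- c("preop_score", "data.frame")
  out
}

score_totals <- function(score) {
  if (inherits(score, "preop_score") || is.data.frame(score)) {
    if (is.null(score$total)) stop("score table lacks a 'total' column")
    return(score$total)
  }
  if (!is.numeric(score)) stop("'score' must be a preop_score or numeric totals")
  score
}

#' Dichotomous prediction of a difficult cholecystectomy
#'
#' A case is predicted difficult when the total score strictly exceeds the
#' cutoff: at the default cutoff 3, a score of 3 is predicted easy and a
#' score of 4 difficult.
#'
#' @param score a `preop_score` table or numeric vector of totals.
#' @param cutoff non-negative integer threshold (default 3).
#' @return Logical vector, `TRUE` = predicted difficult.
#' @export
predict_difficult <- function(score, cutoff = 3) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("'cutoff' must be a single non-negative number")
  score_totals(score) > cutoff
}

#' Three-way preoperative category
#'
#' Maps the total score into ordered categories easy / difficult /
#' very_difficult via two band boundaries: totals `<= bands[1]` are easy,
#' totals in `(bands[1], bands[2]]` difficult, larger totals
#' very_difficult.  The default bands (5, 9) are a documented convention
#' (all validation analyses use the binary `> 3` rule, so the three-way
#' split is descriptive only).
#'
#' @inheritParams predict_difficult
#' @param bands strictly increasing numeric vector of two band boundaries.
#' @return Ordered factor with levels easy < difficult < very_difficult.
#' @export
categorize_preop <- function(score, bands = c(5, 9)) {
  if (!is.numeric(bands) || length(bands) != 2L || any(is.na(bands)) ||
      diff(bands) <= 0)
    stop("'bands' must be two strictly increasing boundaries")
  tot <- score_totals(score)
  idx <- 1L + (tot > bands[1]) + (tot > bands[2])
  factor(grade_levels[idx], levels = grade_levels, ordered = TRUE)
}
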