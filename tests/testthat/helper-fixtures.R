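# shared fixtures: printed contingency tables of the validation study and
# small record constructors used across tests

# easy / difficult counts per variable level (rows = levels)
printed_tables <- list(
  hypertension     = matrix(c(107, 1, 36, 6), nrow = 2,
                            dimnames = list(c("no", "yes"), c("easy", "difficult"))),
  pericholecystic  = matrix(c(108, 0, 37, 5), nrow = 2),
  impacted_stone   = matrix(c(108, 0, 41, 1), nrow = 2),
  palpable_gb      = matrix(c(108, 0, 41, 1), nrow = 2),
  hospitalization  = matrix(c(86, 22, 26, 16), nrow = 2),
  gender           = matrix(c(89, 19, 33, 9), nrow = 2),
  diabetes         = matrix(c(101, 7, 36, 6), nrow = 2),
  gb_wall          = matrix(c(103, 5, 28, 14), nrow = 2),
  bmi_3level       = matrix(c(45, 61, 2, 12, 30, 0), nrow = 3),
  scar_3level      = matrix(c(83, 25, 0, 30, 10, 2), nrow = 3)
)

# one fully specified patient record, overridable field by field
make_record <- function(...) {
  rec <- data.frame(
    patient_id = "P1", age_years = 30, sex = "female",
    prior_hospitalization = FALSE, bmi = 22,
    palpable_gallbladder = FALSE, abdominal_scar = "none",
    gb_wall_thickened = FALSE, impacted_stone = FALSE,
    pericholecystic_collection = FALSE, hypertension = FALSE,
    diabetes = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

make_intraop <- function(...) {
  rec <- data.frame(
    patient_id = "P1", duration_min = 45, bile_spillage = FALSE,
    stone_spillage = FALSE, injury = "none", conversion_to_open = FALSE,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# random valid patient records for property-style tests
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age_years = sample(18:85, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    prior_hospitalization = sample(c(TRUE, FALSE), n, replace = TRUE),
    bmi = runif(n, 16, 40),
    palpable_gallbladder = sample(c(TRUE, FALSE), n, replace = TRUE),
    abdominal_scar = sample(c("none", "infraumbilical", "supraumbilical"),
                            n, replace = TRUE),
    gb_wall_thickened = sample(c(TRUE, FALSE), n, replace = TRUE),
    impacted_stone = sample(c(TRUE, FALSE), n, replace = TRUE),
    pericholecystic_collection = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# random small contingency tables (at least 2x2, modest totals)
random_table <- function(r, c, max_cell = 8) {
  matrix(sample(0:max_cell, r * c, replace = TRUE), nrow = r)
}

# brute-force two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins, probabilities from binomial coefficients
fisher_bruteforce_p <- function(x) {
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ]); c1 <- sum(x[, 1]); n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  obs <- lchoose(r1, x[1, 1]) + lchoose(r2, c1 - x[1, 1]) - lchoose(n, c1)
  min(1, sum(exp(logp[logp <= obs + log1p(1e-7)])))
}
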