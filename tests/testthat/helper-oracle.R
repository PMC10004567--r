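# Independent brute-force oracle for case identification, written as a plain
# per-person month-by-month scan with base R only. It deliberately shares no
# code with identify_cases().

oracle_identify <- function(claims, enrollment, spec, index_year) {
  affil_col <- sprintf("affiliated_%d", index_year)
  rows_by_person <- split(seq_len(nrow(claims)), claims$person_id)
  members <- character(0)
  for (i in seq_len(nrow(enrollment))) {
    pid <- enrollment$person_id[i]
    if (!isTRUE(enrollment[[affil_col]][i])) next
    if ((index_year - enrollment$birth_year[i]) < 20) next
    months_seen <- logical(12)
    has_proc <- FALSE
    for (j in rows_by_person[[pid]]) {
      code_match <- FALSE
      for (root in spec$code_roots) {
        if (substr(claims$icd10_code[j], 1, nchar(root)) == root) {
          code_match <- TRUE
          break
        }
      }
      if (code_match && claims$year[j] == index_year) {
        months_seen[claims$month[j]] <- TRUE
      }
      if (claims$procedure_category[j] %in%
            c("chemotherapy", "radiotherapy", "surgery") &&
          claims$year[j] >= index_year - spec$lookback_years &&
          claims$year[j] <= index_year - 1) {
        has_proc <- TRUE
      }
    }
    if (sum(months_seen) >= spec$min_months &&
        (!spec$require_procedure || has_proc)) {
      members <- c(members, pid)
    }
  }
  sort(members)
}

# Random small claims world, built directly (not via the simulator) so the
# oracle tests exercise identify_cases on inputs it did not help create.
random_instance <- function(seed, n_persons = NULL, index_year = 2018) {
  set.seed(seed)
  n <- if (is.null(n_persons)) sample(20:200, 1) else n_persons
  regime <- sample(c("contributory", "subsidized"), n, replace = TRUE)
  region <- ifelse(
    regime == "contributory",
    sample(c("Atlantic", "Bogota", "Central", "Oriental",
             "Orinoquia/Amazonia", "Pacific"), n, replace = TRUE),
    NA_character_)
  enrollment <- data.table::data.table(
    person_id = sprintf("X%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_year = index_year - sample(15:90, n, replace = TRUE),
    region = region,
    regime = regime)
  enrollment[[sprintf("affiliated_%d", index_year)]] <-
    stats::runif(n) < 0.9
  n_claims <- sample(0:(6 * n), 1)
  claims <- data.table::data.table(
    person_id = sample(enrollment$person_id, n_claims, replace = TRUE),
    year = sample((index_year - 4):index_year, n_claims, replace = TRUE),
    month = sample(1:12, n_claims, replace = TRUE),
    icd10_code = sample(c("C33", "C340", "C341", "C349", "C509", "C780",
                          "J449", "I10X"), n_claims, replace = TRUE),
    procedure_category = sample(
      c("none", "none", "none", "none", "chemotherapy", "radiotherapy",
        "surgery"), n_claims, replace = TRUE))
  list(enrollment = enrollment, claims = claims, index_year = index_year)
}

# One-stratum simulation parameters used across recovery/coverage tests.
single_stratum_params <- function(n_persons, prevalence_per_100k, seed, ...) {
  strata <- data.table::data.table(
    regime = "contributory", sex = "male", region = "Central",
    age_group = "45-64", weight = 1,
    prevalence_per_100k = prevalence_per_100k)
  simulation_params(n_persons = n_persons, strata = strata, seed = seed, ...)
}

point_mass <- function(k) {
  p <- rep(0, 12)
  p[k] <- 1
  p
}
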