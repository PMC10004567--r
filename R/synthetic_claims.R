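# Synthetic enrollment + claims generator with known ground truth.
# Stands in for the restricted national databases (enrollee registry and
# premium-sufficiency service records) so every downstream stage is testable.

DEFAULT_LEAF_CODES <- c("C33", "C340", "C341", "C342", "C343", "C348", "C349")

default_strata <- function() {
  # Population composition loosely shaped like the insured adult population:
  # a large contributory regime spread over six regions and a single-city
  # subsidized regime (no region recorded). Weights are generator defaults,
  # not estimates of anything.
  contrib <- data.table::CJ(
    regime = "contributory",
    sex = SEXES,
    region = REGIONS,
    age_group = c("20-44", "45-64", "65+"))
  subs <- data.table::CJ(
    regime = "subsidized",
    sex = SEXES,
    region = NA_character_,
    age_group = c("20-44", "45-64", "65+"))
  strata <- rbind(contrib, subs)
  age_w <- c("20-44" = 0.55, "45-64" = 0.30, "65+" = 0.15)
  regime_w <- c(contributory = 0.8, subsidized = 0.2)
  strata[, weight := regime_w[regime] * age_w[age_group] * 0.5 /
           data.table::fifelse(regime == "contributory", length(REGIONS), 1)]
  strata[, weight := weight / sum(weight)]
  # crude prevalence rising steeply with age, as lung cancer does
  prev <- c("20-44" = 1.2, "45-64" = 14, "65+" = 60)
  strata[, prevalence_per_100k := prev[age_group]]
  strata[]
}

#' Construct and validate synthetic-simulation parameters
#'
#' The defaults describe a plausible claims world: most true prevalent cases
#' accumulate lung-cancer-coded services in four or more distinct months of
#' an index year, a small fraction of non-cases receive transient rule-out
#' coding concentrated in one or two months, and a majority of cases carry at
#' least one oncological procedure in the preceding three years.
#'
#' @param n_persons number of persons to simulate.
#' @param index_years calendar years for which prevalence is defined.
#' @param lookback_years years before each index year searched for
#'   procedures (default 3).
#' @param strata `data.table` with columns `regime`, `sex`, `region`,
#'   `age_group`, `weight` (summing to 1) and `prevalence_per_100k`;
#'   defaults to [default_strata()]. A single-stratum table is accepted.
#' @param persistence_distribution probability vector over 1..12: number of
#'   distinct coded months in an index year for a true case.
#' @param false_coding_rate probability a non-case has any lung-cancer-coded
#'   month in an index year.
#' @param false_months_distribution probability vector over 1..12 for the
#'   coded months of a false coder.
#' @param procedure_probability_case probability a true case has >= 1
#'   oncological procedure in the lookback window.
#' @param procedure_probability_noncase same for false coders.
#' @param leaf_codes ICD-10 leaf codes sampled uniformly for coded claims.
#' @param seed integer seed; all generation is deterministic given it.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_persons,
                              index_years = 2017:2019,
                              lookback_years = 3L,
                              strata = default_strata(),
                              persistence_distribution =
                                c(0.02, 0.03, 0.05, 0.12, 0.13, 0.14,
                                  0.13, 0.12, 0.10, 0.08, 0.05, 0.03),
                              false_coding_rate = 0.002,
                              false_months_distribution =
                                c(0.80, 0.15, 0.05, rep(0, 9)),
                              procedure_probability_case = 0.6,
                              procedure_probability_noncase = 0.02,
                              leaf_codes = DEFAULT_LEAF_CODES,
                              seed = 20230310L) {
  stopifnot(is.numeric(n_persons), length(n_persons) == 1L, n_persons >= 1)
  strata <- data.table::as.data.table(strata)
  required <- c("regime", "sex", "region", "age_group", "weight",
                "prevalence_per_100k")
  missing <- setdiff(required, names(strata))
  if (length(missing) > 0L) {
    stop(sprintf("invalid params: strata missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(strata$weight) - 1) > 1e-9) {
    stop("invalid params: stratum weights must sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (any(strata$prevalence_per_100k < 0)) {
    stop("invalid params: prevalence_per_100k must be non-negative",
         call. = FALSE)
  }
  check_pvec <- function(p, name) {
    if (length(p) != 12L || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf(
        "invalid params: %s must be a length-12 probability vector summing to 1",
        name), call. = FALSE)
    }
  }
  check_pvec(persistence_distribution, "persistence_distribution")
  check_pvec(false_months_distribution, "false_months_distribution")
  for (p in list(false_coding_rate, procedure_probability_case,
                 procedure_probability_noncase)) {
    if (p < 0 || p > 1) {
      stop("invalid params: probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  strata[, stratum_id := seq_len(.N)]
  structure(
    list(n_persons = as.integer(n_persons),
         index_years = as.integer(index_years),
         lookback_years = as.integer(lookback_years),
         strata = strata,
         persistence_distribution = persistence_distribution,
         false_coding_rate = false_coding_rate,
         false_months_distribution = false_months_distribution,
         procedure_probability_case = procedure_probability_case,
         procedure_probability_noncase = procedure_probability_noncase,
         leaf_codes = leaf_codes,
         seed = as.integer(seed)),
    class = "simulation_params")
}

age_bounds <- function(age_group) {
  switch(age_group,
         "20-44" = c(20L, 44L),
         "45-64" = c(45L, 64L),
         "65+"   = c(65L, 90L),
         stop(sprintf("unknown age_group: %s", age_group), call. = FALSE))
}

#' Generate a synthetic enrollment table and its ground-truth case table
#'
#' Persons are assigned to strata multinomially by `strata$weight`; case
#' status per index year is drawn independently as
#' Bernoulli(prevalence / 100,000) for the person's stratum. Everyone is
#' affiliated at mid-year of every index year (no enrollment churn).
#' Deterministic given `params$seed` (Mersenne-Twister).
#'
#' @param params a [simulation_params()] object.
#' @return list with `enrollment` (a `data.table` shaped like
#'   [read_enrollment()] output) and `truth` (person_id, stratum_id, one
#'   `is_case_<year>` column per index year).
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_persons
  strata <- params$strata
  sid <- sample.int(nrow(strata), n, replace = TRUE, prob = strata$weight)

  first_year <- min(params$index_years)
  bounds <- t(vapply(strata$age_group, age_bounds, integer(2)))
  lo <- bounds[sid, 1]
  hi <- bounds[sid, 2]
  age_at_first <- lo + floor(stats::runif(n) * (hi - lo + 1))
  enrollment <- data.table::data.table(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = strata$sex[sid],
    birth_year = as.integer(first_year - age_at_first),
    region = strata$region[sid],
    regime = strata$regime[sid])
  truth <- data.table::data.table(
    person_id = enrollment$person_id,
    stratum_id = sid)
  for (yr in params$index_years) {
    enrollment[, (sprintf("affiliated_%d", yr)) := TRUE]
    p <- strata$prevalence_per_100k[sid] / 1e5
    truth[, (sprintf("is_case_%d", yr)) := stats::runif(n) < p]
  }
  list(enrollment = enrollment[], truth = truth[])
}

sample_distinct_months <- function(k) {
  # vectorized draw of k distinct months of the year per person
  idx <- rep(seq_along(k), k)
  months <- unlist(lapply(k, function(ki) sample.int(12L, ki)), use.names = FALSE)
  list(person = idx, month = months)
}

emit_coded_claims <- function(ids, k, year, leaf_codes) {
  if (length(ids) == 0L) {
    return(data.table::data.table(person_id = character(0), year = integer(0),
                                  month = integer(0), icd10_code = character(0),
                                  procedure_category = character(0)))
  }
  dm <- sample_distinct_months(k)
  data.table::data.table(
    person_id = ids[dm$person],
    year = year,
    month = dm$month,
    icd10_code = leaf_codes[sample.int(length(leaf_codes), length(dm$month),
                                       replace = TRUE)],
    procedure_category = "none")
}

emit_procedure_claims <- function(ids, index_year, lookback_years, leaf_codes) {
  if (length(ids) == 0L) {
    return(data.table::data.table(person_id = character(0), year = integer(0),
                                  month = integer(0), icd10_code = character(0),
                                  procedure_category = character(0)))
  }
  n <- length(ids)
  data.table::data.table(
    person_id = ids,
    year = index_year - sample.int(lookback_years, n, replace = TRUE),
    month = sample.int(12L, n, replace = TRUE),
    icd10_code = leaf_codes[sample.int(length(leaf_codes), n, replace = TRUE)],
    procedure_category = ONCOLOGICAL_PROCEDURES[
      sample.int(3L, n, replace = TRUE)])
}

#' Generate synthetic claims for a generated population
#'
#' For each index year, every true case receives lung-cancer-coded claims in
#' `k ~ persistence_distribution` distinct months of that year and, with
#' probability `procedure_probability_case`, one oncological procedure claim
#' dated within the lookback window. Non-cases become false coders with
#' probability `false_coding_rate` (months drawn from
#' `false_months_distribution`, procedures with
#' `procedure_probability_noncase`). Deterministic given `params$seed`
#' (the claims stream uses `seed + 1`).
#'
#' @param population output of [generate_population()].
#' @param params the same [simulation_params()] object.
#' @return a `data.table` of claims (person_id, year, month, icd10_code,
#'   procedure_category).
#' @export
generate_claims <- function(population, params) {
  stopifnot(inherits(params, "simulation_params"))
  truth <- population$truth
  if (!identical(sort(truth$person_id), sort(population$enrollment$person_id))) {
    stop("truth table and enrollment table cover different persons",
         call. = FALSE)
  }
  set.seed(params$seed + 1L)
  pieces <- list()
  for (yr in params$index_years) {
    is_case <- truth[[sprintf("is_case_%d", yr)]]
    case_ids <- truth$person_id[is_case]
    noncase_ids <- truth$person_id[!is_case]

    k_case <- sample.int(12L, length(case_ids), replace = TRUE,
                         prob = params$persistence_distribution)
    pieces[[length(pieces) + 1L]] <-
      emit_coded_claims(case_ids, k_case, yr, params$leaf_codes)
    with_proc <- case_ids[stats::runif(length(case_ids)) <
                            params$procedure_probability_case]
    pieces[[length(pieces) + 1L]] <-
      emit_procedure_claims(with_proc, yr, params$lookback_years,
                            params$leaf_codes)

    false_ids <- noncase_ids[stats::runif(length(noncase_ids)) <
                               params$false_coding_rate]
    if (length(false_ids) > 0L) {
      k_false <- sample.int(12L, length(false_ids), replace = TRUE,
                            prob = params$false_months_distribution)
      pieces[[length(pieces) + 1L]] <-
        emit_coded_claims(false_ids, k_false, yr, params$leaf_codes)
      false_proc <- false_ids[stats::runif(length(false_ids)) <
                                params$procedure_probability_noncase]
      pieces[[length(pieces) + 1L]] <-
        emit_procedure_claims(false_proc, yr, params$lookback_years,
                              params$leaf_codes)
    }
  }
  claims <- data.table::rbindlist(pieces)
  data.table::setorder(claims, person_id, year, month)
  claims[]
}

#' Realized true prevalence in the synthetic truth table
#'
#' The parameter-recovery oracle: `100000 * cases / persons` within a
#' stratum-year, computed with exact integer counts before the one final
#' division.
#'
#' @param truth the truth `data.table` from [generate_population()].
#' @param params the [simulation_params()] used (for stratum definitions).
#' @param year index year.
#' @param stratum a [stratum_key()]; default the all-"all" aggregate.
#' @return realized prevalence per 100,000 (numeric scalar).
#' @export
true_prevalence <- function(truth, params, year, stratum = stratum_key()) {
  col <- sprintf("is_case_%d", year)
  if (!col %in% names(truth)) {
    stop(sprintf("truth table has no case column for year %d", year),
         call. = FALSE)
  }
  strata <- params$strata
  keep <- rep(TRUE, nrow(strata))
  if (stratum$regime != "all") keep <- keep & strata$regime == stratum$regime
  if (stratum$sex != "all") keep <- keep & strata$sex == stratum$sex
  if (stratum$age_group != "all") keep <- keep & strata$age_group == stratum$age_group
  if (stratum$region != "all") {
    keep <- keep & !is.na(strata$region) & strata$region == stratum$region
  }
  ids <- strata$stratum_id[keep]
  sub <- truth[truth$stratum_id %in% ids]
  if (nrow(sub) == 0L) stop("empty stratum in truth table", call. = FALSE)
  1e5 * sum(sub[[col]]) / nrow(sub)
}

#' Simulate a full synthetic dataset in one call
#'
#' @param params a [simulation_params()] object.
#' @return list with `enrollment`, `claims`, `truth`, and `params`.
#' @export
simulate_claims_data <- function(params) {
  pop <- generate_population(params)
  claims <- generate_claims(pop, params)
  list(enrollment = pop$enrollment, claims = claims, truth = pop$truth,
       params = params)
}
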