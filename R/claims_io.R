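# Data model, schema validation and readers/writers for the four tables the
# pipeline exchanges: enrollment, claims, benchmarks and prevalence estimates.

REGIONS <- c("Atlantic", "Bogota", "Central", "Oriental",
             "Orinoquia/Amazonia", "Pacific")
REGIMES <- c("contributory", "subsidized")
SEXES <- c("male", "female")
PROCEDURE_CATEGORIES <- c("chemotherapy", "radiotherapy", "surgery", "none")
ONCOLOGICAL_PROCEDURES <- c("chemotherapy", "radiotherapy", "surgery")

#' Normalize a raw ICD-10 diagnosis code
#'
#' Upper-cases the code and removes dots and internal whitespace, so that
#' `"c34.1"`, `"C34 1"` and `"C341"` all map to `"C341"`. Normalization is
#' idempotent: applying it twice equals applying it once.
#'
#' @param code character vector of raw diagnosis codes.
#' @return character vector of normalized codes, same length as `code`.
#' @examples
#' normalize_icd10(c("c34.1", "C33", " C34 9 "))
#' @export
normalize_icd10 <- function(code) {
  if (!is.character(code)) {
    stop("`code` must be a character vector", call. = FALSE)
  }
  out <- toupper(gsub("[.[:space:]]+", "", code))
  bad <- which(is.na(out) | !nzchar(out))
  if (length(bad) > 0L) {
    stop(sprintf("malformed ICD-10 code at record(s) %s: empty after normalization",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

new_validation_report <- function(record_counts, dropped_records, warnings) {
  structure(
    list(record_counts = record_counts,
         dropped_records = dropped_records,
         warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in names(x$record_counts)) {
    cat(sprintf("  %s: %d record(s)\n", nm, x$record_counts[[nm]]))
  }
  cat(sprintf("  dropped: %d\n", nrow(x$dropped_records)))
  if (nrow(x$dropped_records) > 0L) {
    reasons <- table(x$dropped_records$reason)
    for (r in names(reasons)) cat(sprintf("    %s: %d\n", r, reasons[[r]]))
  }
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}

require_columns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop(sprintf("%s file is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate an enrollment table
#'
#' Reads a delimited enrollment file into the denominator universe. Expected
#' columns: `person_id`, `sex`, `birth_year`, `region`, `regime`, plus one
#' logical `affiliated_<year>` column per study year (affiliation on 30 June
#' of that year). Rows violating the record invariants are dropped and
#' reported, not silently fixed: region is mandatory for the contributory
#' regime, `birth_year` must not exceed any affiliated year, and duplicated
#' `person_id`s keep the first occurrence with a warning.
#'
#' @param path path to a delimited text file with a header row.
#' @param delim field delimiter (default comma).
#' @param schema_config optional named character vector mapping canonical
#'   column names (`person_id`, `sex`, ...) to the names used in the file.
#' @return a list with elements `records` (a `data.table`) and `report`
#'   (a [`validation_report`][normalize_icd10]).
#' @export
read_enrollment <- function(path, delim = ",", schema_config = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read enrollment file: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = delim, colClasses = list(character = "person_id"))
  if (!is.null(schema_config)) {
    data.table::setnames(dt, old = unname(schema_config), new = names(schema_config),
                         skip_absent = TRUE)
  }
  require_columns(dt, c("person_id", "sex", "birth_year", "regime"), "enrollment")
  if (!"region" %in% names(dt)) dt[, region := NA_character_]

  affil_cols <- grep("^affiliated_[0-9]{4}$", names(dt), value = TRUE)
  if (length(affil_cols) == 0L) {
    stop("enrollment file has no affiliated_<year> column", call. = FALSE)
  }
  years <- as.integer(sub("^affiliated_", "", affil_cols))
  for (col in affil_cols) dt[, (col) := as.logical(get(col))]
  dt[, person_id := as.character(person_id)]
  dt[, birth_year := suppressWarnings(as.integer(birth_year))]
  dt[, region := data.table::fifelse(is.na(region) | region == "", NA_character_,
                                     as.character(region))]

  dropped <- list()
  drop_rows <- function(idx, reason) {
    if (length(idx) > 0L) {
      dropped[[length(dropped) + 1L]] <<- data.table::data.table(
        locator = dt$person_id[idx], reason = reason)
    }
    idx
  }

  bad <- integer(0)
  bad <- union(bad, drop_rows(which(is.na(dt$person_id) | dt$person_id == ""),
                              "missing person_id"))
  bad <- union(bad, drop_rows(which(!dt$sex %in% SEXES), "invalid sex"))
  bad <- union(bad, drop_rows(which(!dt$regime %in% REGIMES), "invalid regime"))
  bad <- union(bad, drop_rows(which(is.na(dt$birth_year)), "invalid birth_year"))
  # age must be >= 0 at every affiliated year
  min_affil_year <- apply(as.matrix(dt[, ..affil_cols]), 1L, function(row) {
    yy <- years[which(as.logical(row))]
    if (length(yy) == 0L) NA_integer_ else min(yy)
  })
  bad <- union(bad, drop_rows(
    which(!is.na(dt$birth_year) & !is.na(min_affil_year) &
            dt$birth_year > min_affil_year),
    "negative age at affiliated year"))
  bad <- union(bad, drop_rows(
    which(dt$regime == "contributory" & is.na(dt$region)), "missing region"))
  bad <- union(bad, drop_rows(
    which(!is.na(dt$region) & !dt$region %in% REGIONS), "unknown region"))

  keep <- setdiff(seq_len(nrow(dt)), bad)
  records <- dt[keep]

  warnings <- character(0)
  dup <- duplicated(records$person_id)
  if (any(dup)) {
    warnings <- c(warnings, sprintf(
      "%d duplicate person_id row(s) dropped (kept first occurrence): %s",
      sum(dup), paste(utils::head(unique(records$person_id[dup]), 5L),
                      collapse = ", ")))
    records <- records[!dup]
  }

  dropped_dt <- if (length(dropped) > 0L) data.table::rbindlist(dropped) else
    data.table::data.table(locator = character(0), reason = character(0))
  report <- new_validation_report(
    record_counts = list(enrollment = nrow(records)),
    dropped_records = dropped_dt,
    warnings = warnings)
  list(records = records[], report = report)
}

parse_service_month <- function(x) {
  # accepts ISO "YYYY-MM" or "YYYY-MM-DD"; anything else is unparseable
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})(-[0-9]{2})?$", x))
  year <- vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_,
                 integer(1))
  month <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_,
                  integer(1))
  month[!is.na(month) & (month < 1L | month > 12L)] <- NA_integer_
  year[is.na(month)] <- NA_integer_
  list(year = year, month = month)
}

#' Read and validate a claims table
#'
#' Reads a delimited service-line file. Expected columns: `person_id`,
#' `service_date` (ISO year-month or year-month-day; truncated to month),
#' `icd10_code` (normalized via [normalize_icd10()]) and
#' `procedure_category` (one of chemotherapy, radiotherapy, surgery, none;
#' empty values default to `"none"`). Rows with unparseable dates, empty
#' codes, or dates outside `study_horizon` are dropped with a reason.
#'
#' @param path path to a delimited text file with a header row.
#' @param delim field delimiter.
#' @param schema_config optional canonical-to-file column-name mapping.
#' @param study_horizon optional integer vector `c(first_year, last_year)`
#'   bounding valid service dates (lookback start to last index year).
#' @return list with `records` (`data.table` with columns `person_id`,
#'   `year`, `month`, `icd10_code`, `procedure_category`) and `report`.
#' @export
read_claims <- function(path, delim = ",", schema_config = NULL,
                        study_horizon = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read claims file: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = delim, colClasses = list(character = "person_id"))
  if (!is.null(schema_config)) {
    data.table::setnames(dt, old = unname(schema_config), new = names(schema_config),
                         skip_absent = TRUE)
  }
  require_columns(dt, c("person_id", "service_date", "icd10_code"), "claims")
  if (!"procedure_category" %in% names(dt)) dt[, procedure_category := "none"]
  dt[, person_id := as.character(person_id)]
  dt[, procedure_category := as.character(procedure_category)]
  dt[is.na(procedure_category) | procedure_category == "",
     procedure_category := "none"]

  ym <- parse_service_month(as.character(dt$service_date))
  dt[, `:=`(year = ym$year, month = ym$month)]

  dropped <- list()
  bad <- integer(0)
  add <- function(idx, reason) {
    if (length(idx) > 0L) {
      dropped[[length(dropped) + 1L]] <<- data.table::data.table(
        locator = sprintf("row %d (person %s)", idx, dt$person_id[idx]),
        reason = reason)
    }
    idx
  }
  bad <- union(bad, add(which(is.na(dt$year)), "unparseable date"))
  raw_code <- as.character(dt$icd10_code)
  empty_code <- which(is.na(raw_code) | !nzchar(trimws(raw_code)))
  bad <- union(bad, add(empty_code, "malformed code"))
  bad <- union(bad, add(which(!dt$procedure_category %in% PROCEDURE_CATEGORIES),
                        "unknown procedure_category"))
  if (!is.null(study_horizon)) {
    bad <- union(bad, add(
      which(!is.na(dt$year) &
              (dt$year < study_horizon[1] | dt$year > study_horizon[2])),
      "outside study horizon"))
  }

  keep <- setdiff(seq_len(nrow(dt)), bad)
  records <- dt[keep]
  records[, icd10_code := normalize_icd10(icd10_code)]
  records <- records[, .(person_id, year, month, icd10_code, procedure_category)]

  dropped_dt <- if (length(dropped) > 0L) data.table::rbindlist(dropped) else
    data.table::data.table(locator = character(0), reason = character(0))
  report <- new_validation_report(
    record_counts = list(claims = nrow(records)),
    dropped_records = dropped_dt,
    warnings = character(0))
  list(records = records[], report = report)
}

#' Write a claims table in the on-disk schema
#'
#' Renders the in-memory `year`/`month` pair back to an ISO `service_date`
#' (`YYYY-MM`) column so the file is readable by [read_claims()].
#'
#' @param claims claims `data.table`.
#' @param path output path.
#' @param delim field delimiter.
#' @return invisibly, the path written.
#' @export
write_claims <- function(claims, path, delim = ",") {
  out <- data.table::data.table(
    person_id = claims$person_id,
    service_date = sprintf("%04d-%02d", claims$year, claims$month),
    icd10_code = claims$icd10_code,
    procedure_category = claims$procedure_category)
  data.table::fwrite(out, path, sep = delim)
  invisible(path)
}

#' Read a benchmark table of official aggregated prevalence rates
#'
#' Columns: `source` (e.g. CAC, NCI, GLOBOCAN), `stratum` (the string
#' `"general"` or a `field=value` pair such as `"sex=female"`), and
#' `rate_per_100k` (non-negative).
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter.
#' @return a `data.table` with the three columns above.
#' @export
read_benchmarks <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("cannot read benchmark file: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = delim)
  require_columns(dt, c("source", "stratum", "rate_per_100k"), "benchmark")
  dt[, rate_per_100k := as.numeric(rate_per_100k)]
  if (any(is.na(dt$rate_per_100k) | dt$rate_per_100k < 0)) {
    stop("benchmark rates must be non-negative numbers", call. = FALSE)
  }
  dt[]
}

#' Write prevalence estimates to a delimited file
#'
#' One row per (algorithm, year, stratum); the rate and both CI bounds are
#' rendered with two decimals in separate columns so the file round-trips to
#' rendered precision through [read_estimates()].
#'
#' @param estimates a non-empty `data.table` of prevalence estimates as
#'   produced by [bootstrap_ci()] or [stratum_prevalence()].
#' @param path output path.
#' @param delim field delimiter.
#' @return invisibly, the path written.
#' @export
write_estimates <- function(estimates, path, delim = ",") {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    stop("`estimates` must be non-empty", call. = FALSE)
  }
  out <- data.table::copy(data.table::as.data.table(estimates))
  for (col in intersect(c("rate_per_100k", "ci_low", "ci_high"), names(out))) {
    out[, (col) := sprintf("%.2f", get(col))]
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = delim)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write estimates to: %s", path), call. = FALSE)
  invisible(path)
}

#' Read back a prevalence-estimates file written by [write_estimates()]
#' @param path path to the file.
#' @param delim field delimiter.
#' @return a `data.table`.
#' @export
read_estimates <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("cannot read estimates file: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = delim, colClasses = list(character = "algorithm_label"))
  for (col in intersect(c("rate_per_100k", "ci_low", "ci_high"), names(dt))) {
    dt[, (col) := as.numeric(get(col))]
  }
  dt[]
}
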