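# The candidate algorithm grid and its application to a claims table.
# An algorithm is a computable phenotype: a minimum number of distinct
# lung-cancer-coded calendar months in the index year, optionally combined
# with at least one oncological procedure in a lookback window of preceding
# calendar years.

#' Construct a case-identification algorithm specification
#'
#' @param min_months minimum distinct calendar months of the index year with
#'   at least one lung-cancer-coded claim (1..12).
#' @param require_procedure logical; whether at least one oncological
#'   procedure (chemotherapy, radiotherapy or surgery) is required in the
#'   lookback window. `FALSE` defines the "sensitive" family, `TRUE` the
#'   "specific" family.
#' @param lookback_years length of the procedure lookback window; the window
#'   is the `lookback_years` calendar years strictly before the index year.
#' @param code_roots ICD-10 prefixes defining the target condition; leaf
#'   codes under a root match by prefix.
#' @param label human-readable label; defaults to e.g. `"sensitive-m4"`.
#' @return an object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(min_months, require_procedure = FALSE,
                           lookback_years = 3L,
                           code_roots = c("C33", "C34"), label = NULL) {
  min_months <- as.integer(min_months)
  if (is.na(min_months) || min_months < 1L || min_months > 12L) {
    stop("min_months must be an integer in 1..12", call. = FALSE)
  }
  if (lookback_years < 1L) stop("lookback_years must be >= 1", call. = FALSE)
  if (length(code_roots) == 0L) stop("code_roots must be non-empty", call. = FALSE)
  if (is.null(label)) {
    label <- sprintf("%s-m%d",
                     if (require_procedure) "specific" else "sensitive",
                     min_months)
  }
  structure(
    list(min_months = min_months,
         require_procedure = isTRUE(require_procedure),
         lookback_years = as.integer(lookback_years),
         code_roots = toupper(code_roots),
         label = label),
    class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf(
    "<algorithm_spec> %s: >=%d coded month(s)%s; roots %s; lookback %d y\n",
    x$label, x$min_months,
    if (x$require_procedure) " + >=1 oncological procedure" else "",
    paste(x$code_roots, collapse = ","), x$lookback_years))
  invisible(x)
}

#' Does a normalized ICD-10 code denote the target condition?
#'
#' Prefix match against the configured roots, so `"C341"` matches root
#' `"C34"` and a root matches itself.
#'
#' @param code character vector of normalized codes.
#' @param code_roots character vector of prefixes.
#' @return logical vector.
#' @export
is_lung_cancer_code <- function(code, code_roots = c("C33", "C34")) {
  Reduce(`|`, lapply(code_roots, function(r) startsWith(code, r)))
}

#' Count distinct coded months for one person in an index year
#'
#' Number of distinct calendar months of `index_year` with at least one
#' claim for `person_id` whose code matches `code_roots`; repeated claims
#' within a month count once, and claims outside the index year never count.
#'
#' @param claims claims `data.table` (normalized codes).
#' @param person_id person identifier.
#' @param index_year calendar year.
#' @param code_roots ICD-10 prefixes.
#' @return integer in 0..12 (0 if the person has no matching claims).
#' @export
count_code_months <- function(claims, person_id, index_year,
                              code_roots = c("C33", "C34")) {
  pid <- person_id
  sub <- claims[claims$person_id == pid & claims$year == index_year]
  if (nrow(sub) == 0L) return(0L)
  length(unique(sub$month[is_lung_cancer_code(sub$icd10_code, code_roots)]))
}

#' Does a person have an oncological procedure in the lookback window?
#'
#' TRUE iff at least one claim with procedure category chemotherapy,
#' radiotherapy or surgery is dated in the calendar years
#' `[index_year - lookback_years, index_year - 1]` — strictly before the
#' index year.
#'
#' @inheritParams count_code_months
#' @param lookback_years window length in years.
#' @return logical scalar.
#' @export
has_oncological_procedure <- function(claims, person_id, index_year,
                                      lookback_years = 3L) {
  pid <- person_id
  any(claims$person_id == pid &
        claims$procedure_category %in% ONCOLOGICAL_PROCEDURES &
        claims$year >= index_year - lookback_years &
        claims$year <= index_year - 1L)
}

# vectorized internals used by identify_cases -------------------------------

code_month_counts <- function(claims, index_year, code_roots) {
  sub <- claims[claims$year == index_year &
                  is_lung_cancer_code(claims$icd10_code, code_roots)]
  if (nrow(sub) == 0L) {
    return(data.table::data.table(person_id = character(0),
                                  n_months = integer(0)))
  }
  sub[, .(n_months = data.table::uniqueN(month)), by = person_id]
}

procedure_person_ids <- function(claims, index_year, lookback_years) {
  unique(claims$person_id[
    claims$procedure_category %in% ONCOLOGICAL_PROCEDURES &
      claims$year >= index_year - lookback_years &
      claims$year <= index_year - 1L])
}

eligible_persons <- function(enrollment, index_year) {
  col <- sprintf("affiliated_%d", index_year)
  if (!col %in% names(enrollment)) {
    stop(sprintf("enrollment table has no affiliation column for year %d",
                 index_year), call. = FALSE)
  }
  affil <- enrollment[[col]]
  affil & (index_year - enrollment$birth_year) >= 20L
}

#' Apply an algorithm to a claims table for one index year
#'
#' Members are the persons affiliated at mid-year of `index_year`, aged 20
#' or older at the index year (age = `index_year - birth_year`), with at
#' least `spec$min_months` distinct coded months in the index year, and —
#' when `spec$require_procedure` — at least one oncological procedure in the
#' lookback window. Equivalent to a per-person brute-force scan.
#'
#' @param claims claims `data.table` (normalized codes).
#' @param enrollment enrollment `data.table`.
#' @param spec an [algorithm_spec()].
#' @param index_year calendar year.
#' @return an object of class `case_set` with fields `index_year`,
#'   `algorithm`, and `members` (character vector of person ids).
#' @export
identify_cases <- function(claims, enrollment, spec, index_year) {
  stopifnot(inherits(spec, "algorithm_spec"))
  eligible <- eligible_persons(enrollment, index_year)
  pool <- enrollment$person_id[eligible]

  counts <- code_month_counts(claims, index_year, spec$code_roots)
  hits <- counts$person_id[counts$n_months >= spec$min_months]
  members <- intersect(hits, pool)
  if (spec$require_procedure) {
    members <- intersect(
      members, procedure_person_ids(claims, index_year, spec$lookback_years))
  }
  structure(
    list(index_year = as.integer(index_year), algorithm = spec,
         members = sort(members)),
    class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %s, year %d: %d member(s)\n",
              x$algorithm$label, x$index_year, length(x$members)))
  invisible(x)
}

#' Enumerate the candidate algorithm grid
#'
#' The default grid crosses `min_months` 1..8 with the procedure requirement
#' off and on, giving 16 candidate algorithms ordered by `min_months` then
#' by procedure requirement (sensitive before specific).
#'
#' @param min_months integer vector of month thresholds.
#' @param require_procedure logical vector of procedure options.
#' @param lookback_years,code_roots passed to [algorithm_spec()].
#' @return ordered list of `algorithm_spec` objects.
#' @export
enumerate_algorithm_grid <- function(min_months = 1:8,
                                     require_procedure = c(FALSE, TRUE),
                                     lookback_years = 3L,
                                     code_roots = c("C33", "C34")) {
  if (length(min_months) == 0L || length(require_procedure) == 0L) {
    stop("algorithm grid is empty", call. = FALSE)
  }
  grid <- expand.grid(require_procedure = sort(require_procedure),
                      min_months = sort(unique(as.integer(min_months))))
  grid <- grid[order(grid$min_months, grid$require_procedure), ]
  lapply(seq_len(nrow(grid)), function(i) {
    algorithm_spec(min_months = grid$min_months[i],
                   require_procedure = grid$require_procedure[i],
                   lookback_years = lookback_years,
                   code_roots = code_roots)
  })
}
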