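# Stratified and aggregated prevalence per 100,000 with nonparametric
# bootstrap percentile confidence intervals. The denominator is the mid-year
# affiliated headcount aged >= 20; age groups are the half-open bins
# [20,45), [45,65), [65,Inf) labelled "20-44", "45-64", "65+".

AGE_GROUPS <- c("20-44", "45-64", "65+")

#' Construct a stratum key
#'
#' A stratum is a combination of regime, sex, age group and region, each of
#' which may be `"all"` (marginalized). Region may only be specified for the
#' contributory regime: the subsidized data carry no region.
#'
#' @param regime one of contributory, subsidized, all.
#' @param sex one of male, female, all.
#' @param age_group one of 20-44, 45-64, 65+, all.
#' @param region one of the six regions or all.
#' @return an object of class `stratum_key`.
#' @export
stratum_key <- function(regime = "all", sex = "all", age_group = "all",
                        region = "all") {
  match_one <- function(x, choices, what) {
    if (!x %in% c(choices, "all")) {
      stop(sprintf("invalid %s: %s (expected one of %s, all)", what, x,
                   paste(choices, collapse = ", ")), call. = FALSE)
    }
    x
  }
  regime <- match_one(regime, REGIMES, "regime")
  sex <- match_one(sex, SEXES, "sex")
  age_group <- match_one(age_group, AGE_GROUPS, "age_group")
  region <- match_one(region, REGIONS, "region")
  if (region != "all" && regime != "contributory") {
    stop("region-specific strata require regime = \"contributory\"",
         call. = FALSE)
  }
  structure(list(regime = regime, sex = sex, age_group = age_group,
                 region = region),
            class = "stratum_key")
}

#' @export
format.stratum_key <- function(x, ...) {
  parts <- c(regime = x$regime, sex = x$sex, age_group = x$age_group,
             region = x$region)
  parts <- parts[parts != "all"]
  if (length(parts) == 0L) return("general")
  paste(sprintf("%s=%s", names(parts), parts), collapse = ",")
}

#' @export
print.stratum_key <- function(x, ...) {
  cat(sprintf("<stratum_key> %s\n", format(x)))
  invisible(x)
}

#' Parse a stratum label back into a [stratum_key()]
#' @param label `"general"` or comma-separated `field=value` pairs.
#' @return a `stratum_key`.
#' @export
parse_stratum <- function(label) {
  if (identical(label, "general") || !nzchar(label)) return(stratum_key())
  kv <- strsplit(strsplit(label, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  args <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  do.call(stratum_key, as.list(args))
}

age_group_of <- function(age) {
  # half-open bins restore a partition of ages >= 20
  out <- rep(NA_character_, length(age))
  out[age >= 20 & age < 45] <- "20-44"
  out[age >= 45 & age < 65] <- "45-64"
  out[age >= 65] <- "65+"
  out
}

stratum_membership <- function(enrollment, index_year, stratum) {
  keep <- rep(TRUE, nrow(enrollment))
  if (stratum$regime != "all") keep <- keep & enrollment$regime == stratum$regime
  if (stratum$sex != "all") keep <- keep & enrollment$sex == stratum$sex
  if (stratum$age_group != "all") {
    ag <- age_group_of(index_year - enrollment$birth_year)
    keep <- keep & !is.na(ag) & ag == stratum$age_group
  }
  if (stratum$region != "all") {
    keep <- keep & !is.na(enrollment$region) &
      enrollment$region == stratum$region
  }
  keep
}

#' Mid-year denominator for a stratum
#'
#' Count of persons affiliated on 30 June of `index_year`, aged 20 or older
#' at the index year, matching every non-`"all"` field of the stratum.
#'
#' @param enrollment enrollment `data.table`.
#' @param index_year calendar year.
#' @param stratum a [stratum_key()].
#' @return integer count.
#' @export
midyear_denominator <- function(enrollment, index_year,
                                stratum = stratum_key()) {
  sum(eligible_persons(enrollment, index_year) &
        stratum_membership(enrollment, index_year, stratum))
}

new_estimate_row <- function(algorithm_label, index_year, stratum,
                             numerator, denominator,
                             ci_low = NA_real_, ci_high = NA_real_,
                             n_boot = NA_integer_, seed = NA_integer_) {
  data.table::data.table(
    algorithm_label = algorithm_label,
    index_year = as.integer(index_year),
    stratum = format(stratum),
    regime = stratum$regime, sex = stratum$sex,
    age_group = stratum$age_group, region = stratum$region,
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    rate_per_100k = 1e5 * numerator / denominator,
    ci_low = ci_low, ci_high = ci_high,
    n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Point prevalence of a case set within a stratum
#'
#' `100000 * |members in stratum| / mid-year denominator`. An empty stratum
#' denominator is an explicit error, never NaN.
#'
#' @param caseset a `case_set` from [identify_cases()].
#' @param enrollment enrollment `data.table` from the same universe.
#' @param stratum a [stratum_key()].
#' @return a one-row `data.table` prevalence estimate (CI columns `NA`).
#' @export
stratum_prevalence <- function(caseset, enrollment, stratum = stratum_key()) {
  stopifnot(inherits(caseset, "case_set"))
  denom <- midyear_denominator(enrollment, caseset$index_year, stratum)
  if (denom == 0L) {
    stop(sprintf("empty stratum denominator for %s in %d", format(stratum),
                 caseset$index_year), call. = FALSE)
  }
  in_stratum <- stratum_membership(enrollment, caseset$index_year, stratum) &
    eligible_persons(enrollment, caseset$index_year)
  num <- sum(enrollment$person_id[in_stratum] %in% caseset$members)
  new_estimate_row(caseset$algorithm$label, caseset$index_year, stratum,
                   num, denom)
}

#' Aggregate prevalence from stratum case counts
#'
#' Combines the per-(region, age group, sex) contributory counts `n_ijk`
#' with the per-(age group, sex) subsidized counts `m_jk` over a mid-year
#' global denominator: `100000 * (sum(n_ijk) + sum(m_jk)) / N_global`. When
#' the strata partition the population this equals the union-case-set rate
#' exactly.
#'
#' @param n_ijk integer vector of contributory stratum numerators.
#' @param m_jk integer vector of subsidized stratum numerators.
#' @param N_global total mid-year affiliated count (aged >= 20).
#' @return prevalence rate per 100,000 (numeric scalar).
#' @export
aggregate_prevalence <- function(n_ijk, m_jk, N_global) {
  if (N_global <= 0) stop("N_global must be positive", call. = FALSE)
  if (any(n_ijk < 0) || any(m_jk < 0)) {
    stop("stratum numerators must be non-negative", call. = FALSE)
  }
  total <- sum(n_ijk) + sum(m_jk)
  if (total > N_global) {
    stop("aggregate numerator exceeds N_global: overlapping strata?",
         call. = FALSE)
  }
  1e5 * total / N_global
}

#' Bootstrap confidence intervals for stratified prevalence
#'
#' Nonparametric bootstrap: persons (enrollment rows, carrying their claims)
#' are resampled with replacement to the original population size `B` times;
#' each stratum rate is recomputed per replicate and the CI is the 2.5th and
#' 97.5th percentile of the replicate distribution. A replicate with an
#' empty stratum denominator contributes rate 0 (with one warning).
#' Deterministic given `seed`.
#'
#' @param claims claims `data.table` (normalized).
#' @param enrollment enrollment `data.table`.
#' @param spec an [algorithm_spec()].
#' @param index_year calendar year.
#' @param strata list of [stratum_key()] objects (default: the aggregate).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95, percentile method).
#' @return a `data.table` with one estimate row per stratum, CI filled in.
#' @export
bootstrap_ci <- function(claims, enrollment, spec, index_year,
                         strata = list(stratum_key()), B = 1000L,
                         seed = 20230310L, conf_level = 0.95) {
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  if (inherits(strata, "stratum_key")) strata <- list(strata)
  caseset <- identify_cases(claims, enrollment, spec, index_year)

  n <- nrow(enrollment)
  eligible <- eligible_persons(enrollment, index_year)
  is_case <- eligible & (enrollment$person_id %in% caseset$members)
  memb <- vapply(strata, function(s) {
    stratum_membership(enrollment, index_year, s) & eligible
  }, logical(n))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = n)

  point <- data.table::rbindlist(lapply(strata, function(s) {
    stratum_prevalence(caseset, enrollment, s)
  }))

  set.seed(seed)
  alpha <- (1 - conf_level) / 2
  rates <- matrix(NA_real_, nrow = B, ncol = length(strata))
  empty_seen <- FALSE
  case_num <- as.numeric(is_case)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    for (s in seq_along(strata)) {
      in_s <- memb[idx, s]
      den <- sum(in_s)
      if (den == 0L) {
        empty_seen <- TRUE
        rates[b, s] <- 0
      } else {
        rates[b, s] <- 1e5 * sum(case_num[idx][in_s]) / den
      }
    }
  }
  if (empty_seen) {
    warning("some bootstrap replicates had an empty stratum; rate 0 used",
            call. = FALSE)
  }
  qs <- apply(rates, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  seed_used <- as.integer(seed)
  point[, `:=`(ci_low = qs[1, ], ci_high = qs[2, ],
               n_boot = as.integer(B))]
  point[, seed := seed_used]
  point[]
}
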