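make_enrollment <- function(n_female = 400, n_male = 600, year = 2018L) {
  data.table::data.table(
    person_id = sprintf("e%04d", seq_len(n_female + n_male)),
    sex = c(rep("female", n_female), rep("male", n_male)),
    birth_year = 1960L,
    region = "Central", regime = "contributory",
    affiliated_2018 = TRUE)
}

test_that("stratum_key validates fields and region/regime coupling", {
  expect_equal(format(stratum_key()), "general")
  expect_equal(format(stratum_key(sex = "female", age_group = "65+")),
               "sex=female,age_group=65+")
  expect_error(stratum_key(sex = "other"), "invalid sex")
  expect_error(stratum_key(region = "Pacific"), "contributory")
  expect_error(stratum_key(regime = "subsidized", region = "Pacific"),
               "contributory")
  # label round-trip
  k <- stratum_key(regime = "contributory", region = "Pacific")
  expect_equal(format(parse_stratum(format(k))), format(k))
  expect_equal(format(parse_stratum("general")), "general")
})

test_that("midyear_denominator counts eligible affiliated persons", {
  enr <- make_enrollment()
  expect_equal(midyear_denominator(enr, 2018), 1000L)
  expect_equal(midyear_denominator(enr, 2018, stratum_key(sex = "female")),
               400L)
  # a person not affiliated at mid-year is excluded even with claims
  enr$affiliated_2018[1] <- FALSE
  expect_equal(midyear_denominator(enr, 2018), 999L)
  # under-20s are excluded from the denominator
  enr$birth_year[2] <- 2000L
  expect_equal(midyear_denominator(enr, 2018), 998L)
  expect_error(midyear_denominator(enr, 2020), "no affiliation column")
})

fixed_caseset <- function(members, year = 2018L, spec = algorithm_spec(4)) {
  structure(list(index_year = year, algorithm = spec,
                 members = sort(members)),
            class = "case_set")
}

test_that("stratum_prevalence computes exact rates and guards division", {
  enr <- make_enrollment(n_female = 25000, n_male = 25000)
  est <- stratum_prevalence(fixed_caseset(enr$person_id[1:5]), enr)
  expect_equal(est$rate_per_100k, 10)
  expect_equal(est$numerator, 5L)
  expect_equal(est$denominator, 50000L)

  est0 <- stratum_prevalence(fixed_caseset(character(0)), enr)
  expect_equal(est0$rate_per_100k, 0)

  expect_error(
    stratum_prevalence(fixed_caseset("e0001"), enr,
                       stratum_key(regime = "subsidized")),
    "empty stratum")
})

test_that("aggregate_prevalence matches arithmetic and guards overlap", {
  expect_equal(aggregate_prevalence(c(2, 3), 5, 100000), 10)
  expect_equal(aggregate_prevalence(rep(0, 4), rep(0, 2), 1000), 0)
  expect_error(aggregate_prevalence(c(900), c(200), 1000), "overlapping")
  expect_error(aggregate_prevalence(1, 1, 0), "positive")
})

test_that("sum-over-strata equals the union-case-set rate exactly", {
  for (seed in 31:40) {
    inst <- random_instance(seed)
    spec <- algorithm_spec(2)
    cs <- identify_cases(inst$claims, inst$enrollment, spec, inst$index_year)
    # full cross-classification of the eligible universe
    enr <- inst$enrollment
    N_global <- midyear_denominator(enr, inst$index_year)
    if (N_global == 0) next
    combos <- data.table::CJ(sex = c("male", "female"),
                             age_group = c("20-44", "45-64", "65+"))
    n_ijk <- c()
    m_jk <- c()
    for (i in seq_len(nrow(combos))) {
      for (reg in unique(stats::na.omit(enr$region))) {
        s <- stratum_key(regime = "contributory", sex = combos$sex[i],
                         age_group = combos$age_group[i], region = reg)
        if (midyear_denominator(enr, inst$index_year, s) > 0) {
          n_ijk <- c(n_ijk, stratum_prevalence(cs, enr, s)$numerator)
        }
      }
      s2 <- stratum_key(regime = "subsidized", sex = combos$sex[i],
                        age_group = combos$age_group[i])
      if (midyear_denominator(enr, inst$index_year, s2) > 0) {
        m_jk <- c(m_jk, stratum_prevalence(cs, enr, s2)$numerator)
      }
    }
    union_rate <- stratum_prevalence(cs, enr, stratum_key())$rate_per_100k
    expect_identical(sum(n_ijk) + sum(m_jk), length(cs$members))
    expect_equal(aggregate_prevalence(n_ijk, m_jk, N_global), union_rate)
  }
})

test_that("bootstrap_ci is deterministic and degenerate when variance is 0", {
  # every person is a case: every resample yields rate 100000
  enr <- make_enrollment(n_female = 0, n_male = 50)
  cl <- data.table::rbindlist(lapply(enr$person_id, function(p) {
    data.table::data.table(person_id = p, year = 2018L, month = 1:4,
                           icd10_code = "C341", procedure_category = "none")
  }))
  est <- bootstrap_ci(cl, enr, algorithm_spec(4), 2018, B = 50, seed = 9)
  expect_equal(est$ci_low, est$rate_per_100k)
  expect_equal(est$ci_high, est$rate_per_100k)
  expect_equal(est$rate_per_100k, 1e5)
  expect_equal(est$n_boot, 50L)

  est2 <- bootstrap_ci(cl, enr, algorithm_spec(4), 2018, B = 50, seed = 9)
  expect_identical(est, est2)
  expect_error(bootstrap_ci(cl, enr, algorithm_spec(4), 2018, B = 1),
               "B must be >= 2")
})

test_that("bootstrap CI brackets the point estimate and stays in bounds", {
  p <- single_stratum_params(20000, 200, seed = 13, index_years = 2018L,
                             persistence_distribution = point_mass(6),
                             false_coding_rate = 0,
                             procedure_probability_case = 1)
  sim <- simulate_claims_data(p)
  est <- bootstrap_ci(sim$claims, sim$enrollment, algorithm_spec(4, TRUE),
                      2018, B = 200, seed = 3)
  expect_lte(est$ci_low, est$rate_per_100k)
  expect_gte(est$ci_high, est$rate_per_100k)
  expect_gte(est$ci_low, 0)
  expect_lte(est$ci_high, 1e5)
})

test_that("CI width shrinks with population size at fixed prevalence", {
  widths <- vapply(c(5000, 50000), function(n) {
    p <- single_stratum_params(n, 500, seed = 17, index_years = 2018L,
                               persistence_distribution = point_mass(6),
                               false_coding_rate = 0,
                               procedure_probability_case = 1)
    sim <- simulate_claims_data(p)
    est <- bootstrap_ci(sim$claims, sim$enrollment, algorithm_spec(4), 2018,
                        B = 100, seed = 5)
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})
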