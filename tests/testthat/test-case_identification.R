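test_that("is_lung_cancer_code matches by prefix on normalized codes", {
  expect_true(is_lung_cancer_code("C341"))
  expect_true(is_lung_cancer_code("C33"))
  expect_false(is_lung_cancer_code("C50"))
  expect_equal(is_lung_cancer_code(c("C330", "C349", "C780", "D341")),
               c(TRUE, TRUE, FALSE, FALSE))
})

tiny_claims <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(person_id = r[[1]], year = as.integer(r[[2]]),
                           month = as.integer(r[[3]]), icd10_code = r[[4]],
                           procedure_category = r[[5]])
  }))
}

test_that("count_code_months counts distinct index-year months only", {
  cl <- tiny_claims(
    list("p1", 2018, 1, "C341", "none"),
    list("p1", 2018, 1, "C33", "none"),
    list("p1", 2018, 3, "C349", "none"),
    list("p1", 2017, 5, "C341", "none"),
    list("p2", 2017, 6, "C341", "none"))
  expect_equal(count_code_months(cl, "p1", 2018), 2L)
  expect_equal(count_code_months(cl, "p2", 2018), 0L)
  expect_equal(count_code_months(cl, "absent", 2018), 0L)
  cl12 <- do.call(tiny_claims, lapply(1:12, function(m)
    list("p3", 2018, m, "C33", "none")))
  expect_equal(count_code_months(cl12, "p3", 2018), 12L)
})

test_that("has_oncological_procedure uses a strictly-prior lookback window", {
  # paper-style window: index 2018, lookback 3 -> years 2015..2017
  cl <- tiny_claims(list("p1", 2015, 6, "C341", "chemotherapy"))
  expect_true(has_oncological_procedure(cl, "p1", 2018, 3))
  cl2 <- tiny_claims(list("p1", 2014, 12, "C341", "surgery"))
  expect_false(has_oncological_procedure(cl2, "p1", 2018, 3))
  # a procedure in the index year itself never satisfies the criterion
  cl3 <- tiny_claims(list("p1", 2018, 2, "C341", "radiotherapy"))
  expect_false(has_oncological_procedure(cl3, "p1", 2018, 3))
})

test_that("lookback window agrees with a brute-force year scan", {
  set.seed(42)
  for (rep in 1:25) {
    yr <- sample(2012:2020, 1)
    lb <- sample(1:5, 1)
    cl <- tiny_claims(list("p1", sample(2008:2022, 1), sample(1:12, 1),
                           "C341", sample(c("chemotherapy", "surgery"), 1)))
    oracle <- any(vapply((yr - lb):(yr - 1), function(y) cl$year[1] == y,
                         logical(1)))
    expect_identical(has_oncological_procedure(cl, "p1", yr, lb), oracle)
  }
})

test_that("identify_cases applies eligibility, months and procedure rules", {
  enrollment <- data.table::data.table(
    person_id = c("p1", "p2", "p3", "p4"),
    sex = "male", birth_year = c(1960L, 1960L, 1999L, 1960L),
    region = "Central", regime = "contributory",
    affiliated_2018 = c(TRUE, TRUE, TRUE, FALSE))
  four_months <- function(pid) {
    do.call(tiny_claims, lapply(1:4, function(m)
      list(pid, 2018, m, "C341", "none")))
  }
  cl <- rbind(four_months("p1"), four_months("p3"), four_months("p4"))

  sens <- identify_cases(cl, enrollment, algorithm_spec(4), 2018)
  # p3 is aged 19 and p4 is unaffiliated at mid-year: both excluded
  expect_equal(sens$members, "p1")
  spec <- identify_cases(cl, enrollment, algorithm_spec(4, TRUE), 2018)
  expect_equal(spec$members, character(0))

  cl2 <- rbind(cl, tiny_claims(list("p1", 2016, 5, "C341", "chemotherapy")))
  spec2 <- identify_cases(cl2, enrollment, algorithm_spec(4, TRUE), 2018)
  expect_equal(spec2$members, "p1")

  expect_error(identify_cases(cl, enrollment, algorithm_spec(4), 2019),
               "no affiliation column")
})

test_that("enumerate_algorithm_grid builds the ordered candidate grid", {
  grid <- enumerate_algorithm_grid()
  expect_length(grid, 16L)
  labels <- vapply(grid, `[[`, character(1), "label")
  expect_equal(labels[1:4],
               c("sensitive-m1", "specific-m1", "sensitive-m2", "specific-m2"))
  expect_true(all(c("sensitive-m4", "specific-m4") %in% labels))

  pair <- enumerate_algorithm_grid(min_months = 4)
  expect_length(pair, 2L)
  expect_equal(vapply(pair, `[[`, character(1), "label"),
               c("sensitive-m4", "specific-m4"))

  expect_length(enumerate_algorithm_grid(1:3, FALSE), 3L)
  expect_error(enumerate_algorithm_grid(integer(0)), "empty")
})

test_that("identify_cases equals the brute-force oracle on random worlds", {
  grid <- enumerate_algorithm_grid()
  for (seed in 1:20) {
    inst <- random_instance(seed)
    for (spec in grid[c(1, 6, 7, 8, 16)]) {
      got <- identify_cases(inst$claims, inst$enrollment, spec,
                            inst$index_year)$members
      want <- oracle_identify(inst$claims, inst$enrollment, spec,
                              inst$index_year)
      expect_identical(got, want,
                       label = sprintf("seed %d, %s", seed, spec$label))
    }
  }
})

test_that("specific subsets sensitive; counts monotone in min_months", {
  for (seed in 21:30) {
    inst <- random_instance(seed)
    prev_n <- Inf
    for (m in 1:8) {
      sens <- identify_cases(inst$claims, inst$enrollment,
                             algorithm_spec(m), inst$index_year)$members
      spec <- identify_cases(inst$claims, inst$enrollment,
                             algorithm_spec(m, TRUE), inst$index_year)$members
      expect_true(all(spec %in% sens))
      expect_lte(length(sens), prev_n)
      prev_n <- length(sens)
    }
  }
})
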