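# Scoring every grid algorithm's aggregate estimate against external
# benchmark point values, and picking the sensitive and specific winners.
# "Closest to the official sources" is operationalized as: number of
# benchmark point estimates falling inside the bootstrap CI (dominant),
# with the summed absolute distance between point rate and benchmarks as
# tie-break, then the smaller month threshold.

#' Benchmark-consistency score of one estimate
#'
#' @param estimate a one-row prevalence estimate (list or single-row
#'   `data.frame`) with `rate_per_100k`, `ci_low`, `ci_high` and `stratum`.
#' @param benchmarks `data.table` of benchmark values whose `stratum` column
#'   matches the estimate's stratum.
#' @return list with `score` (count of benchmarks inside the CI, closed
#'   interval) and `distance` (sum of absolute differences between the point
#'   rate and each benchmark).
#' @export
consistency_score <- function(estimate, benchmarks) {
  est <- as.list(data.table::as.data.table(estimate)[1])
  if (is.na(est$ci_low) || is.na(est$ci_high)) {
    stop("estimate has no confidence interval", call. = FALSE)
  }
  if (nrow(benchmarks) == 0L) stop("benchmarks must be non-empty", call. = FALSE)
  est_stratum <- if (!is.null(est$stratum)) est$stratum else "general"
  if (!all(benchmarks$stratum == est_stratum)) {
    stop(sprintf(
      "benchmark strata (%s) do not match estimate stratum (%s)",
      paste(unique(benchmarks$stratum), collapse = ", "), est_stratum),
      call. = FALSE)
  }
  b <- benchmarks$rate_per_100k
  list(score = sum(b >= est$ci_low & b <= est$ci_high),
       distance = sum(abs(est$rate_per_100k - b)))
}

#' Select the best sensitive and specific algorithms against benchmarks
#'
#' Every algorithm's aggregate estimates (one per index year, with CIs) are
#' scored against the benchmark point values; scores and distances are
#' summed over the index years. Within each family (no procedure
#' requirement = sensitive; procedure required = specific) algorithms are
#' ranked by higher total score, then lower total distance, then lower
#' `min_months`; the top-ranked one is selected. Deterministic and
#' invariant to input order.
#'
#' @param estimates `data.table` of aggregate ("general"-stratum) estimates
#'   with CIs, one row per algorithm x index year, carrying
#'   `algorithm_label`, and either `min_months`/`require_procedure` columns
#'   or labels parseable as `<family>-m<k>`.
#' @param benchmarks `data.table` of general-stratum benchmark values.
#' @return a `data.table` (class `selection_result`) with one row per
#'   algorithm: `algorithm_label`, `family`, `min_months`, `score`,
#'   `distance`, `selected`.
#' @export
select_algorithms <- function(estimates, benchmarks) {
  est <- data.table::as.data.table(estimates)
  if (nrow(est) == 0L) stop("no estimates supplied", call. = FALSE)
  benchmarks <- data.table::as.data.table(benchmarks)
  gen_bench <- benchmarks[benchmarks$stratum == "general"]
  if (nrow(gen_bench) == 0L) {
    stop("no general-stratum benchmarks supplied", call. = FALSE)
  }
  if (!"require_procedure" %in% names(est)) {
    est[, require_procedure := startsWith(algorithm_label, "specific")]
  }
  if (!"min_months" %in% names(est)) {
    est[, min_months := as.integer(sub("^.*-m([0-9]+)$", "\\1",
                                       algorithm_label))]
  }

  scored <- est[, {
    s <- consistency_score(.SD, gen_bench)
    list(score = s$score, distance = s$distance)
  }, by = .(algorithm_label, require_procedure, min_months, index_year)]

  totals <- scored[, .(score = sum(score), distance = sum(distance)),
                   by = .(algorithm_label, require_procedure, min_months)]
  totals[, family := data.table::fifelse(require_procedure, "specific",
                                         "sensitive")]
  for (fam in c("sensitive", "specific")) {
    if (!any(totals$family == fam)) {
      stop(sprintf("no algorithm in the %s family", fam), call. = FALSE)
    }
  }
  data.table::setorder(totals, family, -score, distance, min_months)
  totals[, selected := seq_len(.N) == 1L, by = family]
  data.table::setorder(totals, min_months, require_procedure)
  out <- totals[, .(algorithm_label, family, min_months, score, distance,
                    selected)]
  data.table::setattr(out, "class", c("selection_result", class(out)))
  out[]
}

#' The selected pair from a selection result
#' @param selection output of [select_algorithms()].
#' @return named list with elements `sensitive` and `specific`
#'   (algorithm labels).
#' @export
selected_pair <- function(selection) {
  sel <- selection[selection$selected == TRUE, ]
  list(sensitive = sel$algorithm_label[sel$family == "sensitive"],
       specific = sel$algorithm_label[sel$family == "specific"])
}
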