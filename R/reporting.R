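# Rendering benchmark-comparison tables and orchestrating the pipeline
# end-to-end: simulate/read -> identify (grid) -> estimate (+CIs) ->
# select -> report.

benchmark_key <- function(sex, age_group, region) {
  # benchmark tables ignore regime: their key is the varying field only
  parts <- c(sex = sex, age_group = age_group, region = region)
  parts <- parts[parts != "all"]
  if (length(parts) == 0L) return("general")
  paste(sprintf("%s=%s", names(parts), parts), collapse = ",")
}

format_cell <- function(rate, lo, hi) {
  if (is.na(rate)) return("N")
  if (is.na(lo) || is.na(hi)) return(sprintf("%.2f", rate))
  sprintf("%.2f (%.2f; %.2f)", rate, lo, hi)
}

#' Render a benchmark-comparison prevalence table
#'
#' Produces a table shaped like a published comparison table: one row per
#' stratum (general prevalence, then sex, age-group and — when present —
#' region strata), one `"rate (ci_low; ci_high)"` cell per (index year,
#' family) with two decimals, and one benchmark column per source. Missing
#' cells and benchmarks are rendered `"N"` (no information).
#'
#' @param estimates `data.table` of estimates with CIs (one regime's rows).
#' @param benchmarks `data.table` of benchmark values (may be empty).
#' @param family_pair named list with `sensitive` and `specific` algorithm
#'   labels, e.g. the output of [selected_pair()].
#' @param index_years years to place as column blocks; defaults to the
#'   years present in `estimates`.
#' @return a `data.frame` of character cells, with a `stratum` column.
#' @export
render_prevalence_table <- function(estimates, benchmarks = NULL,
                                    family_pair, index_years = NULL) {
  est <- data.table::as.data.table(estimates)
  if (nrow(est) == 0L) stop("no estimates to render", call. = FALSE)
  if (is.null(index_years)) index_years <- sort(unique(est$index_year))
  est <- est[est$algorithm_label %in% unlist(family_pair), ]

  rows <- unique(est[, .(sex, age_group, region)])
  ord <- with(rows, order(sex != "all" | age_group != "all" | region != "all",
                          sex == "all", sex,
                          age_group == "all", age_group,
                          region == "all", region))
  rows <- rows[ord]

  sources <- if (!is.null(benchmarks) && nrow(benchmarks) > 0L) {
    unique(benchmarks$source)
  } else character(0)

  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i]
    key <- benchmark_key(r$sex, r$age_group, r$region)
    label <- if (key == "general") "General prevalence" else
      sub("^[a-z_]+=", "", key)
    cells <- list(stratum = label)
    for (yr in index_years) {
      for (fam in c("sensitive", "specific")) {
        hit <- est[est$algorithm_label == family_pair[[fam]] &
                     est$index_year == yr & est$sex == r$sex &
                     est$age_group == r$age_group & est$region == r$region, ]
        cells[[sprintf("%s_%d", fam, yr)]] <-
          if (nrow(hit) == 1L) {
            format_cell(hit$rate_per_100k, hit$ci_low, hit$ci_high)
          } else "N"
      }
    }
    for (src in sources) {
      b <- benchmarks[benchmarks$source == src & benchmarks$stratum == key, ]
      cells[[src]] <- if (nrow(b) >= 1L) {
        sprintf("%.4g", b$rate_per_100k[1])
      } else "N"
    }
    data.table::as.data.table(cells)
  })
  as.data.frame(data.table::rbindlist(out))
}

default_pipeline_config <- function() {
  list(
    simulate = list(n_persons = 50000L),
    index_years = 2017:2019,
    grid = list(min_months = 1:8, require_procedure = c(FALSE, TRUE)),
    strata = c("general", "sex=male", "sex=female",
               "age_group=20-44", "age_group=45-64", "age_group=65+"),
    n_boot = 200L,
    seed = 20230310L,
    benchmarks = system.file("extdata", "benchmarks_table1.csv",
                             package = "phenoprev"))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate/read, applies the whole algorithm grid over each index
#' year, estimates the aggregate and requested strata with bootstrap CIs,
#' selects the sensitive/specific pair against the benchmarks, and writes
#' `estimates.csv`, `selection.csv`, `report.csv` and `manifest.json` to
#' `out_dir`. Rerunning with the same configuration reproduces all numbers.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `simulate` (arguments to [simulation_params()]) or `inputs` (paths
#'   `enrollment`, `claims`), `index_years`, `grid` (`min_months`,
#'   `require_procedure`), `strata` (character stratum labels),
#'   `benchmarks` (path, optional), `n_boot`, `seed`.
#' @param out_dir output directory; created if absent.
#' @return invisibly, a list with `estimates`, `selection`, `report`,
#'   `benchmarks` and the resolved `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("phenoprev_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]]) && nm != "simulate") config[[nm]] <- defaults[[nm]]
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  index_years <- as.integer(config$index_years)
  seed <- as.integer(config$seed)

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$inputs)) {
    enr <- read_enrollment(config$inputs$enrollment)
    clm <- read_claims(config$inputs$claims)
    enrollment <- enr$records
    claims <- clm$records
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$index_years <- index_years
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    params <- do.call(simulation_params, sim_args)
    sim <- simulate_claims_data(params)
    enrollment <- sim$enrollment
    claims <- sim$claims
    data.table::fwrite(enrollment, file.path(out_dir, "enrollment.csv"))
    write_claims(claims, file.path(out_dir, "claims.csv"))
    data.table::fwrite(sim$truth, file.path(out_dir, "truth.csv"))
  } else {
    stop("pipeline config needs either `inputs` or `simulate`", call. = FALSE)
  }

  benchmarks <- NULL
  if (!is.null(config$benchmarks) && nzchar(config$benchmarks) &&
      file.exists(config$benchmarks)) {
    benchmarks <- read_benchmarks(config$benchmarks)
  }

  # --- stage: identify + estimate over the grid ---------------------------
  grid <- enumerate_algorithm_grid(
    min_months = as.integer(config$grid$min_months),
    require_procedure = as.logical(config$grid$require_procedure))
  strata <- lapply(as.character(config$strata), parse_stratum)
  has_general <- any(vapply(strata, function(s) format(s) == "general",
                            logical(1)))
  if (!has_general) strata <- c(list(stratum_key()), strata)

  est_pieces <- list()
  for (spec in grid) {
    for (yr in index_years) {
      est_pieces[[length(est_pieces) + 1L]] <- tryCatch(
        bootstrap_ci(claims, enrollment, spec, yr, strata = strata,
                     B = as.integer(config$n_boot),
                     seed = seed + spec$min_months * 100L +
                       as.integer(spec$require_procedure) * 10L + yr %% 100L),
        error = function(e) stop(sprintf(
          "estimation stage failed for %s, year %d: %s", spec$label, yr,
          conditionMessage(e)), call. = FALSE))
    }
  }
  estimates <- data.table::rbindlist(est_pieces)
  mm <- vapply(grid, `[[`, integer(1), "min_months")
  rp <- vapply(grid, `[[`, logical(1), "require_procedure")
  lbl <- vapply(grid, `[[`, character(1), "label")
  estimates[, min_months := mm[match(algorithm_label, lbl)]]
  estimates[, require_procedure := rp[match(algorithm_label, lbl)]]
  write_estimates(estimates, file.path(out_dir, "estimates.csv"))

  # --- stage: select -------------------------------------------------------
  selection <- NULL
  if (!is.null(benchmarks)) {
    general <- estimates[estimates$stratum == "general", ]
    selection <- select_algorithms(general, benchmarks)
    data.table::fwrite(selection, file.path(out_dir, "selection.csv"))
  } else {
    warning("no benchmarks supplied; selection stage skipped", call. = FALSE)
  }

  # --- stage: report -------------------------------------------------------
  report <- NULL
  if (!is.null(selection)) {
    pair <- selected_pair(selection)
    report <- render_prevalence_table(estimates, benchmarks, pair,
                                      index_years)
    data.table::fwrite(report, file.path(out_dir, "report.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoprev")),
    r_version = R.version.string,
    seed = seed,
    config_hash = digest_config(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(estimates = estimates, selection = selection,
                 report = report, benchmarks = benchmarks, config = config,
                 out_dir = out_dir))
}

digest_config <- function(config) {
  # stable content hash without extra dependencies
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
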