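#' Declarative configuration for an end-to-end run
#'
#' Collects every tunable of the pipeline in one validated object: the
#' seed, grid, date axis, season definitions, candidate soil-moisture
#' threshold pairs, emission constants, air-quality category scheme, the
#' I/O-ratio source and the time-budget source. Unknown fields are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param seed Integer seed driving all synthetic randomness (mandatory
#'   for synthetic runs).
#' @param grid A [grid_spec()].
#' @param dates Date axis of the run.
#' @param periods Season definitions ([default_periods()]).
#' @param threshold_pairs List of `c(upper, lower)` soil-moisture pairs to
#'   sweep.
#' @param constants [emission_constants()].
#' @param scheme [category_scheme()].
#' @param io_ratio `"computed"` (pooled dry-season fire-derived median
#'   from the QC'd observations) or a fixed positive number.
#' @param budget `"questionnaire"` (two-stage mean of the pebble records)
#'   or a fixed `c(indoor_hours, outdoor_hours)` summing to 24.
#' @param truth Named list of [truth_params()] overrides for the synthetic
#'   scenario (the seed is supplied automatically).
#' @param background,kernel_width,conc_per_g Dispersion-toy settings.
#' @param n_respondents,total_population Questionnaire and population
#'   sizes.
#' @param cadence_min Sensor sampling cadence in minutes.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return A `peatsmoke_config` object.
#' @export
pipeline_config <- function(seed = 1L,
                            grid = grid_spec(),
                            dates = seq(as.Date("2023-08-16"),
                                        as.Date("2023-12-01"), by = "day"),
                            periods = default_periods(),
                            threshold_pairs = list(c(0.5, 0.25), c(0.5, 0.1),
                                                   c(0.45, 0.1), c(0.35, 0.1)),
                            constants = emission_constants(),
                            scheme = category_scheme(),
                            io_ratio = "computed",
                            budget = "questionnaire",
                            truth = list(),
                            background = 25, kernel_width = 2,
                            conc_per_g = 1.5e-6,
                            n_respondents = 60,
                            total_population = 2.8e6,
                            cadence_min = 2,
                            out_dir = NULL) {
  cfg <- structure(
    list(
      seed = seed, grid = grid, dates = sort(as.Date(dates)),
      periods = periods, threshold_pairs = threshold_pairs,
      constants = constants, scheme = scheme, io_ratio = io_ratio,
      budget = budget, truth = truth, background = background,
      kernel_width = kernel_width, conc_per_g = conc_per_g,
      n_respondents = n_respondents, total_population = total_population,
      cadence_min = cadence_min, out_dir = out_dir
    ),
    class = "peatsmoke_config"
  )
  cfg
}

#' Validate a pipeline configuration
#'
#' Lists every violated invariant; an empty report means the configuration
#' is runnable. [run_pipeline()] calls this before any computation.
#'
#' @param config A [pipeline_config()].
#' @return Tibble of violations: `field`, `message` (zero rows iff valid).
#' @export
validate_config <- function(config) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  if (!inherits(config, "peatsmoke_config")) {
    add("config", "not a peatsmoke_config object")
    return(dplyr::bind_rows(v))
  }
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed)))) {
    add("seed", "seed must be an integer")
  }
  if (!inherits(config$grid, "grid_spec")) add("grid", "not a grid_spec")
  if (length(config$dates) == 0) add("dates", "empty date axis")
  for (i in seq_along(config$threshold_pairs)) {
    tp <- config$threshold_pairs[[i]]
    ok <- length(tp) == 2 && tp[1] > tp[2] && tp[2] > 0
    if (!ok) {
      add(sprintf("threshold_pairs[%d]", i),
          "need upper > lower > 0 soil-moisture thresholds")
    }
  }
  if (length(config$threshold_pairs) == 0) {
    add("threshold_pairs", "at least one pair required")
  }
  if (!inherits(config$constants, "emission_constants")) {
    add("constants", "not an emission_constants object")
  } else if (any(config$constants$ef < 0)) {
    add("constants$ef", "negative emission factor")
  }
  if (is.numeric(config$io_ratio)) {
    if (config$io_ratio <= 0) add("io_ratio", "fixed I/O ratio must be > 0")
  } else if (!identical(config$io_ratio, "computed")) {
    add("io_ratio", "must be 'computed' or a positive number")
  }
  if (is.numeric(config$budget)) {
    if (length(config$budget) != 2 ||
        !isTRUE(all.equal(sum(config$budget), 24)) ||
        any(config$budget < 0)) {
      add("budget", "fixed budget must be two non-negative hours summing to 24")
    }
  } else if (!identical(config$budget, "questionnaire")) {
    add("budget", "must be 'questionnaire' or c(indoor, outdoor) hours")
  }
  if (!is.numeric(config$cadence_min) || config$cadence_min <= 0) {
    add("cadence_min", "cadence must be a positive number of minutes")
  }
  tryCatch(assign_period(config$dates[1], config$periods),
           error = function(e) add("periods", conditionMessage(e)))
  known_truth <- setdiff(names(formals(truth_params)), "seed")
  bad <- setdiff(names(config$truth), known_truth)
  if (length(bad)) {
    add("truth", paste("unknown truth override:", paste(bad, collapse = ", ")))
  }
  dplyr::bind_rows(v)
}

# Pooled dry-season fire-derived median I/O ratio from QC'd daily means.
.computed_io_ratio <- function(daily, periods) {
  fd <- fire_derived_daily(daily, periods) |>
    dplyr::mutate(pm25 = .data$pm25_fire) |>
    dplyr::select("site_id", "placement", "date", "pm25")
  io <- compute_io_ratio(fd, periods) |>
    dplyr::filter(.data$ratio > 0)
  period_median_ratio(io, "dry")
}

#' Run the full exposure-assessment pipeline on a synthetic scenario
#'
#' Executes the three-step workflow end to end: (1) generate the scenario
#' and QC the sensor records into RH-corrected daily means; (2) sweep the
#' candidate soil-moisture threshold pairs, disperse each emission
#' scenario into a modeled outdoor field and select the scenario that best
#' matches the observed outdoor daily means (lowest RMSE); (3) infer
#' indoor concentrations with the I/O ratio, weight by the time budget and
#' tally population per air-quality category, with and without fires.
#' Identical config + seed reproduces identical outputs.
#'
#' @param config A valid [pipeline_config()].
#' @return A `peatsmoke_run` list: the scenario, QC tables, sweep,
#'   evaluation, selected scenario, I/O ratio, time budget, daily
#'   exposure fields and tallies, plus a `manifest` recording the config
#'   hash, seed and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  report <- validate_config(config)
  if (nrow(report) > 0) {
    stop("invalid configuration:\n",
         paste0("  - ", report$field, ": ", report$message, collapse = "\n"),
         call. = FALSE)
  }

  truth <- do.call(truth_params, c(list(seed = config$seed), config$truth))
  scenario <- gen_scenario(
    truth, grid = config$grid, dates = config$dates,
    periods = config$periods, constants = config$constants,
    n_respondents = config$n_respondents,
    total_population = config$total_population,
    background = config$background, kernel_width = config$kernel_width,
    conc_per_g = config$conc_per_g, cadence_min = config$cadence_min
  )

  hourly <- qc_hourly(scenario$samples, cadence_min = config$cadence_min)
  daily <- qc_daily(hourly)

  pairs <- purrr::map(config$threshold_pairs,
                      ~ threshold_pair(.x[1], .x[2]))
  dry <- config$periods[config$periods$period == "dry", ]
  dry_period <- if (nrow(dry) == 1) c(dry$start, dry$end) else NULL
  sweep <- sweep_thresholds(pairs, scenario$hotspots, scenario$sm_field,
                            config$grid, config$constants,
                            period = dry_period)

  fields <- purrr::map(sweep$scenarios, function(sc) {
    gen_dispersion_fields(
      dplyr::filter(sc$field, .data$species == "PM25"),
      config$grid, config$dates, background = config$background,
      kernel_width = config$kernel_width, conc_per_g = config$conc_per_g
    )$with_fire
  })
  obs_outdoor <- dplyr::filter(daily, .data$placement == "outdoor")
  evaluation <- evaluate_scenarios(obs_outdoor, fields, scenario$sites,
                                   config$grid)
  best <- select_best_scenario(evaluation$pooled)

  io_ratio <- if (is.numeric(config$io_ratio)) config$io_ratio else
    .computed_io_ratio(daily, config$periods)
  budget <- if (is.numeric(config$budget)) {
    time_budget(config$budget[1], config$budget[2])
  } else {
    aggregate_time_budget(scenario$questionnaire)
  }

  with_out <- fields[[best]]
  without_out <- scenario$without_fire
  exposure_of <- function(outdoor_field) {
    indoor <- modeled_indoor(outdoor_field, io_ratio)
    dplyr::mutate(
      outdoor_field,
      value = time_weighted_exposure(indoor$value, outdoor_field$value, budget)
    )
  }
  exp_with <- exposure_of(with_out)
  exp_without <- exposure_of(without_out)
  tallies <- dplyr::bind_rows(
    dplyr::mutate(
      tally_population(exp_with, scenario$population, config$scheme),
      fires_scenario = "with"
    ),
    dplyr::mutate(
      tally_population(exp_without, scenario$population, config$scheme),
      fires_scenario = "without"
    )
  )

  manifest <- list(
    package = "peatsmoke",
    package_version = as.character(utils::packageVersion("peatsmoke")),
    seed = as.integer(config$seed),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_sites = truth$n_sites,
    n_days = length(config$dates),
    n_raw_samples = nrow(scenario$samples),
    n_hotspots = nrow(scenario$hotspots),
    qc_hours_flagged = sum(hourly$completeness_flag |
                             (!is.na(hourly$concordance_flag) &
                                hourly$concordance_flag)),
    best_scenario = best,
    io_ratio = io_ratio,
    budget_indoor_h = budget$t_indoor,
    budget_outdoor_h = budget$t_outdoor,
    outputs = character()
  )

  run <- structure(
    list(
      scenario = scenario, hourly = hourly, daily = daily, sweep = sweep,
      evaluation = evaluation, best_scenario = best, io_ratio = io_ratio,
      budget = budget, modeled_outdoor = with_out,
      modeled_outdoor_nofires = without_out, exposure_with = exp_with,
      exposure_without = exp_without, tallies = tallies,
      manifest = manifest, config = config
    ),
    class = "peatsmoke_run"
  )

  if (!is.null(config$out_dir)) {
    run$manifest$outputs <- write_run(run, config$out_dir)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(run$manifest, manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.peatsmoke_run <- function(x, ...) {
  cat("<peatsmoke_run>\n")
  cat("  best emission scenario:", x$best_scenario, "\n")
  cat(sprintf("  I/O ratio: %.3f; budget %.1f h indoor / %.1f h outdoor\n",
              x$io_ratio, x$budget$t_indoor, x$budget$t_outdoor))
  invisible(x)
}

# Write the run's tabular outputs; returns named relative paths.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- c(
    daily = "daily.csv", hourly = "hourly.csv",
    sweep = "sweep_summary.csv", metrics = "metrics.csv",
    tallies = "tallies.csv", sites = "sites.csv",
    hotspots = "hotspots.csv", questionnaire = "questionnaire.csv"
  )
  readr::write_csv(run$daily, file.path(dir, outputs["daily"]))
  readr::write_csv(run$hourly, file.path(dir, outputs["hourly"]))
  readr::write_csv(generics::tidy(run$sweep), file.path(dir, outputs["sweep"]))
  readr::write_csv(run$evaluation$pooled, file.path(dir, outputs["metrics"]))
  readr::write_csv(run$tallies, file.path(dir, outputs["tallies"]))
  readr::write_csv(run$scenario$sites, file.path(dir, outputs["sites"]))
  readr::write_csv(run$scenario$hotspots, file.path(dir, outputs["hotspots"]))
  readr::write_csv(run$scenario$questionnaire,
                   file.path(dir, outputs["questionnaire"]))
  truth <- run$scenario$truth
  truth$failure_date <- as.character(truth$failure_date)
  yaml::write_yaml(unclass(truth), file.path(dir, "truth.yaml"))
  c(outputs, truth = "truth.yaml")
}
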