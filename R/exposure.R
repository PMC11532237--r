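#' Daily indoor/outdoor concentration ratio per site
#'
#' The I/O ratio is the daily indoor mean divided by the daily outdoor mean
#' at the same site. Days with a missing or zero outdoor value are skipped
#' (the ratio is undefined, never infinite). Ratios above 1 point to indoor
#' sources; below 1, to the building attenuating outdoor smoke.
#'
#' @param daily Daily QC output ([qc_daily()]): `site_id`, `placement`,
#'   `date`, `pm25`.
#' @param periods Optional period table ([default_periods()]); when given,
#'   each day is labelled with its season.
#' @return Tibble: `site_id`, `date`, `indoor`, `outdoor`, `ratio`
#'   (and `period` when `periods` is supplied).
#' @export
compute_io_ratio <- function(daily, periods = NULL) {
  wide <- daily |>
    dplyr::select("site_id", "placement", "date", "pm25") |>
    tidyr::pivot_wider(names_from = "placement", values_from = "pm25")
  if (!all(c("indoor", "outdoor") %in% names(wide))) {
    stop("need both indoor and outdoor series", call. = FALSE)
  }
  out <- wide |>
    dplyr::filter(!is.na(.data$indoor), !is.na(.data$outdoor),
                  .data$outdoor != 0) |>
    dplyr::mutate(ratio = .data$indoor / .data$outdoor)
  if (nrow(out) == 0) stop("no overlapping indoor/outdoor days", call. = FALSE)
  if (!is.null(periods)) {
    out <- dplyr::mutate(out, period = assign_period(.data$date, periods))
  }
  dplyr::arrange(out, .data$site_id, .data$date)
}

#' Median I/O ratio over a period
#'
#' The standard sample median (midpoint of the two central values for even
#' counts), pooled over all sites by default or per site.
#'
#' @param io Output of [compute_io_ratio()] with a `period` column.
#' @param period Period label to summarise (e.g. `"dry"`).
#' @param by_site Summarise per site instead of pooling.
#' @return A single number, or a tibble (`site_id`, `median_ratio`) when
#'   `by_site = TRUE`.
#' @export
period_median_ratio <- function(io, period, by_site = FALSE) {
  x <- dplyr::filter(io, .data$period == !!period, !is.na(.data$ratio))
  if (nrow(x) == 0) stop("no ratios in period '", period, "'", call. = FALSE)
  if (by_site) {
    x |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(median_ratio = stats::median(.data$ratio),
                       .groups = "drop")
  } else {
    stats::median(x$ratio)
  }
}

#' Fire-derived concentration: subtract the wet-season baseline
#'
#' The fire-derived concentration on a day is that day's concentration
#' minus the same series' wet-season mean. Negative values are retained
#' (they indicate days cleaner than the baseline), not clipped.
#'
#' @param daily Daily QC output: `site_id`, `placement`, `date`, `pm25`.
#' @param periods Period table defining the wet season
#'   ([default_periods()]).
#' @return `daily` with columns `wet_mean` and `pm25_fire` added.
#' @export
fire_derived_daily <- function(daily, periods = default_periods()) {
  labelled <- dplyr::mutate(daily, period = assign_period(.data$date, periods))
  wet <- labelled |>
    dplyr::filter(.data$period == "wet", !is.na(.data$pm25)) |>
    dplyr::group_by(.data$site_id, .data$placement) |>
    dplyr::summarise(wet_mean = mean(.data$pm25), .groups = "drop")
  if (nrow(wet) == 0) stop("wet season empty: no baseline", call. = FALSE)
  labelled |>
    dplyr::left_join(wet, by = c("site_id", "placement")) |>
    dplyr::mutate(pm25_fire = .data$pm25 - .data$wet_mean)
}

#' Infer indoor concentrations from a modeled outdoor field
#'
#' Modeled indoor PM2.5 is the modeled outdoor field multiplied by the
#' (observation-derived) I/O ratio, cell by cell.
#'
#' @param field Tidy outdoor field with a `value` column (µg m^-3).
#' @param io_ratio Positive scalar I/O ratio.
#' @return The field with `value` scaled by `io_ratio`.
#' @export
modeled_indoor <- function(field, io_ratio) {
  if (!is.numeric(io_ratio) || length(io_ratio) != 1 || io_ratio <= 0) {
    stop("io_ratio must be a positive scalar", call. = FALSE)
  }
  dplyr::mutate(field, value = .data$value * io_ratio)
}

#' A 24-hour indoor/outdoor time budget
#'
#' @param t_indoor,t_outdoor Hours per day spent in each micro-environment;
#'   must sum to exactly 24.
#' @return A `time_budget` object.
#' @export
time_budget <- function(t_indoor, t_outdoor) {
  if (!isTRUE(all.equal(t_indoor + t_outdoor, 24)) ||
      t_indoor < 0 || t_outdoor < 0) {
    stop("time budget hours must be non-negative and sum to 24", call. = FALSE)
  }
  structure(list(t_indoor = t_indoor, t_outdoor = t_outdoor),
            class = "time_budget")
}

#' @export
print.time_budget <- function(x, ...) {
  cat(sprintf("<time_budget> indoor %.1f h / outdoor %.1f h\n",
              x$t_indoor, x$t_outdoor))
  invisible(x)
}

#' Mean daily time budget from pebble-allocation questionnaires
#'
#' Respondents allocate exactly 24 pebbles (hours) across home and up to
#' three livelihoods, splitting each venue's pebbles into indoor and
#' outdoor time. Aggregation is two-stage: the mean indoor hours per
#' location first, then the mean across locations, so locations with more
#' respondents do not dominate.
#'
#' @param records Questionnaire tibble: `respondent_id`, `location_id`,
#'   `venue`, `pebbles_indoor`, `pebbles_outdoor`.
#' @return A [time_budget()].
#' @export
aggregate_time_budget <- function(records) {
  per_resp <- records |>
    dplyr::group_by(.data$location_id, .data$respondent_id) |>
    dplyr::summarise(
      indoor = sum(.data$pebbles_indoor),
      total = sum(.data$pebbles_indoor + .data$pebbles_outdoor),
      .groups = "drop"
    )
  if (any(per_resp$total != 24)) {
    stop("each respondent must allocate exactly 24 pebbles", call. = FALSE)
  }
  per_loc <- per_resp |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(indoor = mean(.data$indoor), .groups = "drop")
  t_in <- mean(per_loc$indoor)
  time_budget(t_in, 24 - t_in)
}

#' Time-activity-weighted daily exposure
#'
#' Exposure is the time-weighted mean of the concentrations in the two
#' micro-environments:
#' \deqn{Exposure = \frac{c_{in} t_{in} + c_{out} t_{out}}{24}}
#' The result is a convex combination, so it always lies between the two
#' concentrations.
#'
#' @param conc_indoor,conc_outdoor Concentrations, µg m^-3 (vectorised).
#' @param budget A [time_budget()].
#' @return Exposure concentration, µg m^-3.
#' @examples
#' time_weighted_exposure(90, 100, time_budget(16.2, 7.8)) # 93.25
#' @export
time_weighted_exposure <- function(conc_indoor, conc_outdoor, budget) {
  stopifnot(inherits(budget, "time_budget"))
  (conc_indoor * budget$t_indoor + conc_outdoor * budget$t_outdoor) / 24
}

#' Air-quality category scheme for daily PM2.5
#'
#' Five ordered categories with inclusive upper bounds, following the US
#' EPA 24-hour PM2.5 breakpoints with the "unhealthy for sensitive groups"
#' band folded into moderate: good <= 12.0, moderate <= 55.4, unhealthy
#' <= 150.4, very unhealthy <= 250.4, dangerous above. A day counts as
#' "unhealthy or worse" only strictly above 55.4 µg m^-3.
#'
#' @param categories Character vector of category names, cleanest first.
#' @param upper Upper bounds (µg m^-3), strictly increasing; the last must
#'   be `Inf` so the scheme is exhaustive.
#' @return A `category_scheme` tibble.
#' @export
category_scheme <- function(
    categories = c("good", "moderate", "unhealthy", "very_unhealthy",
                   "dangerous"),
    upper = c(12.0, 55.4, 150.4, 250.4, Inf)) {
  if (length(categories) != length(upper)) {
    stop("categories and upper bounds must have equal length", call. = FALSE)
  }
  if (any(diff(upper) <= 0)) {
    stop("category bounds must be strictly increasing", call. = FALSE)
  }
  if (!is.infinite(upper[length(upper)])) {
    stop("last bound must be Inf so categories are exhaustive", call. = FALSE)
  }
  structure(
    tibble::tibble(category = categories, upper = upper),
    class = c("category_scheme", "tbl_df", "tbl", "data.frame")
  )
}

#' Classify concentrations into air-quality categories
#'
#' A concentration falls in the first category whose upper bound is greater
#' than or equal to it (bounds inclusive on the upper end), so 55.4 µg m^-3
#' is still moderate and 55.5 is unhealthy under the defaults.
#'
#' @param conc Daily concentrations, µg m^-3, non-negative (vectorised).
#' @param scheme A [category_scheme()].
#' @return Ordered factor of category labels.
#' @export
classify_category <- function(conc, scheme = category_scheme()) {
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  idx <- findInterval(conc, scheme$upper, left.open = TRUE) + 1L
  factor(scheme$category[idx], levels = scheme$category, ordered = TRUE)
}

#' Guideline exceedance flags
#'
#' Daily-mean exceedance of the WHO (15 µg m^-3) and Indonesian
#' (65 µg m^-3) 24-hour PM2.5 guidelines, independent of the category
#' scheme.
#'
#' @param conc Daily concentrations, µg m^-3.
#' @param who,indonesia Guideline values, µg m^-3.
#' @return Tibble of logicals `exceeds_who`, `exceeds_indonesia`.
#' @export
guideline_exceedance <- function(conc, who = 15, indonesia = 65) {
  tibble::tibble(exceeds_who = conc > who, exceeds_indonesia = conc > indonesia)
}

#' Tally population by air-quality category per day
#'
#' Classifies each cell-day of an exposure field and sums the population of
#' the cells in each category; categories partition the total population
#' every day.
#'
#' @param exposure_field Tidy field: `date`, `lat`, `lon`, `value`
#'   (µg m^-3).
#' @param population Tibble `lat`, `lon`, `population` on the same grid.
#' @param scheme A [category_scheme()].
#' @return Tibble: `date`, `category`, `persons` (all categories present
#'   each day, zero-filled).
#' @export
tally_population <- function(exposure_field, population,
                             scheme = category_scheme()) {
  joined <- dplyr::inner_join(exposure_field, population,
                              by = c("lat", "lon"))
  if (nrow(joined) != nrow(exposure_field)) {
    stop("grid mismatch between exposure field and population", call. = FALSE)
  }
  joined |>
    dplyr::mutate(category = classify_category(.data$value, scheme)) |>
    dplyr::group_by(.data$date, .data$category) |>
    dplyr::summarise(persons = sum(.data$population), .groups = "drop") |>
    tidyr::complete(
      date = unique(exposure_field$date),
      category = factor(scheme$category, levels = scheme$category,
                        ordered = TRUE),
      fill = list(persons = 0)
    ) |>
    dplyr::arrange(.data$date, .data$category)
}

#' Weekly mean of a daily field
#'
#' Averages a daily field to calendar weeks (weeks start on Monday; the
#' week's start date labels the result), for weekly-cadence exposure
#' tallies alongside the daily ones.
#'
#' @param field Tidy daily field: `date`, `lat`, `lon`, `value`.
#' @return Weekly field with `date` = week start.
#' @export
weekly_mean_field <- function(field) {
  field |>
    dplyr::mutate(
      date = .data$date - (as.integer(format(.data$date, "%u")) - 1L)
    ) |>
    dplyr::group_by(.data$date, .data$lat, .data$lon) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Fire contribution to modeled PM2.5
#'
#' The contribution of fires is the cellwise difference between the
#' with-fires and without-fires model fields.
#'
#' @param field_with,field_without Aligned tidy fields (`date`, `lat`,
#'   `lon`, `value`).
#' @return Field of differences (`value = with - without`).
#' @export
fire_contribution <- function(field_with, field_without) {
  joined <- dplyr::inner_join(
    field_with, field_without,
    by = c("date", "lat", "lon"), suffix = c("_with", "_without")
  )
  if (nrow(joined) != nrow(field_with) || nrow(joined) != nrow(field_without)) {
    stop("grid mismatch between with- and without-fires fields", call. = FALSE)
  }
  dplyr::transmute(
    joined,
    date = .data$date, lat = .data$lat, lon = .data$lon,
    value = .data$value_with - .data$value_without
  )
}
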