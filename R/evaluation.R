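# Drop incomplete pairs before computing any metric.
.paired <- function(model, obs, min_n = 1) {
  ok <- !is.na(model) & !is.na(obs)
  if (sum(ok) < min_n) stop("not enough paired values", call. = FALSE)
  list(m = model[ok], o = obs[ok])
}

#' Root mean square error
#'
#' @param model,obs Paired daily series, µg m^-3; incomplete pairs are
#'   dropped.
#' @return RMSE in µg m^-3.
#' @export
rmse <- function(model, obs) {
  p <- .paired(model, obs)
  sqrt(mean((p$m - p$o)^2))
}

#' Normalized mean bias factor
#'
#' A sign-symmetric bias statistic: when the model mean exceeds the
#' observed mean it equals `mean(m)/mean(o) - 1`; otherwise
#' `1 - mean(o)/mean(m)`. Swapping the arguments flips the sign exactly,
#' and the magnitude is the factor by which the larger mean exceeds the
#' smaller, minus one.
#'
#' @inheritParams rmse
#' @return Dimensionless bias factor.
#' @export
nmbf <- function(model, obs) {
  p <- .paired(model, obs)
  mm <- mean(p$m)
  mo <- mean(p$o)
  if (mm <= 0 || mo <= 0) stop("means must be positive", call. = FALSE)
  if (mm >= mo) mm / mo - 1 else 1 - mo / mm
}

#' Normalized mean absolute error factor
#'
#' The mean absolute error normalised by the smaller of the two series
#' totals: `sum(|m - o|) / sum(o)` when the model mean is at least the
#' observed mean, else `sum(|m - o|) / sum(m)`. Always at least `|nmbf|`.
#'
#' @inheritParams rmse
#' @return Dimensionless error factor, non-negative.
#' @export
nmaef <- function(model, obs) {
  p <- .paired(model, obs)
  mm <- mean(p$m)
  mo <- mean(p$o)
  if (mm <= 0 || mo <= 0) stop("means must be positive", call. = FALSE)
  sum(abs(p$m - p$o)) / if (mm >= mo) sum(p$o) else sum(p$m)
}

#' Pearson correlation between model and observations
#'
#' @inheritParams rmse
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(model, obs) {
  p <- .paired(model, obs, min_n = 2)
  if (stats::sd(p$m) == 0 || stats::sd(p$o) == 0) {
    stop("correlation undefined for constant series", call. = FALSE)
  }
  stats::cor(p$m, p$o)
}

#' All evaluation statistics for one model-observation pairing
#'
#' @inheritParams rmse
#' @return One-row tibble: `r`, `rmse`, `nmbf`, `nmaef`, `n`.
#' @export
metric_set <- function(model, obs) {
  p <- .paired(model, obs)
  tibble::tibble(
    r = pearson_r(model, obs),
    rmse = rmse(model, obs),
    nmbf = nmbf(model, obs),
    nmaef = nmaef(model, obs),
    n = length(p$m)
  )
}

#' Extract a gridded field at site locations
#'
#' Returns the daily series of the grid cell containing each site (nearest
#' cell centre; sites on a cell edge snap deterministically to the
#' lower-index cell). Sites outside the grid are an error.
#'
#' @param field Tidy field: `date`, `lat`, `lon`, `value`.
#' @param sites Tibble: `site_id`, `lat`, `lon`.
#' @param grid The [grid_spec()] the field lives on.
#' @return Tibble: `site_id`, `date`, `value`.
#' @export
extract_at_sites <- function(field, sites, grid) {
  cell <- snap_to_grid(grid, sites$lon, sites$lat)
  sites |>
    dplyr::mutate(lat = cell$lat, lon = cell$lon) |>
    dplyr::select("site_id", "lat", "lon") |>
    dplyr::inner_join(field, by = c("lat", "lon"),
                      relationship = "many-to-many") |>
    dplyr::select("site_id", "date", "value") |>
    dplyr::arrange(.data$site_id, .data$date)
}

#' Evaluate emission scenarios against observed daily PM2.5
#'
#' Pairs each scenario's modeled outdoor field, extracted at the site
#' locations, with QC'd observed outdoor daily means, then computes the
#' evaluation statistics. Pooled metrics (all sites stacked into one set
#' of daily pairs) are the default presentation; per-site metrics are also
#' carried.
#'
#' @param obs_daily Daily QC output restricted to outdoor placements:
#'   `site_id`, `date`, `pm25` (flagged days already `NA`).
#' @param scenario_fields Named list of modeled outdoor fields (`date`,
#'   `lat`, `lon`, `value`), one per emission scenario.
#' @param sites Site coordinates: `site_id`, `lat`, `lon`.
#' @param grid The shared [grid_spec()].
#' @return A `peat_eval` object; [tidy()] gives the pooled metric table,
#'   `$per_site` the per-site metrics, [glance()] the selected scenario.
#' @export
evaluate_scenarios <- function(obs_daily, scenario_fields, sites, grid) {
  stopifnot(length(scenario_fields) >= 1, !is.null(names(scenario_fields)))
  obs <- obs_daily |>
    dplyr::filter(!is.na(.data$pm25)) |>
    dplyr::select("site_id", "date", obs = "pm25")

  pairings <- purrr::imap(scenario_fields, function(field, nm) {
    extract_at_sites(field, sites, grid) |>
      dplyr::rename(model = "value") |>
      dplyr::inner_join(obs, by = c("site_id", "date"))
  })

  pooled <- purrr::imap_dfr(pairings, function(pr, nm) {
    dplyr::bind_cols(tibble::tibble(scenario = nm),
                     metric_set(pr$model, pr$obs))
  })
  per_site <- purrr::imap_dfr(pairings, function(pr, nm) {
    pr |>
      dplyr::group_by(.data$site_id) |>
      dplyr::group_modify(~ metric_set(.x$model, .x$obs)) |>
      dplyr::ungroup() |>
      dplyr::mutate(scenario = nm, .before = 1)
  })

  structure(
    list(pooled = pooled, per_site = per_site),
    class = "peat_eval"
  )
}

#' @export
print.peat_eval <- function(x, ...) {
  cat("<peat_eval> pooled daily metrics per scenario\n")
  print(x$pooled)
  cat("selected:", select_best_scenario(x$pooled), "\n")
  invisible(x)
}

#' Tidy pooled metrics of a scenario evaluation
#'
#' @param x A `peat_eval` from [evaluate_scenarios()].
#' @param ... Unused.
#' @export
tidy.peat_eval <- function(x, ...) x$pooled

#' @rdname tidy.peat_eval
#' @export
glance.peat_eval <- function(x, ...) {
  dplyr::filter(x$pooled, .data$scenario == select_best_scenario(x$pooled))
}

#' Select the best emission scenario from a metric table
#'
#' The scenario with the lowest RMSE wins; ties are broken by smallest
#' absolute NMBF, then smallest NMAEF, then scenario name, so the choice
#' does not depend on row order.
#'
#' @param metrics Tibble with columns `scenario`, `rmse`, `nmbf`, `nmaef`
#'   (e.g. `tidy()` of a `peat_eval`).
#' @return The selected scenario name.
#' @export
select_best_scenario <- function(metrics) {
  if (inherits(metrics, "peat_eval")) metrics <- metrics$pooled
  if (nrow(metrics) == 0) stop("empty metric table", call. = FALSE)
  ranked <- dplyr::arrange(
    metrics, .data$rmse, abs(.data$nmbf), .data$nmaef, .data$scenario
  )
  ranked$scenario[[1]]
}
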