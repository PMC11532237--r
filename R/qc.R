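#' Clip relative humidity to the correction's validity band
#'
#' The hygroscopic-growth correction over-corrects at extreme humidities, so
#' RH is restricted to 30--70% before use: values below 30 are set to 30 and
#' values above 70 are set to 70.
#'
#' @param rh_pct Relative humidity in percent, in \[0, 100\].
#' @return Clipped RH in \[30, 70\]. `NA` values propagate.
#' @export
clip_rh <- function(rh_pct) {
  bad <- !is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100)
  if (any(bad)) {
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  }
  pmin(pmax(rh_pct, 30), 70)
}

#' Correct raw optical PM2.5 for hygroscopic particle growth
#'
#' Low-cost optical sensors overestimate PM2.5 at high relative humidity
#' because hygroscopic particles swell and scatter more light. The RH-growth
#' correction divides the raw CF_1 mass concentration by a growth factor:
#'
#' \deqn{PM_{adj} = \frac{PM_{CF1}}{1 + \dfrac{0.24}{100/RH - 1}}}
#'
#' The correction never increases a reading and is monotone non-increasing
#' in RH for a fixed raw value. RH should already be clipped to \[30, 70\]
#' with [clip_rh()]; RH = 100 is rejected (growth factor diverges).
#'
#' @param pm25_cf1 Raw PM2.5 (CF_1 conversion), µg m^-3, non-negative.
#' @param rh_pct Relative humidity in percent, normally in \[30, 70\].
#' @return Adjusted PM2.5 in µg m^-3, never exceeding the input.
#' @examples
#' rh_growth_adjust(156, 70) # 100
#' @export
rh_growth_adjust <- function(pm25_cf1, rh_pct) {
  if (any(pm25_cf1 < 0, na.rm = TRUE)) {
    stop("pm25_cf1 must be non-negative", call. = FALSE)
  }
  if (any(rh_pct >= 100, na.rm = TRUE)) {
    stop("rh_pct must be < 100 (growth factor diverges)", call. = FALSE)
  }
  pm25_cf1 / (1 + 0.24 / (100 / rh_pct - 1))
}

#' Flag hours where the two optical channels disagree
#'
#' Each monitor carries two independent particle counters (channels A and
#' B). An hour is flagged as discordant when the absolute difference of the
#' hourly channel means exceeds 50% of their mean; equality at the boundary
#' passes. Hours where both channels are missing return `NA` (missing, a
#' state distinct from discordant).
#'
#' @param mean_a,mean_b Hourly mean PM2.5 of channels A and B, µg m^-3.
#' @return Logical: `TRUE` = discordant, `FALSE` = concordant, `NA` = not
#'   assessable (at least one channel missing).
#' @export
concordance_flag <- function(mean_a, mean_b) {
  ifelse(
    is.na(mean_a) | is.na(mean_b),
    NA,
    abs(mean_a - mean_b) > 0.5 * (mean_a + mean_b) / 2
  )
}

#' Combine the two channels of a monitor into a single series
#'
#' Default is the mean of channels A and B. When a channel is excluded for
#' a monitor (a known hardware failure), the other channel is used alone.
#' When neither is excluded but one is missing in a given step, the
#' remaining channel is passed through as a reduced-confidence fallback.
#'
#' @param a,b Aligned channel values (same timestamps), µg m^-3.
#' @param excluded_channel `NULL`, `"A"` or `"B"`.
#' @return Numeric vector of combined values.
#' @export
combine_channels <- function(a, b, excluded_channel = NULL) {
  if (!is.null(excluded_channel)) {
    excluded_channel <- match.arg(excluded_channel, c("A", "B"))
    return(if (excluded_channel == "A") b else a)
  }
  dplyr::case_when(
    is.na(a) & is.na(b) ~ NA_real_,
    is.na(a) ~ b,
    is.na(b) ~ a,
    .default = (a + b) / 2
  )
}

#' Mean over an aggregation window with a completeness rule
#'
#' A window mean (hourly over 2-minute samples, or daily over hourly means)
#' is only reported when strictly more than `min_frac` of the expected
#' values are available; otherwise the window is flagged and carries no
#' value. The same rule applies at both aggregation levels.
#'
#' @param x Values within one window (`NA` = missing).
#' @param expected_count Number of values a complete window would hold.
#' @param min_frac Completeness threshold (strict), default 0.75.
#' @return A one-row tibble: `mean` (NA when flagged), `n` available,
#'   `completeness_flag`.
#' @export
aggregate_mean <- function(x, expected_count, min_frac = 0.75) {
  if (expected_count <= 0) {
    stop("expected_count must be positive", call. = FALSE)
  }
  n <- sum(!is.na(x))
  ok <- n / expected_count > min_frac
  tibble::tibble(
    mean = if (ok) mean(x, na.rm = TRUE) else NA_real_,
    n = n,
    completeness_flag = !ok
  )
}

#' Default season definitions for the 2023 fire season
#'
#' Pre-dry season Aug 16--31, dry season Sep 1--Oct 31 (the fire period),
#' wet season Nov 1--Dec 1. Dates outside any interval are labelled
#' `"other"` by [assign_period()].
#'
#' @param year Calendar year the intervals fall in.
#' @return A tibble with columns `period`, `start`, `end` (inclusive).
#' @export
default_periods <- function(year = 2023) {
  tibble::tibble(
    period = c("pre_dry", "dry", "wet"),
    start = as.Date(sprintf(c("%d-08-16", "%d-09-01", "%d-11-01"), year)),
    end = as.Date(sprintf(c("%d-08-31", "%d-10-31", "%d-12-01"), year))
  )
}

#' Label dates with their season
#'
#' @param date A `Date` vector.
#' @param periods A tibble of disjoint inclusive intervals
#'   (`period`, `start`, `end`); defaults to [default_periods()].
#' @return Character vector of period labels; `"other"` outside all
#'   intervals.
#' @export
assign_period <- function(date, periods = default_periods()) {
  stopifnot(all(c("period", "start", "end") %in% names(periods)))
  if (any(periods$end < periods$start)) {
    stop("period end before start", call. = FALSE)
  }
  p <- dplyr::arrange(periods, .data$start)
  if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)])) {
    stop("period intervals overlap", call. = FALSE)
  }
  out <- rep("other", length(date))
  for (i in seq_len(nrow(p))) {
    hit <- !is.na(date) & date >= p$start[i] & date <= p$end[i]
    out[hit] <- p$period[i]
  }
  out[is.na(date)] <- NA_character_
  out
}

#' Hourly QC: RH correction, channel concordance and completeness
#'
#' Processes raw 2-minute dual-channel records into hourly mean PM2.5 per
#' monitor (site x placement). The order of operations is: clip RH to
#' 30--70%, apply the RH-growth correction to each 2-minute CF_1 reading,
#' average to hourly channel means (requiring > 75% of expected samples),
#' flag discordant hours (channel difference > 50% of the channel mean),
#' then combine channels. Discordant hours carry no value. Timestamps are
#' treated as UTC.
#'
#' @param raw Tibble of raw samples with columns `timestamp` (POSIXct, UTC),
#'   `site_id`, `placement` (`"indoor"`/`"outdoor"`), `channel`
#'   (`"A"`/`"B"`), `pm25_cf1`, `rh_pct`.
#' @param exclude_channel Optional tibble (`site_id`, `placement`,
#'   `channel`) of channels excluded monitor-wide for known failures; the
#'   other channel is then used alone.
#' @param cadence_min Sampling cadence in minutes (default 2, so 30
#'   samples per hour are expected).
#' @param min_frac Completeness threshold, strict (default 0.75).
#' @return Tibble: `site_id`, `placement`, `hour`, `pm25`, `n_samples`,
#'   `completeness_flag`, `concordance_flag`, `single_channel`.
#' @export
qc_hourly <- function(raw, exclude_channel = NULL, cadence_min = 2,
                      min_frac = 0.75) {
  needed <- c("timestamp", "site_id", "placement", "channel", "pm25_cf1", "rh_pct")
  stopifnot(all(needed %in% names(raw)))
  if (cadence_min <= 0) stop("cadence must be positive", call. = FALSE)
  if (any(raw$pm25_cf1 < 0, na.rm = TRUE)) {
    stop("negative raw pm25_cf1 rejected at ingest", call. = FALSE)
  }
  expected <- 60 / cadence_min

  adj <- raw |>
    dplyr::mutate(
      pm25_adj = rh_growth_adjust(.data$pm25_cf1, clip_rh(.data$rh_pct)),
      hour = floor_to_hour(.data$timestamp)
    )

  by_channel <- adj |>
    dplyr::group_by(.data$site_id, .data$placement, .data$channel, .data$hour) |>
    dplyr::summarise(
      n = sum(!is.na(.data$pm25_adj)),
      mean = mean(.data$pm25_adj, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(.data$n / expected > min_frac, .data$mean, NA_real_))

  wide <- by_channel |>
    tidyr::pivot_wider(
      names_from = "channel", values_from = c("mean", "n"),
      names_sep = "_", values_fill = list(n_A = 0L, n_B = 0L)
    )
  for (col in c("mean_A", "mean_B")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("n_A", "n_B")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
    wide[[col]][is.na(wide[[col]])] <- 0L
  }

  if (!is.null(exclude_channel)) {
    stopifnot(all(c("site_id", "placement", "channel") %in% names(exclude_channel)))
    excl <- dplyr::mutate(exclude_channel, .excluded = .data$channel) |>
      dplyr::select("site_id", "placement", ".excluded")
    wide <- dplyr::left_join(wide, excl, by = c("site_id", "placement"))
  } else {
    wide$.excluded <- NA_character_
  }

  wide |>
    dplyr::mutate(
      mean_A = ifelse(!is.na(.data$.excluded) & .data$.excluded == "A",
                      NA_real_, .data$mean_A),
      mean_B = ifelse(!is.na(.data$.excluded) & .data$.excluded == "B",
                      NA_real_, .data$mean_B),
      concordance_flag = ifelse(
        is.na(.data$.excluded),
        concordance_flag(.data$mean_A, .data$mean_B),
        FALSE
      ),
      pm25_raw = combine_channels(.data$mean_A, .data$mean_B),
      pm25 = ifelse(!is.na(.data$concordance_flag) & .data$concordance_flag,
                    NA_real_, .data$pm25_raw),
      n_samples = .data$n_A + .data$n_B,
      completeness_flag = is.na(.data$mean_A) & is.na(.data$mean_B),
      single_channel = xor(is.na(.data$mean_A), is.na(.data$mean_B)) &
        is.na(.data$.excluded)
    ) |>
    dplyr::select(
      "site_id", "placement", "hour", "pm25", "n_samples",
      "completeness_flag", "concordance_flag", "single_channel"
    ) |>
    dplyr::arrange(.data$site_id, .data$placement, .data$hour)
}

# Hour floor in UTC.
floor_to_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Daily QC means from hourly QC output
#'
#' A daily (UTC) mean is reported when strictly more than `min_frac` of the
#' 24 hours carry a usable value. Hours flagged for completeness or channel
#' discordance count as missing.
#'
#' @param hourly Output of [qc_hourly()].
#' @param min_frac Completeness threshold, strict (default 0.75).
#' @return Tibble: `site_id`, `placement`, `date`, `pm25`, `n_hours`,
#'   `completeness_flag`.
#' @export
qc_daily <- function(hourly, min_frac = 0.75) {
  hourly |>
    dplyr::mutate(date = as.Date(.data$hour, tz = "UTC")) |>
    dplyr::group_by(.data$site_id, .data$placement, .data$date) |>
    dplyr::summarise(
      n_hours = sum(!is.na(.data$pm25)),
      pm25 = mean(.data$pm25, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      completeness_flag = .data$n_hours / 24 <= min_frac,
      pm25 = ifelse(.data$completeness_flag, NA_real_, .data$pm25)
    ) |>
    dplyr::select(
      "site_id", "placement", "date", "pm25", "n_hours", "completeness_flag"
    )
}
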