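# Small shared fixtures built in code.

tiny_grid <- function() grid_spec(nlon = 4, nlat = 4)

# Raw 2-minute samples for one monitor-hour with controllable missingness
# and channel values; RH fixed at 50 unless given.
raw_hour <- function(site = "PA01", placement = "outdoor",
                     pm_a = 10, pm_b = 10, n = 30, rh = 50,
                     hour = as.POSIXct("2023-09-10 06:00:00", tz = "UTC")) {
  times <- hour + 120 * (seq_len(n) - 1)
  dplyr::bind_rows(
    tibble::tibble(timestamp = times, site_id = site, placement = placement,
                   channel = "A", pm25_cf1 = pm_a, rh_pct = rh, temp_c = 27),
    tibble::tibble(timestamp = times, site_id = site, placement = placement,
                   channel = "B", pm25_cf1 = pm_b, rh_pct = rh, temp_c = 27)
  )
}

# Deterministic flat field over a grid and dates.
flat_field <- function(grid, dates, value = 1) {
  tidyr::expand_grid(date = as.Date(dates), grid_cells(grid)) |>
    dplyr::mutate(value = value)
}

# Growth factor used when synthesising raw CF_1 readings by hand.
growth_factor <- function(rh) 1 + 0.24 / (100 / rh - 1)
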