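#' Ground-truth parameters for a synthetic scenario
#'
#' Holds every quantity the generator injects, so downstream stages can be
#' tested for recovery of known truth. Defaults emulate an El Niño fire
#' season: a regional smoke signal shared homogeneously across sites during
#' the dry season, site I/O ratios near 0.9, a ~40 µg m^-3 outdoor
#' background, and relative humidity mostly above 70%.
#'
#' @param seed Integer seed; all generator randomness derives from it via
#'   per-component sub-streams.
#' @param n_sites Number of monitoring sites.
#' @param true_io_ratio_per_site Injected indoor/outdoor ratio(s), > 0;
#'   a scalar is recycled across sites.
#' @param fire_signal_peak Peak of the shared dry-season fire signal,
#'   µg m^-3 (0 disables fires in the sensor series).
#' @param baseline_outdoor Non-fire outdoor concentration, µg m^-3.
#' @param indoor_source_amplitude Amplitude of episodic indoor source
#'   bursts (cooking, smoking), µg m^-3.
#' @param channel_noise_sd Independent per-channel noise, µg m^-3. The
#'   magnitude is not observationally constrained, so it is a parameter,
#'   not a constant.
#' @param failure_site Optional site id whose outdoor channel A drifts
#'   upward (a foreign-object failure) after `failure_date`.
#' @param failure_date Date the drift starts.
#' @param rh_mean,rh_sd Relative-humidity distribution, percent; the
#'   defaults put about 78% of draws above 70%.
#' @param mean_indoor_hours Population mean hours per day spent indoors,
#'   in \[0, 24\].
#' @return A `truth_params` object.
#' @export
truth_params <- function(seed = 1L,
                         n_sites = 5,
                         true_io_ratio_per_site = 0.9,
                         fire_signal_peak = 160,
                         baseline_outdoor = 40,
                         indoor_source_amplitude = 30,
                         channel_noise_sd = 5,
                         failure_site = NULL,
                         failure_date = as.Date("2023-09-26"),
                         rh_mean = 78,
                         rh_sd = 10.4,
                         mean_indoor_hours = 16.2) {
  ratios <- rep_len(true_io_ratio_per_site, n_sites)
  amps <- c(fire_signal_peak, baseline_outdoor, indoor_source_amplitude,
            channel_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(ratios <= 0)) stop("true I/O ratios must be > 0", call. = FALSE)
  if (mean_indoor_hours < 0 || mean_indoor_hours > 24) {
    stop("mean_indoor_hours must lie in [0, 24]", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_sites = as.integer(n_sites),
      true_io_ratio_per_site = ratios,
      fire_signal_peak = fire_signal_peak,
      baseline_outdoor = baseline_outdoor,
      indoor_source_amplitude = indoor_source_amplitude,
      channel_noise_sd = channel_noise_sd,
      failure_site = failure_site,
      failure_date = as.Date(failure_date),
      rh_mean = rh_mean, rh_sd = rh_sd,
      mean_indoor_hours = mean_indoor_hours
    ),
    class = "truth_params"
  )
}

# Independent sub-stream seeds so adding a component never perturbs the
# draws of another. Kept below 2^31 - 1.
.substream <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}

# Shared regional fire signal: a Gaussian hump inside the dry season,
# identical at all sites (smoke from regional peat fires mixes over the
# whole domain).
.fire_signal <- function(dates, peak, periods) {
  per <- assign_period(dates, periods)
  dry <- periods[periods$period == "dry", ]
  if (nrow(dry) == 0 || peak == 0) return(numeric(length(dates)))
  center <- as.numeric(dry$start) + 0.65 * (as.numeric(dry$end) - as.numeric(dry$start))
  width <- (as.numeric(dry$end) - as.numeric(dry$start)) / 4
  ifelse(per == "dry",
         peak * exp(-0.5 * ((as.numeric(dates) - center) / width)^2),
         0)
}

#' Generate a dual-channel low-cost sensor network
#'
#' Emulates a network of paired indoor/outdoor optical PM2.5 monitors at
#' 2-minute cadence. The outdoor series is baseline + a shared dry-season
#' fire signal + noise; the indoor series is the site's true I/O ratio
#' times the (noise-free) outdoor signal plus episodic indoor source
#' bursts. Channels A and B are independent noisy copies. Raw CF_1
#' readings include the hygroscopic-growth overread implied by the drawn
#' RH, so the QC correction recovers the underlying signal. If
#' `truth$failure_site` is set, that site's outdoor channel A drifts to
#' above 1000 µg m^-3 after the failure date.
#'
#' @param truth A [truth_params()].
#' @param dates Date vector (consecutive days) the network runs over;
#'   should span the pre-dry, dry and wet sub-periods.
#' @param cadence_min Sampling cadence in minutes (> 0).
#' @param periods Period table ([default_periods()]).
#' @param sites Optional site-metadata tibble (from [gen_scenario()]);
#'   generated when `NULL`.
#' @param grid Grid used to place sites when `sites` is `NULL`.
#' @return List with `samples` (raw record tibble: `timestamp`, `site_id`,
#'   `placement`, `channel`, `pm25_cf1`, `rh_pct`, `temp_c`) and `sites`
#'   (metadata: `site_id`, `lat`, `lon`, `location_class`, `building_type`,
#'   `smoker_present`).
#' @export
gen_sensor_network <- function(truth, dates, cadence_min = 2,
                               periods = default_periods(),
                               sites = NULL, grid = grid_spec()) {
  stopifnot(inherits(truth, "truth_params"))
  if (length(dates) == 0) stop("empty date range", call. = FALSE)
  if (cadence_min <= 0) stop("cadence must be positive", call. = FALSE)
  dates <- sort(as.Date(dates))
  if (is.null(sites)) sites <- .gen_sites(truth, grid)

  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(dates[length(dates)], "23:59:59"), tz = "UTC")
  times <- seq(t0, t1, by = cadence_min * 60)
  day <- as.Date(times, tz = "UTC")
  nt <- length(times)

  set.seed(.substream(truth$seed, 1L))
  fire <- .fire_signal(day, truth$fire_signal_peak, periods)
  growth <- function(rh) 1 + 0.24 / (100 / clip_rh(rh) - 1)

  samples <- purrr::map_dfr(seq_len(truth$n_sites), function(i) {
    sid <- sites$site_id[i]
    site_offset <- stats::rnorm(1, 0, 3)
    outdoor_true <- pmax(truth$baseline_outdoor + site_offset + fire, 1)

    # Episodic indoor bursts: some days get a 2-hour elevated window.
    burst <- numeric(nt)
    if (truth$indoor_source_amplitude > 0) {
      burst_day <- stats::runif(length(dates)) < 0.15
      start_hr <- sample(6:20, length(dates), replace = TRUE)
      hr <- as.numeric(format(times, "%H"))
      di <- match(day, dates)
      in_burst <- burst_day[di] & hr >= start_hr[di] & hr < start_hr[di] + 2
      burst[in_burst] <- truth$indoor_source_amplitude
    }
    indoor_true <- truth$true_io_ratio_per_site[i] * outdoor_true + burst

    purrr::map_dfr(c("indoor", "outdoor"), function(pl) {
      rh <- pmin(pmax(stats::rnorm(nt, truth$rh_mean, truth$rh_sd), 0), 100)
      temp <- stats::rnorm(nt, 27, 2)
      truth_pm <- if (pl == "indoor") indoor_true else outdoor_true
      purrr::map_dfr(c("A", "B"), function(ch) {
        pm <- pmax(truth_pm + stats::rnorm(nt, 0, truth$channel_noise_sd), 0)
        if (!is.null(truth$failure_site) && sid == truth$failure_site &&
            pl == "outdoor" && ch == "A") {
          days_since <- as.numeric(day - truth$failure_date)
          drift <- 1500 * pmin(pmax(days_since / 5, 0), 1)
          pm <- pm + drift
        }
        tibble::tibble(
          timestamp = times, site_id = sid, placement = pl, channel = ch,
          pm25_cf1 = pm * growth(rh), rh_pct = rh, temp_c = temp
        )
      })
    })
  })
  list(samples = samples, sites = sites)
}

.gen_sites <- function(truth, grid) {
  set.seed(.substream(truth$seed, 6L))
  n <- truth$n_sites
  classes <- rep(c("urban", "rural"), length.out = max(n - 1, 1))
  if (n > 1) classes <- c(classes[seq_len(n - 1)], "remote")
  tibble::tibble(
    site_id = sprintf("PA%02d", seq_len(n)),
    lat = stats::runif(n, grid$lat_bounds[1], grid$lat_bounds[2]),
    lon = stats::runif(n, grid$lon_bounds[1], grid$lon_bounds[2]),
    location_class = classes[seq_len(n)],
    building_type = ifelse(classes[seq_len(n)] == "urban", "concrete", "wooden"),
    smoker_present = seq_len(n) %% 2 == 0
  )
}

#' Generate a fire scene: hotspots, peat mask and soil moisture
#'
#' Daily-mean soil moisture declines monotonically from the start of the
#' record to the driest day (65% through the dry season), then recovers;
#' the spatial field is the daily curve plus a fixed cell offset. The
#' daily hotspot count is a deterministic, decreasing function of
#' domain-mean soil moisture, so the driest day carries the scenario
#' maximum and wet days carry none. Hotspot locations favour the peat
#' area (the southern half of the domain).
#'
#' @param seed Integer sub-stream seed.
#' @param grid A [grid_spec()].
#' @param dates Date vector for the scene.
#' @param periods Period table locating the dry season.
#' @param sm_max,sm_min Range of the domain-mean soil-moisture curve,
#'   m^3 m^-3.
#' @param max_daily_hotspots Count on the driest day.
#' @param peat_weight Probability a hotspot is drawn from the peat area.
#' @return List: `hotspots` (`date`, `lat`, `lon`, `on_peat`, `frp`),
#'   `peat_mask` (`lat`, `lon`, `on_peat`), `sm_field` (`date`, `lat`,
#'   `lon`, `sm`), `driest_date`.
#' @export
gen_fire_scene <- function(seed, grid, dates, periods = default_periods(),
                           sm_max = 0.45, sm_min = 0.08,
                           max_daily_hotspots = 40, peat_weight = 0.85) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dates) == 0) stop("empty date range", call. = FALSE)
  dates <- sort(as.Date(dates))
  set.seed(.substream(seed, 2L))

  dry <- periods[periods$period == "dry", ]
  t_num <- as.numeric(dates)
  driest <- if (nrow(dry) == 1) {
    as.numeric(dry$start) + round(0.65 * (as.numeric(dry$end) - as.numeric(dry$start)))
  } else {
    t_num[1] + round(0.65 * (t_num[length(t_num)] - t_num[1]))
  }
  recover_days <- 15

  curve <- vapply(t_num, function(t) {
    if (t <= driest) {
      frac <- (t - t_num[1]) / max(driest - t_num[1], 1)
      sm_min + (sm_max - sm_min) * cos(pi / 2 * frac)^2
    } else if (t <= driest + recover_days) {
      sm_min + (sm_max - sm_min) * (t - driest) / recover_days
    } else {
      sm_max
    }
  }, numeric(1))

  cells <- grid_cells(grid)
  peat_mask <- dplyr::mutate(cells, on_peat = .data$lat < mean(grid$lat_bounds))
  cell_offset <- stats::runif(nrow(cells), -0.02, 0.02)
  cell_offset <- cell_offset - mean(cell_offset)

  sm_field <- tidyr::expand_grid(date = dates, cells) |>
    dplyr::mutate(
      sm = curve[match(.data$date, dates)] +
        rep(cell_offset, times = length(dates))
    )

  n_day <- round(max_daily_hotspots * (sm_max - curve) / (sm_max - sm_min))
  n_day <- pmax(n_day, 0)

  peat_cells <- dplyr::filter(peat_mask, .data$on_peat)
  other_cells <- dplyr::filter(peat_mask, !.data$on_peat)
  hotspots <- purrr::map_dfr(seq_along(dates), function(di) {
    n <- n_day[di]
    if (n == 0) return(NULL)
    from_peat <- stats::runif(n) < peat_weight
    pick <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE), ]
    src <- dplyr::bind_rows(
      pick(peat_cells, sum(from_peat)),
      pick(other_cells, sum(!from_peat))
    )
    tibble::tibble(
      date = dates[di],
      lat = src$lat + stats::runif(n, -0.4, 0.4) * grid$res_lat,
      lon = src$lon + stats::runif(n, -0.4, 0.4) * grid$res_lon,
      on_peat = src$on_peat,
      frp = stats::rlnorm(n, log(30), 0.5)
    )
  })

  list(
    hotspots = hotspots, peat_mask = peat_mask, sm_field = sm_field,
    driest_date = as.Date(driest, origin = "1970-01-01")
  )
}

#' Toy dispersion: smooth emissions into with/without-fire PM2.5 fields
#'
#' A deliberately simple stand-in for a chemical-transport model: each
#' cell's daily emitted mass is spread over the domain with a truncated
#' Gaussian kernel whose per-source weights are normalised to sum to one,
#' so total mass is conserved exactly; the smoothed mass is converted to a
#' concentration enhancement and added to a uniform background. The
#' without-fires field is the background alone, so the difference field is
#' non-negative and linear in the emissions by construction.
#'
#' @param emission_field Gridded daily emissions
#'   ([grid_daily_emissions()]): `date`, `lat`, `lon`, `emission_g`.
#' @param grid A [grid_spec()].
#' @param dates Full date axis for the output fields (emission-free days
#'   get background only).
#' @param background Uniform background concentration, µg m^-3.
#' @param kernel_width Gaussian kernel scale in cells; 0 keeps mass in the
#'   source cell. Negative is an error.
#' @param conc_per_g Concentration enhancement per gram of smoothed daily
#'   mass in a cell, µg m^-3 g^-1.
#' @return List of tidy fields `with_fire`, `without_fire` (`date`, `lat`,
#'   `lon`, `value` in µg m^-3) and `smoothed_g` (smoothed mass, g).
#' @export
gen_dispersion_fields <- function(emission_field, grid, dates,
                                  background = 25, kernel_width = 2,
                                  conc_per_g = 1.5e-6) {
  stopifnot(inherits(grid, "grid_spec"))
  if (kernel_width < 0) stop("kernel_width must be >= 0", call. = FALSE)
  dates <- sort(as.Date(dates))
  cells <- grid_cells(grid)
  ncell <- nrow(cells)

  # Per-source-normalised Gaussian weights: column j spreads cell j's mass.
  ix <- match(cells$lon, grid$lon)
  iy <- match(cells$lat, grid$lat)
  if (kernel_width == 0) {
    w <- diag(ncell)
  } else {
    d2 <- outer(ix, ix, "-")^2 + outer(iy, iy, "-")^2
    w <- exp(-0.5 * d2 / kernel_width^2)
    w <- sweep(w, 2, colSums(w), "/")
  }

  base <- tidyr::expand_grid(date = dates, cells) |>
    dplyr::mutate(value = background)

  if (nrow(emission_field) == 0) {
    zero <- dplyr::mutate(base, value = 0)
    return(list(with_fire = base, without_fire = base, smoothed_g = zero))
  }

  smoothed <- emission_field |>
    dplyr::group_by(.data$date) |>
    dplyr::group_modify(function(df, key) {
      e <- numeric(ncell)
      idx <- match(paste(df$lat, df$lon), paste(cells$lat, cells$lon))
      e[idx] <- df$emission_g
      dplyr::mutate(cells, value = as.numeric(w %*% e))
    }) |>
    dplyr::ungroup()

  enh <- base |>
    dplyr::left_join(
      dplyr::mutate(smoothed, enh = .data$value * conc_per_g) |>
        dplyr::select("date", "lat", "lon", "enh"),
      by = c("date", "lat", "lon")
    ) |>
    dplyr::mutate(enh = tidyr::replace_na(.data$enh, 0))

  list(
    with_fire = dplyr::transmute(enh, date = .data$date, lat = .data$lat,
                                 lon = .data$lon,
                                 value = .data$value + .data$enh),
    without_fire = base,
    smoothed_g = smoothed
  )
}

#' Generate a population grid
#'
#' Non-negative cell populations summing exactly to the requested total.
#' By default cell weights are lognormal draws (a rough stand-in for the
#' strong clustering of real settlement patterns); explicit weights give
#' deterministic shares.
#'
#' @param seed Integer sub-stream seed.
#' @param grid A [grid_spec()].
#' @param total_population Total persons (> 0).
#' @param weights Optional non-negative per-cell weights (row order of
#'   [grid_cells()]); populations are proportional shares of the total.
#' @return Tibble: `lat`, `lon`, `population`.
#' @export
gen_population_grid <- function(seed, grid, total_population = 2.8e6,
                                weights = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (total_population <= 0) stop("total_population must be > 0", call. = FALSE)
  cells <- grid_cells(grid)
  if (is.null(weights)) {
    set.seed(.substream(seed, 4L))
    weights <- stats::rlnorm(nrow(cells), 0, 1)
  }
  stopifnot(length(weights) == nrow(cells), all(weights >= 0))
  dplyr::mutate(cells, population = total_population * weights / sum(weights))
}

#' Generate pebble-allocation time-budget questionnaires
#'
#' Each respondent distributes exactly 24 integer pebbles (hours) across
#' home and up to three livelihoods, then splits each venue's pebbles into
#' indoor and outdoor time. Each pebble is indoor with probability
#' `mean_indoor_hours / 24`, so the sample mean indoor time converges to
#' the target.
#'
#' @param seed Integer sub-stream seed.
#' @param n_respondents Number of respondents (> 0).
#' @param mean_indoor_hours Target mean indoor hours in \[0, 24\].
#' @param n_locations Number of villages respondents are spread over.
#' @return Tibble: `respondent_id`, `location_id`, `venue`,
#'   `pebbles_indoor`, `pebbles_outdoor`.
#' @export
gen_questionnaire <- function(seed, n_respondents,
                              mean_indoor_hours = 16.2, n_locations = 3) {
  if (n_respondents <= 0) stop("n_respondents must be > 0", call. = FALSE)
  if (mean_indoor_hours < 0 || mean_indoor_hours > 24) {
    stop("mean_indoor_hours must lie in [0, 24]", call. = FALSE)
  }
  set.seed(.substream(seed, 5L))
  p_in <- mean_indoor_hours / 24

  purrr::map_dfr(seq_len(n_respondents), function(r) {
    n_jobs <- sample(0:3, 1, prob = c(0.1, 0.4, 0.3, 0.2))
    venues <- c("home", if (n_jobs > 0) paste0("livelihood_", seq_len(n_jobs)))
    vw <- c(0.6, rep(0.4 / max(n_jobs, 1), n_jobs))
    pebble_venue <- sample(venues, 24, replace = TRUE, prob = vw)
    pebble_indoor <- stats::runif(24) < p_in
    counts <- table(factor(pebble_venue, levels = venues), pebble_indoor)
    tibble::tibble(
      respondent_id = sprintf("R%04d", r),
      location_id = sprintf("V%02d", (r - 1) %% n_locations + 1),
      venue = venues,
      pebbles_indoor = as.integer(if ("TRUE" %in% colnames(counts))
        counts[, "TRUE"] else rep(0L, length(venues))),
      pebbles_outdoor = as.integer(if ("FALSE" %in% colnames(counts))
        counts[, "FALSE"] else rep(0L, length(venues)))
    )
  })
}

#' Generate a complete synthetic scenario
#'
#' Assembles every input the pipeline consumes on one shared grid and date
#' axis, with the injected truth retained for recovery tests: the sensor
#' network, the fire scene (hotspots, peat mask, soil moisture), emissions
#' under a reference threshold pair dispersed into with/without-fire PM2.5
#' fields, a population grid and questionnaire records.
#'
#' @param truth A [truth_params()].
#' @param grid A [grid_spec()].
#' @param dates Date axis (default 16 Aug--1 Dec 2023, the fire-season
#'   deployment window).
#' @param periods Period table.
#' @param reference_thresholds [threshold_pair()] used for the scene's
#'   "true" emissions.
#' @param constants [emission_constants()].
#' @param n_respondents Questionnaire size.
#' @param total_population Persons on the grid.
#' @param background,kernel_width,conc_per_g Dispersion-toy settings, see
#'   [gen_dispersion_fields()].
#' @param cadence_min Sensor cadence, minutes.
#' @return A `peatsmoke_scenario` list: `samples`, `sites`, `hotspots`,
#'   `peat_mask`, `sm_field`, `emission_field`, `with_fire`,
#'   `without_fire`, `population`, `questionnaire`, `truth`, `grid`,
#'   `dates`, `periods`.
#' @export
gen_scenario <- function(truth = truth_params(),
                         grid = grid_spec(),
                         dates = seq(as.Date("2023-08-16"),
                                     as.Date("2023-12-01"), by = "day"),
                         periods = default_periods(),
                         reference_thresholds = threshold_pair(0.5, 0.1),
                         constants = emission_constants(),
                         n_respondents = 60,
                         total_population = 2.8e6,
                         background = 25, kernel_width = 2,
                         conc_per_g = 1.5e-6,
                         cadence_min = 2) {
  stopifnot(inherits(truth, "truth_params"))
  dates <- sort(as.Date(dates))

  sensors <- gen_sensor_network(truth, dates, cadence_min = cadence_min,
                                periods = periods, grid = grid)
  scene <- gen_fire_scene(truth$seed, grid, dates, periods = periods)
  records <- fire_emissions(scene$hotspots, scene$sm_field,
                            reference_thresholds, grid, constants)
  emission_field <- grid_daily_emissions(records, grid)
  disp <- gen_dispersion_fields(
    dplyr::filter(emission_field, .data$species == "PM25"),
    grid, dates, background = background,
    kernel_width = kernel_width, conc_per_g = conc_per_g
  )
  population <- gen_population_grid(truth$seed, grid, total_population)
  questionnaire <- gen_questionnaire(truth$seed, n_respondents,
                                     truth$mean_indoor_hours)

  structure(
    list(
      samples = sensors$samples, sites = sensors$sites,
      hotspots = scene$hotspots, peat_mask = scene$peat_mask,
      sm_field = scene$sm_field, driest_date = scene$driest_date,
      emission_field = emission_field,
      with_fire = disp$with_fire, without_fire = disp$without_fire,
      population = population, questionnaire = questionnaire,
      truth = truth, grid = grid, dates = dates, periods = periods,
      reference_thresholds = reference_thresholds
    ),
    class = "peatsmoke_scenario"
  )
}

#' @export
print.peatsmoke_scenario <- function(x, ...) {
  cat(sprintf(
    "<peatsmoke_scenario> %d sites, %d days, %d hotspots, seed %d\n",
    x$truth$n_sites, length(x$dates), nrow(x$hotspots), x$truth$seed
  ))
  invisible(x)
}
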