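short_dates <- seq(as.Date("2023-08-16"), as.Date("2023-09-20"), by = "day")

test_that("truth parameters validate their invariants", {
  expect_error(truth_params(true_io_ratio_per_site = 0), "> 0")
  expect_error(truth_params(channel_noise_sd = -1), ">= 0")
  expect_error(truth_params(mean_indoor_hours = 25), "\\[0, 24\\]")
  tr <- truth_params(n_sites = 3, true_io_ratio_per_site = c(0.8, 1.0, 1.2))
  expect_equal(tr$true_io_ratio_per_site, c(0.8, 1.0, 1.2))
})

test_that("without fires the dry-season outdoor mean stays at baseline", {
  tr <- truth_params(seed = 2, n_sites = 2, fire_signal_peak = 0,
                     indoor_source_amplitude = 0, baseline_outdoor = 40)
  net <- gen_sensor_network(tr, short_dates, cadence_min = 10)
  d <- qc_daily(qc_hourly(net$samples, cadence_min = 10))
  dry_out <- d |>
    dplyr::filter(placement == "outdoor",
                  assign_period(date) == "dry", !is.na(pm25))
  # site offsets have sd 3, so site means sit within a few ug/m3 of baseline
  expect_equal(mean(dry_out$pm25), 40, tolerance = 0.2)
  expect_error(gen_sensor_network(tr, as.Date(character())), "empty date")
  expect_error(gen_sensor_network(tr, short_dates, cadence_min = 0),
               "positive")
})

test_that("QC plus I/O stages recover the injected ratio within 0.05", {
  tr <- truth_params(seed = 1, n_sites = 3, true_io_ratio_per_site = 0.9,
                     indoor_source_amplitude = 0)
  dates <- seq(as.Date("2023-08-16"), as.Date("2023-10-31"), by = "day")
  net <- gen_sensor_network(tr, dates, cadence_min = 6)
  d <- qc_daily(qc_hourly(net$samples, cadence_min = 6))
  io <- compute_io_ratio(d, default_periods())
  expect_gte(nrow(io), 60 * 3 * 0.9)
  expect_equal(stats::median(io$ratio), 0.9, tolerance = 0.05)
})

test_that("an injected channel failure is concordance-flagged after onset", {
  tr <- truth_params(seed = 4, n_sites = 2, failure_site = "PA01",
                     failure_date = as.Date("2023-09-01"))
  net <- gen_sensor_network(tr, short_dates, cadence_min = 10)
  h <- qc_hourly(net$samples, cadence_min = 10)
  post <- h |>
    dplyr::filter(site_id == "PA01", placement == "outdoor",
                  as.Date(hour, tz = "UTC") >= as.Date("2023-09-07"))
  expect_gt(mean(post$concordance_flag, na.rm = TRUE), 0.5)
  # the unaffected site stays clean
  ok <- h |> dplyr::filter(site_id == "PA02")
  expect_lt(mean(ok$concordance_flag, na.rm = TRUE), 0.05)
})

test_that("generated RH sits mostly above 70% as during fire seasons", {
  tr <- truth_params(seed = 5, n_sites = 1)
  net <- gen_sensor_network(tr, short_dates, cadence_min = 10)
  expect_equal(mean(net$samples$rh_pct > 70), 0.78, tolerance = 0.03)
  expect_true(all(net$samples$rh_pct >= 0 & net$samples$rh_pct <= 100))
})

test_that("the fire scene couples hotspots to declining soil moisture", {
  g <- tiny_grid()
  dates <- seq(as.Date("2023-08-16"), as.Date("2023-12-01"), by = "day")
  scene <- gen_fire_scene(1, g, dates)

  sm_mean <- scene$sm_field |>
    dplyr::group_by(date) |>
    dplyr::summarise(sm = mean(sm), .groups = "drop")
  pre <- sm_mean$sm[sm_mean$date <= scene$driest_date]
  expect_true(all(diff(pre) < 1e-12))        # monotone decline into dry season
  post <- sm_mean$sm[sm_mean$date >= scene$driest_date]
  expect_true(all(diff(post) >= -1e-12))     # recovery afterwards

  counts <- table(factor(scene$hotspots$date, levels = as.character(dates)))
  expect_equal(unname(counts[as.character(scene$driest_date)]),
               max(counts))                  # driest day carries the maximum

  wet <- dates[assign_period(dates) == "wet"]
  expect_equal(sum(scene$hotspots$date %in% wet), 0)

  expect_true(all(scene$hotspots$lat >= g$lat_bounds[1] &
                    scene$hotspots$lat <= g$lat_bounds[2]))
  expect_true(all(scene$hotspots$lon >= g$lon_bounds[1] &
                    scene$hotspots$lon <= g$lon_bounds[2]))

  # on-peat flag matches the mask at the containing cell
  cell <- snap_to_grid(g, scene$hotspots$lon, scene$hotspots$lat)
  mask <- dplyr::left_join(cell, scene$peat_mask, by = c("lat", "lon"))
  expect_equal(scene$hotspots$on_peat, mask$on_peat)

  expect_error(gen_fire_scene(1, g, as.Date(character())), "empty date")
})

test_that("the dispersion toy conserves mass and is linear in emissions", {
  g <- tiny_grid()
  dates <- as.Date("2023-09-01") + 0:4
  set.seed(8)
  em <- flat_field(g, dates) |>
    dplyr::transmute(date, lat, lon,
                     emission_g = runif(dplyr::n(), 0, 1e9) *
                       rbinom(dplyr::n(), 1, 0.2))
  disp <- gen_dispersion_fields(em, g, dates)
  expect_equal(sum(disp$smoothed_g$value), sum(em$emission_g),
               tolerance = 1e-6)
  expect_true(all(disp$with_fire$value - disp$without_fire$value >= -1e-12))

  doubled <- gen_dispersion_fields(
    dplyr::mutate(em, emission_g = 2 * emission_g), g, dates
  )
  expect_equal(doubled$with_fire$value - doubled$without_fire$value,
               2 * (disp$with_fire$value - disp$without_fire$value),
               tolerance = 1e-9)

  none <- gen_dispersion_fields(em[0, ], g, dates)
  expect_equal(none$with_fire$value, none$without_fire$value)
  expect_error(gen_dispersion_fields(em, g, dates, kernel_width = -1), ">= 0")
})

test_that("population grids are non-negative and conserve the total", {
  g <- tiny_grid()
  pop <- gen_population_grid(3, g, total_population = 2670000)
  expect_true(all(pop$population >= 0))
  expect_equal(sum(pop$population), 2670000, tolerance = 1e-6)

  single <- gen_population_grid(3, grid_spec(nlon = 1, nlat = 1), 1000)
  expect_equal(single$population, 1000)

  two <- gen_population_grid(3, grid_spec(nlon = 2, nlat = 1), 1000,
                             weights = c(1, 1))
  expect_equal(two$population, c(500, 500))
  expect_error(gen_population_grid(3, g, 0), "> 0")
})

test_that("questionnaires allocate exactly 24 pebbles and hit the target mean", {
  q <- gen_questionnaire(11, n_respondents = 1000, mean_indoor_hours = 16.2)
  per <- q |>
    dplyr::group_by(respondent_id) |>
    dplyr::summarise(total = sum(pebbles_indoor + pebbles_outdoor),
                     indoor = sum(pebbles_indoor), .groups = "drop")
  expect_true(all(per$total == 24))
  expect_equal(mean(per$indoor), 16.2, tolerance = 0.2)
  expect_true(all(q$pebbles_indoor == floor(q$pebbles_indoor)))

  all_in <- gen_questionnaire(11, 20, mean_indoor_hours = 24)
  expect_true(all(all_in$pebbles_outdoor == 0))
  expect_error(gen_questionnaire(11, 0), "> 0")
})

test_that("identical seed and parameters reproduce a scenario bit-for-bit", {
  g <- tiny_grid()
  dates <- seq(as.Date("2023-08-20"), as.Date("2023-09-10"), by = "day")
  tr <- truth_params(seed = 42, n_sites = 2)
  s1 <- gen_scenario(tr, grid = g, dates = dates, n_respondents = 10,
                     cadence_min = 20)
  s2 <- gen_scenario(tr, grid = g, dates = dates, n_respondents = 10,
                     cadence_min = 20)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$hotspots, s2$hotspots)
  expect_identical(s1$sm_field, s2$sm_field)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$questionnaire, s2$questionnaire)

  s3 <- gen_scenario(truth_params(seed = 43, n_sites = 2), grid = g,
                     dates = dates, n_respondents = 10, cadence_min = 20)
  expect_false(identical(s1$samples$pm25_cf1, s3$samples$pm25_cf1))
})
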