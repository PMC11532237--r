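daily_for_io <- function(indoor, outdoor,
                         dates = as.Date("2023-09-01") + seq_along(indoor) - 1,
                         site = "PA01") {
  dplyr::bind_rows(
    tibble::tibble(site_id = site, placement = "indoor", date = dates,
                   pm25 = indoor),
    tibble::tibble(site_id = site, placement = "outdoor", date = dates,
                   pm25 = outdoor)
  )
}

test_that("daily I/O ratios divide indoor by outdoor and skip zero outdoor", {
  io <- compute_io_ratio(daily_for_io(c(50, 100, 30), c(100, 100, 0)))
  expect_equal(io$ratio, c(0.5, 1.0))   # zero-outdoor day skipped
  expect_equal(nrow(io), 2)
  expect_error(compute_io_ratio(daily_for_io(NA_real_, 10)), "overlapping")
})

test_that("period median ratio follows the midpoint convention", {
  io <- compute_io_ratio(
    daily_for_io(c(0.8, 1.0, 1.2) * 100, rep(100, 3)),
    periods = default_periods()
  )
  expect_equal(period_median_ratio(io, "dry"), 1.0)

  io2 <- compute_io_ratio(daily_for_io(c(80, 100), c(100, 100)),
                          periods = default_periods())
  expect_equal(period_median_ratio(io2, "dry"), 0.9)

  io3 <- compute_io_ratio(daily_for_io(90, 100), periods = default_periods())
  expect_equal(period_median_ratio(io3, "dry"), 0.9)
  expect_error(period_median_ratio(io3, "wet"), "no ratios")
})

test_that("fire-derived concentration subtracts the wet-season mean, unclipped", {
  dates <- c(as.Date("2023-09-15"), as.Date("2023-10-05"),
             as.Date("2023-11-10"), as.Date("2023-11-20"))
  daily <- tibble::tibble(
    site_id = "PA01", placement = "outdoor", date = dates,
    pm25 = c(136, 40, 44, 48)   # wet mean = 46
  )
  fd <- fire_derived_daily(daily)
  expect_equal(fd$wet_mean, rep(46, 4))
  expect_equal(fd$pm25_fire[1], 90)
  expect_equal(fd$pm25_fire[2], -6)  # negatives retained

  no_wet <- dplyr::filter(daily, date < as.Date("2023-11-01"))
  expect_error(fire_derived_daily(no_wet), "wet season empty")
})

test_that("modeled indoor concentrations scale the outdoor field by the ratio", {
  f <- flat_field(tiny_grid(), as.Date("2023-09-01"), value = 100)
  expect_equal(modeled_indoor(f, 0.9)$value, rep(90, 16))
  expect_equal(modeled_indoor(f, 1)$value, f$value)
  expect_equal(modeled_indoor(dplyr::mutate(f, value = 0), 0.9)$value,
               rep(0, 16))
  expect_error(modeled_indoor(f, -0.5), "positive")
})

test_that("time budgets aggregate two-stage and must sum to 24", {
  recs <- tibble::tibble(
    respondent_id = c("R1", "R2"),
    location_id = c("V1", "V2"),
    venue = "home",
    pebbles_indoor = c(12L, 20L),
    pebbles_outdoor = c(12L, 4L)
  )
  b <- aggregate_time_budget(recs)
  expect_equal(b$t_indoor, 16)
  expect_equal(b$t_outdoor, 8)

  one <- recs[1, ]
  one$pebbles_indoor <- 16L; one$pebbles_outdoor <- 8L
  expect_equal(aggregate_time_budget(one)$t_indoor, 16)

  all_in <- dplyr::mutate(recs, pebbles_indoor = 24L, pebbles_outdoor = 0L)
  expect_equal(aggregate_time_budget(all_in)$t_indoor, 24)

  bad <- dplyr::mutate(recs, pebbles_outdoor = 5L)
  expect_error(aggregate_time_budget(bad), "exactly 24")
  expect_error(time_budget(16, 9), "sum to 24")
})

test_that("time-weighted exposure is the convex combination of the two environments", {
  b <- time_budget(16.2, 7.8)
  expect_equal(time_weighted_exposure(90, 100, b), (90 * 16.2 + 100 * 7.8) / 24)
  expect_equal(time_weighted_exposure(90, 100, b), 93.25)
  expect_equal(time_weighted_exposure(57, 57, b), 57)
  expect_equal(time_weighted_exposure(90, 100, time_budget(24, 0)), 90)

  set.seed(5)
  ci <- runif(200, 0, 300); co <- runif(200, 0, 300)
  e <- time_weighted_exposure(ci, co, b)
  expect_true(all(e >= pmin(ci, co) - 1e-12 & e <= pmax(ci, co) + 1e-12))
})

test_that("air-quality categories use inclusive upper bounds", {
  expect_equal(as.character(classify_category(55.4)), "moderate")
  expect_equal(as.character(classify_category(55.5)), "unhealthy")
  expect_equal(as.character(classify_category(10)), "good")
  expect_equal(as.character(classify_category(12.0)), "good")
  expect_equal(
    as.character(classify_category(c(0, 150.4, 150.5, 250.4, 9999))),
    c("good", "unhealthy", "very_unhealthy", "very_unhealthy", "dangerous")
  )
  expect_error(classify_category(-1), "non-negative")
  expect_error(category_scheme(upper = c(10, 5, Inf),
                               categories = c("a", "b", "c")),
               "strictly increasing")
})

test_that("guideline exceedance flags are independent of the category scheme", {
  g <- guideline_exceedance(c(10, 20, 70))
  expect_equal(g$exceeds_who, c(FALSE, TRUE, TRUE))
  expect_equal(g$exceeds_indonesia, c(FALSE, FALSE, TRUE))
})

test_that("population tallies bin cells by category and partition the total", {
  g <- grid_spec(nlon = 2, nlat = 1)
  pop <- grid_cells(g) |> dplyr::mutate(population = c(1e6, 2e6))
  f <- grid_cells(g) |>
    dplyr::mutate(date = as.Date("2023-09-10"), value = c(10, 60))
  t1 <- tally_population(f, pop)
  expect_equal(t1$persons[t1$category == "good"], 1e6)
  expect_equal(t1$persons[t1$category == "unhealthy"], 2e6)
  expect_equal(sum(t1$persons), 3e6)

  zeroes <- dplyr::mutate(f, value = 0)
  t2 <- tally_population(zeroes, pop)
  expect_equal(t2$persons[t2$category == "good"], 3e6)

  # partition property on random fields, each day
  gg <- tiny_grid()
  set.seed(9)
  pop2 <- gen_population_grid(1, gg, total_population = 2.67e6)
  ff <- flat_field(gg, as.Date("2023-09-01") + 0:6) |>
    dplyr::mutate(value = runif(dplyr::n(), 0, 400))
  t3 <- tally_population(ff, pop2)
  per_day <- tapply(t3$persons, t3$date, sum)
  expect_true(all(abs(per_day - 2.67e6) < 1e-6))
})

test_that("raising the I/O ratio never moves a cell to a cleaner category", {
  gg <- tiny_grid()
  set.seed(13)
  out <- flat_field(gg, as.Date("2023-09-01")) |>
    dplyr::mutate(value = runif(dplyr::n(), 0, 300))
  b <- time_budget(16.2, 7.8)
  expo <- function(r) {
    indoor <- modeled_indoor(out, r)
    classify_category(time_weighted_exposure(indoor$value, out$value, b))
  }
  lo <- expo(0.7); hi <- expo(1.3)
  expect_true(all(as.integer(hi) >= as.integer(lo)))
})

test_that("fire contribution is the exact cellwise with-minus-without difference", {
  gg <- tiny_grid()
  w <- flat_field(gg, as.Date("2023-09-01"), value = 136)
  wo <- flat_field(gg, as.Date("2023-09-01"), value = 24)
  d <- fire_contribution(w, wo)
  expect_equal(d$value, rep(112, 16))
  expect_equal(fire_contribution(w, w)$value, rep(0, 16))
  # adding back is exact
  expect_equal(wo$value + d$value, w$value)
  expect_error(fire_contribution(w, wo[1:3, ]), "mismatch")
})

test_that("weekly means average the daily field within calendar weeks", {
  gg <- grid_spec(nlon = 1, nlat = 1)
  # Mon 2023-09-04 .. Sun 2023-09-10
  f <- flat_field(gg, as.Date("2023-09-04") + 0:6) |>
    dplyr::mutate(value = 1:7)
  w <- weekly_mean_field(f)
  expect_equal(nrow(w), 1)
  expect_equal(w$date, as.Date("2023-09-04"))
  expect_equal(w$value, 4)
})
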