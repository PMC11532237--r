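#' Soil-moisture thresholds for burn-depth scaling
#'
#' Peat burn depth is scaled between a minimum depth (assigned at or above
#' the upper soil-moisture threshold) and a maximum depth (at or below the
#' lower threshold), linear in between.
#'
#' @param upper_sm,lower_sm Soil-moisture thresholds in m^3 m^-3;
#'   `upper_sm > lower_sm > 0`.
#' @return A `threshold_pair` object.
#' @examples
#' threshold_pair(0.5, 0.1)
#' @export
threshold_pair <- function(upper_sm, lower_sm) {
  if (!(is.numeric(upper_sm) && is.numeric(lower_sm)) ||
      !(upper_sm > lower_sm && lower_sm > 0)) {
    stop("invalid thresholds: need upper_sm > lower_sm > 0", call. = FALSE)
  }
  structure(list(upper_sm = upper_sm, lower_sm = lower_sm),
            class = "threshold_pair")
}

#' @export
format.threshold_pair <- function(x, ...) {
  sprintf("%g/%g", x$upper_sm, x$lower_sm)
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat("<threshold_pair>", format(x), "m^3/m^3\n")
  invisible(x)
}

#' Constants of the per-fire emission model
#'
#' Defaults follow field-standard assumptions for Indonesian peatland:
#' a 40 ha burned area per below-ground peat fire detection (100 ha for
#' above-ground surface fires), burn depth between 5 and 37 cm, a peat
#' density of 0.11 g cm^-3, and a PM2.5 emission factor of 22.3 g per kg of
#' fuel burned. All are overridable.
#'
#' @param ba_peat,ba_surface Assumed burned area (ha) per peat / surface
#'   fire.
#' @param bd_min,bd_max Minimum and maximum peat burn depth (cm).
#' @param rho Fuel (peat) density, g cm^-3.
#' @param ef Named vector of emission factors, g per kg of fuel, one entry
#'   per species.
#' @return An `emission_constants` object.
#' @export
emission_constants <- function(ba_peat = 40, ba_surface = 100,
                               bd_min = 5, bd_max = 37,
                               rho = 0.11, ef = c(PM25 = 22.3)) {
  vals <- c(ba_peat = ba_peat, ba_surface = ba_surface, bd_min = bd_min,
            bd_max = bd_max, rho = rho)
  if (any(vals <= 0) || any(ef < 0)) {
    stop("emission constants must be positive (emission factors >= 0)",
         call. = FALSE)
  }
  if (bd_min >= bd_max) stop("bd_min must be < bd_max", call. = FALSE)
  if (is.null(names(ef)) || any(!nzchar(names(ef)))) {
    stop("ef must be a named vector of species emission factors", call. = FALSE)
  }
  structure(
    list(ba_peat = ba_peat, ba_surface = ba_surface, bd_min = bd_min,
         bd_max = bd_max, rho = rho, ef = ef),
    class = "emission_constants"
  )
}

#' Assumed burned area for a fire detection
#'
#' Each hotspot is assigned a fixed burned area by fire type: below-ground
#' peat fires burn a smaller area (default 40 ha) than above-ground surface
#' fires (default 100 ha).
#'
#' @param fire_type `"peat"` or `"surface"` (vectorised).
#' @param constants An [emission_constants()] object.
#' @return Burned area in hectares.
#' @export
assumed_burned_area <- function(fire_type, constants = emission_constants()) {
  if (any(!fire_type %in% c("peat", "surface"))) {
    stop("unknown fire_type: must be 'peat' or 'surface'", call. = FALSE)
  }
  ifelse(fire_type == "peat", constants$ba_peat, constants$ba_surface)
}

#' Burn depth from daily soil moisture
#'
#' When soil moisture is at or above the upper threshold the fire burns to
#' the minimum depth; at or below the lower threshold it burns to the
#' maximum depth; between the two, depth increases linearly as soil
#' moisture decreases:
#'
#' \deqn{BD = BD_{min} + \frac{sm_{up} - sm}{sm_{up} - sm_{lo}}
#'   (BD_{max} - BD_{min})}
#'
#' The function is continuous and non-increasing in soil moisture with
#' range exactly \[bd_min, bd_max\].
#'
#' @param sm Daily-mean volumetric soil moisture, m^3 m^-3 (vectorised).
#' @param thresholds A [threshold_pair()].
#' @param constants An [emission_constants()] object.
#' @return Burn depth in cm.
#' @examples
#' burn_depth(0.05, threshold_pair(0.5, 0.1)) # 37
#' burn_depth(0.9, threshold_pair(0.5, 0.1)) # 5
#' @export
burn_depth <- function(sm, thresholds, constants = emission_constants()) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (any(sm < 0, na.rm = TRUE)) {
    stop("soil moisture must be non-negative", call. = FALSE)
  }
  up <- thresholds$upper_sm
  lo <- thresholds$lower_sm
  frac <- (up - sm) / (up - lo)
  frac <- pmin(pmax(frac, 0), 1)
  constants$bd_min + frac * (constants$bd_max - constants$bd_min)
}

#' Per-fire emitted mass
#'
#' The emitted mass of a species for one fire is the product of burned
#' area, burn depth, fuel density and the species emission factor, with
#' unit conversions to grams: ha to m^2 (x 1e4), cm to m (/ 100) and
#' g cm^-3 to kg m^-3 (x 1000).
#'
#' @param ba_ha Burned area, ha.
#' @param bd_cm Burn depth, cm.
#' @param rho_g_cm3 Fuel density, g cm^-3.
#' @param ef_g_kg Emission factor, g kg^-1.
#' @return Emitted mass in grams.
#' @examples
#' emission_mass(40, 37, 0.11, 22.3) # 3.6304e8 g
#' @export
emission_mass <- function(ba_ha, bd_cm, rho_g_cm3, ef_g_kg) {
  (ba_ha * 1e4) * (bd_cm / 100) * (rho_g_cm3 * 1000) * ef_g_kg
}

#' Emissions for peat-fire hotspots given daily soil moisture
#'
#' Looks up daily soil moisture at each hotspot's containing grid cell
#' (nearest cell centre), converts it to burn depth, and computes emitted
#' mass per species. Only on-peat hotspots are modelled; surface-fire
#' emissions enter the pipeline, if at all, as a pass-through input field.
#'
#' @param hotspots Tibble with columns `date`, `lat`, `lon`, `on_peat`.
#' @param sm_field Tidy soil-moisture field: `date`, `lat`, `lon`, `sm`
#'   (daily means on the scenario grid).
#' @param thresholds A [threshold_pair()].
#' @param grid The shared [grid_spec()].
#' @param constants An [emission_constants()] object.
#' @param species Species to emit; must name entries of `constants$ef`.
#' @return Tibble of emission records: one row per hotspot x species, with
#'   `date`, `lat`, `lon`, `sm`, `burn_depth_cm`, `species`, `emission_g`.
#' @export
fire_emissions <- function(hotspots, sm_field, thresholds, grid,
                           constants = emission_constants(),
                           species = "PM25") {
  stopifnot(inherits(grid, "grid_spec"))
  missing_ef <- setdiff(species, names(constants$ef))
  if (length(missing_ef)) {
    stop("missing emission factor for species: ",
         paste(missing_ef, collapse = ", "), call. = FALSE)
  }
  peat <- dplyr::filter(hotspots, .data$on_peat)
  if (nrow(peat) == 0) {
    return(tibble::tibble(
      date = as.Date(character()), lat = numeric(), lon = numeric(),
      sm = numeric(), burn_depth_cm = numeric(),
      species = character(), emission_g = numeric()
    ))
  }
  cell <- snap_to_grid(grid, peat$lon, peat$lat)
  recs <- peat |>
    dplyr::mutate(cell_lat = cell$lat, cell_lon = cell$lon) |>
    dplyr::left_join(
      dplyr::rename(sm_field, cell_lat = "lat", cell_lon = "lon"),
      by = c("date", "cell_lat", "cell_lon")
    )
  if (any(is.na(recs$sm))) {
    stop("no soil-moisture value for some hotspot cell-days", call. = FALSE)
  }
  recs <- recs |>
    dplyr::mutate(
      burn_depth_cm = burn_depth(.data$sm, thresholds, constants),
      ba_ha = assumed_burned_area("peat", constants)
    )
  purrr::map_dfr(species, function(sp) {
    dplyr::transmute(
      recs,
      date = .data$date, lat = .data$lat, lon = .data$lon, sm = .data$sm,
      burn_depth_cm = .data$burn_depth_cm,
      species = sp,
      emission_g = emission_mass(.data$ba_ha, .data$burn_depth_cm,
                                 constants$rho, constants$ef[[sp]])
    )
  })
}

#' Grid emission records to daily cell totals
#'
#' Each record's mass is assigned wholly to its containing cell-day; the
#' gridded field conserves the record total exactly.
#'
#' @param records Output of [fire_emissions()] (or any tibble with `date`,
#'   `lat`, `lon`, `species`, `emission_g`).
#' @param grid The shared [grid_spec()].
#' @return Tidy field: `date`, `lat`, `lon`, `species`, `emission_g`
#'   (g day^-1 cell^-1), only non-zero cells.
#' @export
grid_daily_emissions <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(records) == 0) {
    return(tibble::tibble(
      date = as.Date(character()), lat = numeric(), lon = numeric(),
      species = character(), emission_g = numeric()
    ))
  }
  cell <- snap_to_grid(grid, records$lon, records$lat)
  records |>
    dplyr::mutate(lat = cell$lat, lon = cell$lon) |>
    dplyr::group_by(.data$date, .data$lat, .data$lon, .data$species) |>
    dplyr::summarise(emission_g = sum(.data$emission_g), .groups = "drop")
}

#' Total emissions over a period, in Tg
#'
#' @param field Gridded daily emissions from [grid_daily_emissions()].
#' @param period Optional `c(start, end)` dates (inclusive); default all.
#' @return Tibble `species`, `total_tg`.
#' @export
total_emissions <- function(field, period = NULL) {
  x <- field
  if (!is.null(period)) {
    period <- as.Date(period)
    x <- dplyr::filter(x, .data$date >= period[1], .data$date <= period[2])
    if (nrow(x) == 0) stop("empty period: no emissions in range", call. = FALSE)
  }
  x |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total_tg = sum(.data$emission_g) / 1e12, .groups = "drop")
}

#' Sweep soil-moisture threshold pairs
#'
#' Recomputes per-fire emissions under each candidate threshold pair and
#' summarises each resulting emission scenario: total PM2.5 (Tg) over the
#' period plus the mean and maximum burn depth over all peat-fire records
#' (hotspot-day weighted).
#'
#' @param pairs List of [threshold_pair()] objects.
#' @param hotspots,sm_field,grid,constants,species As in
#'   [fire_emissions()].
#' @param period Optional `c(start, end)` restricting the total.
#' @return A `peat_sweep` object; [tidy()] gives the per-scenario summary
#'   table, `$scenarios` holds records and gridded fields per pair.
#' @export
sweep_thresholds <- function(pairs, hotspots, sm_field, grid,
                             constants = emission_constants(),
                             species = "PM25", period = NULL) {
  if (length(pairs) < 1) stop("need at least one threshold pair", call. = FALSE)
  scenarios <- purrr::map(pairs, function(tp) {
    recs <- fire_emissions(hotspots, sm_field, tp, grid, constants, species)
    field <- grid_daily_emissions(recs, grid)
    tot <- if (nrow(field)) total_emissions(field, period) else
      tibble::tibble(species = species, total_tg = 0)
    list(
      thresholds = tp,
      records = recs,
      field = field,
      total_tg = tot,
      mean_bd = if (nrow(recs)) mean(recs$burn_depth_cm) else NA_real_,
      max_bd = if (nrow(recs)) max(recs$burn_depth_cm) else NA_real_
    )
  })
  names(scenarios) <- purrr::map_chr(pairs, format)
  structure(
    list(scenarios = scenarios, species = species, period = period),
    class = "peat_sweep"
  )
}

#' @export
print.peat_sweep <- function(x, ...) {
  cat("<peat_sweep>", length(x$scenarios), "emission scenarios\n")
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy summary of an emission-scenario sweep
#'
#' @param x A `peat_sweep` from [sweep_thresholds()].
#' @param ... Unused.
#' @return Tibble: `scenario`, `upper_sm`, `lower_sm`, one `total_tg_*`
#'   column per species, `mean_bd_cm`, `max_bd_cm`.
#' @export
tidy.peat_sweep <- function(x, ...) {
  purrr::imap_dfr(x$scenarios, function(sc, nm) {
    tot <- tidyr::pivot_wider(sc$total_tg, names_from = "species",
                              values_from = "total_tg",
                              names_prefix = "total_tg_")
    dplyr::bind_cols(
      tibble::tibble(
        scenario = nm,
        upper_sm = sc$thresholds$upper_sm,
        lower_sm = sc$thresholds$lower_sm
      ),
      tot,
      tibble::tibble(mean_bd_cm = sc$mean_bd, max_bd_cm = sc$max_bd)
    )
  })
}

#' @rdname tidy.peat_sweep
#' @export
glance.peat_sweep <- function(x, ...) {
  s <- generics::tidy(x)
  tot_col <- paste0("total_tg_", x$species[[1]])
  tibble::tibble(
    n_scenarios = nrow(s),
    min_total_tg = min(s[[tot_col]]),
    max_total_tg = max(s[[tot_col]])
  )
}
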