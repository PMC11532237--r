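#' Plot daily QC'd PM2.5 series by site and placement
#'
#' @param daily Output of [qc_daily()].
#' @param periods Optional period table; the dry season is shaded when
#'   given.
#' @return A ggplot object.
#' @export
plot_daily_series <- function(daily, periods = NULL) {
  p <- ggplot2::ggplot(
    dplyr::filter(daily, !is.na(.data$pm25)),
    ggplot2::aes(x = .data$date, y = .data$pm25, colour = .data$placement)
  )
  if (!is.null(periods)) {
    dry <- periods[periods$period == "dry", ]
    if (nrow(dry) == 1) {
      p <- p + ggplot2::annotate(
        "rect", xmin = dry$start, xmax = dry$end, ymin = -Inf, ymax = Inf,
        alpha = 0.12
      )
    }
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id)) +
    ggplot2::labs(x = NULL, y = expression(PM[2.5] ~ (mu * g ~ m^-3)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.peat_sweep Bar chart of total emissions and burn
#'   depths per threshold pair.
#' @param object A `peat_sweep`.
#' @export
autoplot.peat_sweep <- function(object, ...) {
  s <- generics::tidy(object)
  tot_col <- paste0("total_tg_", object$species[[1]])
  ggplot2::ggplot(s, ggplot2::aes(x = .data$scenario,
                                  y = .data[[tot_col]])) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.8) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("BD %.1f/%.1f cm", .data$mean_bd_cm,
                                   .data$max_bd_cm)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = "soil-moisture thresholds (upper/lower)",
                  y = "total emissions (Tg)") +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.peat_eval Scatter of RMSE against NMBF per scenario;
#'   the selected scenario is highlighted.
#' @param object A `peat_eval`.
#' @export
autoplot.peat_eval <- function(object, ...) {
  m <- object$pooled
  best <- select_best_scenario(m)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$nmbf, y = .data$rmse)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$scenario == best),
                        size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$scenario),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = "normalized mean bias factor",
                  y = expression(RMSE ~ (mu * g ~ m^-3))) +
    ggplot2::theme_minimal()
}

#' Stacked-area chart of population per air-quality category
#'
#' @param tallies Output of [tally_population()] (optionally with a
#'   `fires_scenario` column, faceted when present).
#' @return A ggplot object.
#' @export
plot_exposure_tally <- function(tallies) {
  p <- ggplot2::ggplot(
    tallies,
    ggplot2::aes(x = .data$date, y = .data$persons / 1e6,
                 fill = .data$category)
  ) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      good = "#8bc34a", moderate = "#ffeb3b", unhealthy = "#ff9800",
      very_unhealthy = "#e53935", dangerous = "#6a1b9a"
    )) +
    ggplot2::labs(x = NULL, y = "population (millions)", fill = NULL) +
    ggplot2::theme_minimal()
  if ("fires_scenario" %in% names(tallies)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$fires_scenario),
                                 ncol = 1)
  }
  p
}
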