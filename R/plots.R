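#' Plot a landscape's vegetation map
#'
#' @param object A `landscape_state`.
#' @param ... Unused.
#' @return A ggplot: tile map of vegetation classes.
#' @method autoplot landscape_state
#' @export
autoplot.landscape_state <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$veg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      rock_ice = "grey80", tundra = "#d9c97c", black_spruce = "#1b4332",
      white_spruce = "#52796f", deciduous = "#90be6d")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Vegetation", fill = NULL, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble's annual area burned
#'
#' One line per replicate with the across-run per-year median overlaid —
#' the series the representative run is selected against.
#'
#' @param object A `fire_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fire_ensemble
#' @export
autoplot.fire_ensemble <- function(object, ...) {
  df <- tidy(object)
  med <- df |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(area_burned_km2 = stats::median(.data$area_burned_km2),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year,
                                   y = .data$area_burned_km2)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$run), alpha = 0.3) +
    ggplot2::geom_line(data = med, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "Simulation year", y = "Area burned (km²)",
                  title = paste0("Annual area burned ('", object$scenario,
                                 "' scenario)"),
                  subtitle = "grey: replicates; red: per-year median") +
    ggplot2::theme_minimal()
}

#' Plot habitat time series with percentile envelopes
#'
#' Median winter-habitat area per year and range with the across-run
#' 5th-95th nearest-rank percentile ribbon.
#'
#' @param object A `habitat_summary`.
#' @param ... Unused.
#' @return A ggplot faceted by range.
#' @method autoplot habitat_summary
#' @export
autoplot.habitat_summary <- function(object, ...) {
  ggplot2::ggplot(object$envelope, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::facet_wrap(~range, scales = "free_y") +
    ggplot2::labs(x = "Simulation year", y = "Winter habitat (km²)",
                  title = "Lichen-producing winter habitat",
                  subtitle = "line: across-run median; ribbon: 5th-95th percentiles") +
    ggplot2::theme_minimal()
}

#' Plot a relative-flammability map
#'
#' @param object A `flammability_map_result`.
#' @param ... Unused.
#' @return A ggplot tile map.
#' @method autoplot flammability_map_result
#' @export
autoplot.flammability_map_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$flammability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Relative flammability ('",
                                 object$scenario, "')"),
                  fill = "proportion\nof run-years",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a warm/hot flammability difference map
#'
#' @param object A `flammability_difference`.
#' @param ... Unused.
#' @return A ggplot tile map on a diverging scale centred at 0.
#' @method autoplot flammability_difference
#' @export
autoplot.flammability_difference <- function(object, ...) {
  nr <- nrow(object$diff)
  nc <- ncol(object$diff)
  df <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    diff = as.vector(object$diff)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Relative-flammability difference",
                  fill = object$convention, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
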