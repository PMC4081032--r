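#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble into per-run-year fire summaries
#'
#' @param x A `fire_ensemble`.
#' @param ... Unused.
#' @return A tibble: `run`, `year`, `scenario`, `n_fires`,
#'   `area_burned_km2`.
#' @method tidy fire_ensemble
#' @export
tidy.fire_ensemble <- function(x, ...) {
  ab <- area_burned_matrix(x)
  counts <- x$fires |>
    dplyr::count(.data$run, .data$year, name = "n_fires")
  grid <- tidyr::expand_grid(run = seq_len(x$n_runs),
                             year = seq_len(x$n_years))
  grid |>
    dplyr::left_join(counts, by = c("run", "year")) |>
    dplyr::mutate(
      scenario = x$scenario,
      n_fires = dplyr::coalesce(.data$n_fires, 0L),
      area_burned_km2 = ab[cbind(.data$run, .data$year)]
    ) |>
    dplyr::relocate("scenario", .after = "year")
}

#' One-row ensemble summary
#'
#' @param x A `fire_ensemble`.
#' @param ... Unused.
#' @return A tibble with `scenario`, `n_runs`, `n_years`,
#'   `mean_annual_fires`, `mean_annual_area_km2`, `max_fire_km2`.
#' @method glance fire_ensemble
#' @export
glance.fire_ensemble <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n_runs = x$n_runs,
    n_years = x$n_years,
    mean_annual_fires = nrow(x$fires) / (x$n_runs * x$n_years),
    mean_annual_area_km2 = sum(x$fires$size_km2) / (x$n_runs * x$n_years),
    max_fire_km2 = if (nrow(x$fires) > 0) max(x$fires$size_km2) else 0
  )
}

#' Tidy a habitat summary
#'
#' @param x A `habitat_summary`.
#' @param ... Unused.
#' @return The per-run-year-range area tibble, with decade labels.
#' @method tidy habitat_summary
#' @export
tidy.habitat_summary <- function(x, ...) {
  dplyr::mutate(x$areas, decade = decade_label(.data$year))
}

#' One-row habitat summary
#'
#' @param x A `habitat_summary`.
#' @param ... Unused.
#' @return A tibble with one row per range: start/end median habitat and
#'   the percent change between them.
#' @method glance habitat_summary
#' @export
glance.habitat_summary <- function(x, ...) {
  x$envelope |>
    dplyr::group_by(.data$range) |>
    dplyr::summarise(
      start_km2 = .data$median[which.min(.data$year)],
      end_km2 = .data$median[which.max(.data$year)],
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_change = percent_change(.data$start_km2,
                                              .data$end_km2))
}

#' Tidy a representative-run result
#'
#' @param x A `representative_run_result`.
#' @param ... Unused.
#' @return A tibble with one row per run: `run`, `r`, `selected`.
#' @method tidy representative_run_result
#' @export
tidy.representative_run_result <- function(x, ...) {
  tibble::tibble(run = seq_along(x$all_r), r = x$all_r,
                 selected = seq_along(x$all_r) == x$run)
}

#' Tidy a relative-flammability map
#'
#' @param x A `flammability_map_result`.
#' @param ... Unused.
#' @return A tibble: `row`, `col`, `flammability`.
#' @method tidy flammability_map_result
#' @export
tidy.flammability_map_result <- function(x, ...) {
  nr <- nrow(x$map)
  nc <- ncol(x$map)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    flammability = as.vector(x$map)
  )
}
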