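#' Annual fire-regime statistics
#'
#' Computes, for every year of a historical fire record or of one ensemble
#' replicate, the number of fires, mean fire area (km^2) and total area
#' burned (km^2), optionally restricted to a herd-range mask and/or a
#' subset of vegetation classes.
#'
#' A fire counts toward a mask/class filter if at least one burned pixel
#' intersects it (perimeter databases attribute whole fires to regions);
#' its area under the filter is the intersected area, which keeps areas
#' additive across disjoint vegetation classes. For ensemble replicates the
#' vegetation a pixel burned in is the pre-fire class of that year.
#'
#' @param x A `fire_record` or `fire_ensemble`.
#' @param ... Passed to methods.
#' @return A tibble with columns `year`, `n_fires`, `mean_fire_area_km2`,
#'   `total_area_burned_km2`.
#' @export
regime_stats <- function(x, ...) UseMethod("regime_stats")

# shared core: `fires` is a list of integer cell-index vectors (linear
# indices into the grid), one per fire
regime_stats_core <- function(years, fires_per_year, keep, pixel_area) {
  purrr::map2_dfr(years, fires_per_year, function(yr, fires) {
    if (length(fires) > 0) {
      inter <- vapply(fires, function(cells) sum(keep[cells]), numeric(1))
      inter <- inter[inter > 0] * pixel_area
    } else {
      inter <- numeric(0)
    }
    tibble::tibble(
      year = yr,
      n_fires = length(inter),
      mean_fire_area_km2 = if (length(inter) > 0) mean(inter) else 0,
      total_area_burned_km2 = sum(inter)
    )
  })
}

keep_matrix <- function(template, mask, veg, class_filter) {
  keep <- matrix(TRUE, nrow(template), ncol(template))
  if (!is.null(mask)) {
    m <- if (inherits(mask, "range_mask")) mask$mask else mask
    if (!matrix_same_shape(m, template)) stop("mask shape mismatch")
    if (!any(m)) stop("empty mask")
    keep <- keep & m
  }
  if (!is.null(class_filter)) {
    if (is.null(veg)) stop("class_filter requires a vegetation grid")
    keep <- keep & matrix(veg %in% veg_code(class_filter),
                          nrow(template), ncol(template))
  }
  keep
}

#' @rdname regime_stats
#' @param mask Optional `range_mask` (or logical matrix).
#' @param landscape For `fire_record`: the `landscape_state` whose `veg`
#'   grid attributes burned pixels to classes (required with
#'   `class_filter`).
#' @param class_filter Optional character vector of vegetation class names.
#' @export
regime_stats.fire_record <- function(x, mask = NULL, landscape = NULL,
                                     class_filter = NULL, ...) {
  veg <- if (!is.null(landscape)) landscape$veg else NULL
  keep <- keep_matrix(x$burn_masks[[1]], mask, veg, class_filter)
  fires_per_year <- lapply(x$fire_labels, function(lab) {
    ids <- sort(unique(lab[lab > 0]))
    lapply(ids, function(id) which(lab == id))
  })
  regime_stats_core(x$years, fires_per_year, keep, x$pixel_area)
}

#' @rdname regime_stats
#' @param run For `fire_ensemble`: replicate index.
#' @export
regime_stats.fire_ensemble <- function(x, run = 1, mask = NULL,
                                       class_filter = NULL, ...) {
  stopifnot(run >= 1, run <= x$n_runs)
  nr <- dim(x$burn)[3]
  template <- matrix(FALSE, nr, dim(x$burn)[4])
  fires_run <- dplyr::filter(x$fires, .data$run == !!run)
  fires_per_year <- lapply(seq_len(x$n_years), function(y) {
    rows <- which(fires_run$year == y)
    lapply(rows, function(i) {
      cells <- fires_run$cells[[i]]
      (cells[, 2] - 1L) * nr + cells[, 1]
    })
  })
  if (is.null(class_filter)) {
    keep <- keep_matrix(template, mask, NULL, NULL)
    regime_stats_core(seq_len(x$n_years), fires_per_year, keep,
                      x$pixel_area)
  } else {
    # vegetation changes through time: evaluate the filter against each
    # year's pre-fire vegetation
    purrr::map_dfr(seq_len(x$n_years), function(y) {
      veg <- preburn_veg(x, run, y)
      keep <- keep_matrix(template, mask, veg, class_filter)
      regime_stats_core(y, fires_per_year[y], keep, x$pixel_area)
    })
  }
}

# vegetation grid immediately before the fires of (run, year)
preburn_veg <- function(ensemble, run, year) {
  if (year == 1) return(ensemble$start_states[[run]]$veg)
  idx <- match(year - 1, ensemble$snap_years)
  if (is.na(idx)) stop("no snapshot for year ", year - 1,
                       "; rerun with snapshot_every = 1")
  ensemble$snapshots[[run]][[idx]]$veg
}

#' Decadal fire-regime summary
#'
#' Collapses annual regime statistics to decadal means and sample SDs
#' (n - 1 denominator) of the three fire characteristics, mirroring the
#' usual "average (SD) by decade" reporting layout.
#'
#' @param stats A tibble from [regime_stats()] whose `year` column is the
#'   1-based simulation year.
#' @return A tibble with one row per decade: `decade`, then
#'   `n_fires_mean/sd`, `size_mean/sd`, `area_mean/sd`.
#' @export
decadal_regime_summary <- function(stats) {
  stats |>
    dplyr::mutate(decade = decade_label(.data$year)) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      n_fires_mean = mean(.data$n_fires),
      n_fires_sd = stats::sd(.data$n_fires),
      size_mean = mean(.data$mean_fire_area_km2),
      size_sd = stats::sd(.data$mean_fire_area_km2),
      area_mean = mean(.data$total_area_burned_km2),
      area_sd = stats::sd(.data$total_area_burned_km2),
      .groups = "drop"
    )
}

# period-level aggregates used by the calibration distance; size is the
# mean of per-year mean fire areas over fire years, so the three terms
# respond independently
regime_aggregates <- function(stats) {
  fire_years <- stats$n_fires > 0
  c(
    count_mean = mean(stats$n_fires),
    size_mean = if (any(fire_years)) {
      mean(stats$mean_fire_area_km2[fire_years])
    } else 0,
    area_mean = mean(stats$total_area_burned_km2)
  )
}

#' Calibration distance between simulated and historical fire regimes
#'
#' Normalized squared distance over three period aggregates — mean annual
#' fire count, overall mean fire size, and mean annual area burned — each
#' scaled by its historical value; zero iff all three match. Terms whose
#' historical value is zero fall back to the absolute difference.
#'
#' @param simulated,historical Tibbles from [regime_stats()] covering
#'   periods of equal length.
#' @return A scalar >= 0.
#' @examples
#' s <- tibble::tibble(year = 1:3, n_fires = c(2, 1, 3),
#'                     mean_fire_area_km2 = c(4, 2, 3),
#'                     total_area_burned_km2 = c(8, 2, 9))
#' calibration_distance(s, s)
#' @export
calibration_distance <- function(simulated, historical) {
  if (nrow(simulated) != nrow(historical)) {
    stop("simulated and historical periods must have equal length")
  }
  s <- regime_aggregates(simulated)
  h <- regime_aggregates(historical)
  terms <- ifelse(h != 0, ((s - h) / h)^2, abs(s - h))
  sum(terms)
}

#' Simulate a fire record under stationary climate
#'
#' Runs the annual model for `years` under a stationary climate sampler and
#' packages the resulting burns as a `fire_record` (per-year masks and fire
#' labels), the simulated counterpart of a historical burn-perimeter
#' database; used for calibration comparisons.
#'
#' @param initial A `landscape_state`.
#' @param climate_sampler As in [spin_up()].
#' @param params A [flammability_params()].
#' @param years Number of years.
#' @param succ A [succession_params()].
#' @param seed Integer seed.
#' @return A `fire_record`.
#' @export
simulate_fire_record <- function(initial, climate_sampler, params, years,
                                 succ = succession_params(), seed = 1L) {
  set.seed(as.integer(seed))
  state <- initial
  nr <- nrow(state$veg)
  nc <- ncol(state$veg)
  burn_masks <- vector("list", years)
  fire_labels <- vector("list", years)
  for (y in seq_len(years)) {
    clim <- climate_sampler(y, nr, nc)
    out <- step_year(state, clim, params, succ)
    lab <- matrix(0L, nr, nc)
    for (k in seq_along(out$fires)) lab[out$fires[[k]]$cells] <- k
    burn_masks[[y]] <- out$burn_mask
    fire_labels[[y]] <- lab
    state <- out$state
  }
  structure(
    list(years = seq_len(years), burn_masks = burn_masks,
         fire_labels = fire_labels, pixel_area = initial$pixel_area),
    class = "fire_record"
  )
}

#' Recover the flammability intercept by grid search
#'
#' The comparison-based calibration: for each candidate intercept `beta0`,
#' simulate `n_reps` stationary records with otherwise identical
#' parameters, average their [calibration_distance()] to the historical
#' record's statistics, and return the grid with the best candidate. A
#' diagnostic sweep, not a gradient auto-tuner.
#'
#' @param historical_stats Tibble from [regime_stats()] on the historical
#'   record.
#' @param initial A `landscape_state` (same domain as the history).
#' @param climate_sampler Stationary sampler, as in [spin_up()].
#' @param params Template [flammability_params()]; `beta0` is overridden.
#' @param beta0_grid Numeric vector of candidate intercepts.
#' @param years Years per simulated record (should match the historical
#'   period length).
#' @param n_reps Replicates per candidate (distances are averaged).
#' @param seed Integer master seed.
#' @param succ A [succession_params()].
#' @return A list: `grid` (tibble `beta0`, `distance`) and `best`
#'   (the arg-min `beta0`).
#' @export
calibrate_intercept <- function(historical_stats, initial, climate_sampler,
                                params, beta0_grid, years, n_reps = 2,
                                seed = 1L, succ = succession_params()) {
  seeds <- derive_seeds(seed, length(beta0_grid) * n_reps)
  dist <- vapply(seq_along(beta0_grid), function(i) {
    p <- params
    p$beta0 <- beta0_grid[i]
    mean(vapply(seq_len(n_reps), function(rep) {
      rec <- simulate_fire_record(initial, climate_sampler, p, years, succ,
                                  seed = seeds[(i - 1) * n_reps + rep])
      calibration_distance(regime_stats(rec), historical_stats)
    }, numeric(1)))
  }, numeric(1))
  grid <- tibble::tibble(beta0 = beta0_grid, distance = dist)
  list(grid = grid, best = beta0_grid[which.min(dist)])
}
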