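#' Winter-habitat configuration
#'
#' Lichen-producing winter habitat for caribou is defined as spruce or
#' tundra stands strictly older than the age threshold (forage-lichen
#' recovery generally takes more than 60 years after fire). The inequality
#' is strict, so a stand aged exactly at the threshold does not qualify;
#' both the threshold and the qualifying classes are configurable.
#'
#' @param age_threshold Years (default 60); must be > 0.
#' @param habitat_classes Character vector of qualifying classes (default
#'   tundra and both spruces).
#' @return An object of class `habitat_config`.
#' @examples
#' habitat_config()
#' @export
habitat_config <- function(age_threshold = 60,
                           habitat_classes = c("tundra", "black_spruce",
                                               "white_spruce")) {
  if (age_threshold <= 0) stop("age_threshold must be > 0")
  codes <- veg_code(habitat_classes)
  structure(
    list(age_threshold = age_threshold, habitat_classes = habitat_classes,
         habitat_codes = codes),
    class = "habitat_config"
  )
}

#' Classify winter habitat
#'
#' @param state A `landscape_state`, or a list with matrices `veg` and
#'   `age` (e.g. an ensemble snapshot).
#' @param config A [habitat_config()].
#' @return Logical matrix: `TRUE` where the class qualifies and
#'   `age > age_threshold`.
#' @examples
#' land <- generate_landscape(landscape_config(10, 10, seed = 1))
#' sum(classify_winter_habitat(land))
#' @export
classify_winter_habitat <- function(state, config = habitat_config()) {
  stopifnot(inherits(config, "habitat_config"))
  matrix(state$veg %in% config$habitat_codes &
           state$age > config$age_threshold,
         nrow(state$veg), ncol(state$veg))
}

#' Winter-habitat time series with percentile envelopes
#'
#' For every replicate, snapshot year and herd range, computes the area of
#' winter habitat split into its tundra and spruce components, then the
#' across-run 5th/95th nearest-rank percentile envelope (and median) of
#' total habitat per year and range.
#'
#' @param ensemble A `fire_ensemble` with snapshots.
#' @param masks List of `range_mask` objects (or a single one).
#' @param config A [habitat_config()].
#' @return An object of class `habitat_summary`: tibbles `areas`
#'   (run, year, range, tundra_km2, spruce_km2, total_km2) and `envelope`
#'   (year, range, q05, median, q95), plus `pixel_area`.
#' @export
habitat_timeseries <- function(ensemble, masks, config = habitat_config()) {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  if (inherits(masks, "range_mask")) masks <- list(masks)
  tundra_code <- veg_code("tundra")
  spruce_codes <- veg_code(c("black_spruce", "white_spruce"))
  pa <- ensemble$pixel_area

  areas <- purrr::map_dfr(seq_len(ensemble$n_runs), function(r) {
    purrr::map_dfr(seq_along(ensemble$snap_years), function(k) {
      snap <- ensemble$snapshots[[r]][[k]]
      hab <- classify_winter_habitat(snap, config)
      purrr::map_dfr(masks, function(mk) {
        inm <- hab & mk$mask
        tibble::tibble(
          run = r, year = ensemble$snap_years[k], range = mk$name,
          tundra_km2 = sum(inm & matrix(snap$veg %in% tundra_code,
                                        nrow(hab), ncol(hab))) * pa,
          spruce_km2 = sum(inm & matrix(snap$veg %in% spruce_codes,
                                        nrow(hab), ncol(hab))) * pa
        )
      })
    })
  })
  areas$total_km2 <- areas$tundra_km2 + areas$spruce_km2

  envelope <- areas |>
    dplyr::group_by(.data$year, .data$range) |>
    dplyr::summarise(
      q05 = nearest_rank_quantile(.data$total_km2, 0.05),
      median = nearest_rank_quantile(.data$total_km2, 0.5),
      q95 = nearest_rank_quantile(.data$total_km2, 0.95),
      .groups = "drop"
    )
  structure(
    list(areas = areas, envelope = envelope, pixel_area = pa),
    class = "habitat_summary"
  )
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat("<habitat_summary> ", dplyr::n_distinct(x$areas$run), " runs x ",
      dplyr::n_distinct(x$areas$year), " years x ",
      dplyr::n_distinct(x$areas$range), " range(s)\n", sep = "")
  invisible(x)
}

#' Select the representative replicate
#'
#' Correlates each replicate's annual area-burned series (Pearson r)
#' against the per-year across-run median series and returns the replicate
#' with the highest r (ties broken by the lowest run index). Replicates
#' with zero variance have undefined correlation and are skipped; if the
#' median series or every replicate is constant the correlation is
#' undefined and an error is signalled.
#'
#' @param x A `fire_ensemble` or a numeric matrix `(runs x years)` of
#'   annual area burned.
#' @return An object of class `representative_run_result`: `run` (index)
#'   and `r`, plus the per-run correlation vector `all_r`.
#' @examples
#' m <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 2, 3, 5))
#' representative_run(m)
#' @export
representative_run <- function(x) {
  m <- if (inherits(x, "fire_ensemble")) area_burned_matrix(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 runs")
  if (ncol(m) < 3) stop("need at least 3 years")
  med <- apply(m, 2, stats::median)
  if (stats::sd(med) == 0) stop("per-year median series is constant; correlation undefined")
  r_all <- apply(m, 1, function(row) {
    if (stats::sd(row) == 0) NA_real_ else stats::cor(row, med)
  })
  if (all(is.na(r_all))) stop("all runs constant; correlation undefined")
  best <- unname(which(r_all == max(r_all, na.rm = TRUE))[1])
  structure(
    list(run = best, r = unname(r_all[best]), all_r = unname(r_all)),
    class = "representative_run_result"
  )
}

#' @export
print.representative_run_result <- function(x, ...) {
  cat("<representative_run> run ", x$run, " (r = ",
      round(x$r, 3), ")\n", sep = "")
  invisible(x)
}

#' Relative flammability map
#'
#' The proportion of all run-years in which each pixel burned:
#' burned-run-year count divided by `n_runs * n_years`. Rock/ice pixels
#' never burn and are therefore 0.
#'
#' @param ensemble A `fire_ensemble`.
#' @return An object of class `flammability_map_result`: numeric matrix
#'   `map` in \[0, 1\] plus `n_runs`, `n_years`, `scenario`.
#' @export
relative_flammability <- function(ensemble) {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  counts <- apply(ensemble$burn, c(3, 4), sum)
  structure(
    list(map = counts / (ensemble$n_runs * ensemble$n_years),
         n_runs = ensemble$n_runs, n_years = ensemble$n_years,
         scenario = ensemble$scenario),
    class = "flammability_map_result"
  )
}

#' @export
print.flammability_map_result <- function(x, ...) {
  cat("<relative_flammability> scenario '", x$scenario, "' over ",
      x$n_runs, " runs x ", x$n_years, " years; max ",
      round(max(x$map), 4), "\n", sep = "")
  invisible(x)
}

#' Top-flammability mask
#'
#' Flags the most fire-prone share of the fuel domain: pixels at or above
#' the k-th largest relative-flammability value, where
#' `k = floor(fraction * n)` over the `n` fuel (non-rock/ice) pixels — the
#' nearest-rank analogue of the upper-`fraction` quantile. Ties at the
#' threshold are all included, so the mask can exceed `fraction` of the
#' domain (on an all-equal map it covers the whole fuel domain).
#'
#' @param flam_map A `flammability_map_result` (or plain numeric matrix).
#' @param fraction Target fraction in (0, 1); default 0.2 (the top 20%).
#' @param fuel_mask Optional logical matrix of fuel pixels over which the
#'   quantile is taken (default: all pixels; pass `veg != rock/ice` when a
#'   landscape is available).
#' @return Logical matrix, `TRUE` on the top-flammability pixels.
#' @export
top_flammability_mask <- function(flam_map, fraction = 0.2,
                                  fuel_mask = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- if (inherits(flam_map, "flammability_map_result")) flam_map$map else flam_map
  if (is.null(fuel_mask)) fuel_mask <- matrix(TRUE, nrow(m), ncol(m))
  vals <- m[fuel_mask]
  k <- max(1L, floor(fraction * length(vals)))
  thr <- sort(vals, decreasing = TRUE)[k]
  out <- fuel_mask & m >= thr
  matrix(out, nrow(m), ncol(m))
}

#' Percent of a herd range inside a mask
#'
#' @param mask Logical matrix (e.g. a top-flammability mask).
#' @param range A `range_mask` (or logical matrix) with at least one TRUE
#'   pixel.
#' @return Percent in \[0, 100\]: `100 * |mask & range| / |range|`.
#' @examples
#' rg <- matrix(TRUE, 2, 5)
#' range_overlap_percent(rbind(rep(TRUE, 5), rep(FALSE, 5)), rg)
#' @export
range_overlap_percent <- function(mask, range) {
  r <- if (inherits(range, "range_mask")) range$mask else range
  if (!matrix_same_shape(mask, r)) stop("shape mismatch")
  if (!any(r)) stop("empty range")
  100 * sum(mask & r) / sum(r)
}

#' Difference between two relative-flammability maps
#'
#' Computes `hot - warm` per pixel (positive values mark pixels that burn
#' more often under the hotter trajectory — the convention is explicit in
#' the result's `convention` field).
#'
#' @param warm,hot `flammability_map_result` objects (or matrices) of the
#'   same shape and provenance dimensions.
#' @return A list of class `flammability_difference`: matrix `diff`,
#'   `convention = "hot - warm"`.
#' @export
flammability_difference <- function(warm, hot) {
  wm <- if (inherits(warm, "flammability_map_result")) warm$map else warm
  hm <- if (inherits(hot, "flammability_map_result")) hot$map else hot
  if (!matrix_same_shape(wm, hm)) stop("shape mismatch")
  if (inherits(warm, "flammability_map_result") &&
      inherits(hot, "flammability_map_result") &&
      (warm$n_runs != hot$n_runs || warm$n_years != hot$n_years)) {
    stop("maps have different run-year provenance")
  }
  structure(list(diff = hm - wm, convention = "hot - warm"),
            class = "flammability_difference")
}

#' Percent change between two areas
#'
#' `100 * (area_end - area_start) / area_start`. The companion
#' [format_percent_change()] rounds to integer percent when the magnitude
#' is at least 1 and to one decimal below that, matching the usual
#' reporting style for habitat changes.
#'
#' @param area_start,area_end Areas in km^2; `area_start` must be > 0.
#' @return Signed percent (unrounded).
#' @examples
#' percent_change(41692, 37092)
#' format_percent_change(percent_change(41009, 41300))
#' @export
percent_change <- function(area_start, area_end) {
  if (any(area_start <= 0)) stop("area_start must be > 0")
  100 * (area_end - area_start) / area_start
}

#' @rdname percent_change
#' @param x Percent value(s) from [percent_change()].
#' @export
format_percent_change <- function(x) {
  ifelse(abs(x) >= 1, round(x), round(x, 1))
}

#' Habitat composition percentages
#'
#' Splits total winter habitat into its tundra and spruce shares for given
#' years, ranges and runs.
#'
#' @param summary A `habitat_summary`.
#' @param years Years to keep (default all).
#' @param ranges Range names to keep (default all).
#' @param runs Run indices to keep (default all; pass the representative
#'   run to mirror single-run reporting).
#' @return A tibble: run, year, range, `tundra_pct`, `spruce_pct` (of total
#'   habitat). Rows with zero habitat are dropped with a warning.
#' @export
composition_percent <- function(summary, years = NULL, ranges = NULL,
                                runs = NULL) {
  stopifnot(inherits(summary, "habitat_summary"))
  a <- summary$areas
  if (!is.null(years)) a <- dplyr::filter(a, .data$year %in% !!years)
  if (!is.null(ranges)) a <- dplyr::filter(a, .data$range %in% !!ranges)
  if (!is.null(runs)) a <- dplyr::filter(a, .data$run %in% !!runs)
  zero <- a$total_km2 == 0
  if (any(zero)) {
    warning(sum(zero), " run-year(s) with zero habitat dropped")
    a <- a[!zero, ]
  }
  if (nrow(a) == 0) stop("no habitat rows selected")
  dplyr::transmute(a, .data$run, .data$year, .data$range,
                   tundra_pct = 100 * .data$tundra_km2 / .data$total_km2,
                   spruce_pct = 100 * .data$spruce_km2 / .data$total_km2)
}
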