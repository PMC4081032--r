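#' Two-zone study landscape
#'
#' Builds the synthetic study domain for scenario contrasts: a northern
#' zone dominated by tundra (emulating an arctic winter range) stacked on a
#' southern zone dominated by spruce forest (a boreal winter range). Each
#' zone is generated with its own class proportions and the halves are
#' stitched into one landscape.
#'
#' @param n_rows,n_cols Domain size; the zone boundary is at
#'   `floor(n_rows / 2)`.
#' @param seed Integer seed.
#' @param north_props,south_props Named proportion vectors for the two
#'   zones (defaults: 80% tundra north; 60% spruce south).
#' @return A `landscape_state`.
#' @export
two_zone_landscape <- function(n_rows = 30, n_cols = 30, seed = 1L,
                               north_props = c(rock_ice = 0.03, tundra = 0.80,
                                               black_spruce = 0.08,
                                               white_spruce = 0.04,
                                               deciduous = 0.05),
                               south_props = c(rock_ice = 0.03, tundra = 0.15,
                                               black_spruce = 0.45,
                                               white_spruce = 0.15,
                                               deciduous = 0.22)) {
  n_top <- floor(n_rows / 2)
  seeds <- derive_seeds(seed, 2)
  north <- generate_landscape(landscape_config(
    n_top, n_cols, veg_proportions = north_props, seed = seeds[1]))
  south <- generate_landscape(landscape_config(
    n_rows - n_top, n_cols, veg_proportions = south_props, seed = seeds[2]))
  new_landscape_state(
    rbind(north$veg, south$veg), rbind(north$age, south$age),
    year = 0L, pixel_area = north$pixel_area,
    sched_target = rbind(north$sched_target, south$sched_target),
    sched_due = rbind(north$sched_due, south$sched_due)
  )
}

#' Paired warm/hot scenario experiment
#'
#' The package's headline experiment: on one two-zone landscape with a
#' tundra-dominated northern winter range and a spruce-dominated southern
#' one, run two replicate ensembles under a warm and a hot climate
#' trajectory that share the same seeds and noise and differ only in
#' warming trend, then summarize total area burned and the decadal habitat
#' change per range and scenario.
#'
#' Habitat change is the percent change from the first to the last decade
#' of the across-run median annual habitat series (decade means), the
#' decadal reporting convention used throughout the package.
#'
#' @param seed Integer seed for this pair (landscape, masks, climate noise
#'   and run streams all derive from it).
#' @param n_rows,n_cols Domain size (default 30 x 30).
#' @param n_years Projection horizon (default 90).
#' @param n_runs Replicates per ensemble (default 2).
#' @param spin_up_years Spin-up length per replicate (default 50).
#' @param params A [flammability_params()].
#' @param warm_trend,hot_trend Temperature trends in degrees C per decade
#'   (defaults 0.3 and 0.6).
#' @param range_fraction Fraction of the domain each range covers.
#' @param succ A [succession_params()].
#' @return A list: `summary` (tibble: scenario, range, habitat_start_km2,
#'   habitat_end_km2, pct_change), `area_burned` (tibble: scenario,
#'   total_km2), `ensembles` (list warm/hot), `masks`, `landscape`.
#' @export
paired_scenario_experiment <- function(seed, n_rows = 30, n_cols = 30,
                                       n_years = 90, n_runs = 2,
                                       spin_up_years = 50,
                                       params = flammability_params(),
                                       warm_trend = 0.3, hot_trend = 0.6,
                                       range_fraction = 0.2,
                                       succ = succession_params()) {
  seeds <- derive_seeds(seed, 4)
  land <- two_zone_landscape(n_rows, n_cols, seed = seeds[1])
  cfg <- landscape_config(n_rows, n_cols, seed = seeds[1])
  n_top <- floor(n_rows / 2)
  masks <- generate_range_masks(cfg, list(
    list(name = "tundra_range", target_fraction = range_fraction,
         anchor = c(max(1, n_top %/% 2), n_cols %/% 2)),
    list(name = "spruce_range", target_fraction = range_fraction,
         anchor = c(n_top + max(1, (n_rows - n_top) %/% 2), n_cols %/% 2))
  ), seed = seeds[2])

  pair <- generate_climate_pair(
    n_years, n_rows, n_cols,
    warm = climate_params("warm", t_trend = warm_trend, seed = seeds[3]),
    hot = climate_params("hot", t_trend = hot_trend, seed = seeds[3])
  )
  ensembles <- lapply(pair, function(cc) {
    run_ensemble(land, cc, params, n_runs = n_runs, seed = seeds[4],
                 succ = succ, spin_up_years = spin_up_years)
  })

  summary <- purrr::imap_dfr(ensembles, function(ens, scen) {
    hs <- habitat_timeseries(ens, masks)
    first_dec <- 1:10
    last_dec <- (n_years - 9):n_years
    hs$envelope |>
      dplyr::group_by(.data$range) |>
      dplyr::summarise(
        habitat_start_km2 = mean(.data$median[.data$year %in% first_dec]),
        habitat_end_km2 = mean(.data$median[.data$year %in% last_dec]),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        scenario = scen,
        pct_change = percent_change(.data$habitat_start_km2,
                                    .data$habitat_end_km2)
      ) |>
      dplyr::relocate("scenario")
  })
  area_burned <- purrr::imap_dfr(ensembles, function(ens, scen) {
    tibble::tibble(scenario = scen,
                   total_km2 = sum(area_burned_matrix(ens)))
  })
  list(summary = summary, area_burned = area_burned, ensembles = ensembles,
       masks = masks, landscape = land)
}

#' Directional contrast over many scenario pairs
#'
#' Repeats [paired_scenario_experiment()] over independent seeds and
#' reports, as fractions of pairs, the three directional findings the
#' warming contrast is expected to produce: the hot member burns more area,
#' the hot member's habitat change is more negative (in both ranges
#' combined), and the spruce-dominated range loses a larger fraction of
#' habitat than the tundra-dominated range under the hot member.
#'
#' @param n_pairs Number of independent pairs (>= 1).
#' @param seed Master seed.
#' @param ... Passed on to [paired_scenario_experiment()].
#' @return A list: `pairs` (tibble, one row per pair with the three
#'   indicator columns) and `majority` (named fractions in \[0, 1\]).
#' @export
directional_contrast <- function(n_pairs = 20, seed = 1L, ...) {
  seeds <- derive_seeds(seed, n_pairs)
  pairs <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    ex <- paired_scenario_experiment(seed = seeds[k], ...)
    s <- ex$summary
    ab <- ex$area_burned
    hot <- s[s$scenario == "hot", ]
    warm <- s[s$scenario == "warm", ]
    tibble::tibble(
      pair = k,
      burned_warm_km2 = ab$total_km2[ab$scenario == "warm"],
      burned_hot_km2 = ab$total_km2[ab$scenario == "hot"],
      hot_burns_more = burned_hot_km2 > burned_warm_km2,
      hot_change_pct = mean(hot$pct_change),
      warm_change_pct = mean(warm$pct_change),
      hot_more_negative = hot_change_pct <= warm_change_pct,
      spruce_loss_hot = -hot$pct_change[hot$range == "spruce_range"],
      tundra_loss_hot = -hot$pct_change[hot$range == "tundra_range"],
      spruce_loses_more = spruce_loss_hot > tundra_loss_hot
    )
  })
  majority <- c(
    hot_burns_more = mean(pairs$hot_burns_more),
    hot_more_negative = mean(pairs$hot_more_negative),
    spruce_loses_more = mean(pairs$spruce_loses_more)
  )
  list(pairs = pairs, majority = majority)
}
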