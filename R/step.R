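#' Advance the landscape one year
#'
#' One annual tick of the fire-succession model: compute the flammability
#' map, draw random ignitions, spread each fire in RNG-shuffled order over
#' cells not yet burned this year (an ignition landing on an already burned
#' cell is dropped), then apply post-fire transitions and aging.
#'
#' @param state A `landscape_state`.
#' @param climate_year List with matrices `tas` and `pr`.
#' @param params A [flammability_params()].
#' @param succ A [succession_params()].
#' @return List with elements `state` (advanced one year), `fires` (list of
#'   `fire_event`s) and `burn_mask` (logical matrix, the union of the
#'   fires' cells).
#' @examples
#' land <- generate_landscape(landscape_config(15, 15, seed = 2))
#' clim <- list(tas = matrix(13, 15, 15), pr = matrix(140, 15, 15))
#' set.seed(7)
#' out <- step_year(land, clim, flammability_params(), succession_params())
#' length(out$fires)
#' @export
step_year <- function(state, climate_year, params, succ = succession_params()) {
  flam <- flammability_map(state, climate_year, params)
  ignitions <- ignite(flam, params$max_ignitions)
  burn_mask <- matrix(FALSE, nrow(flam), ncol(flam))
  fires <- list()
  if (nrow(ignitions) > 0) {
    ord <- sample.int(nrow(ignitions))
    for (k in ord) {
      ig <- ignitions[k, ]
      if (burn_mask[ig[1], ig[2]]) next   # consumed by an earlier fire
      fe <- spread_fire(state, flam, ig, params, exclude = burn_mask)
      burn_mask[fe$cells] <- TRUE
      fires[[length(fires) + 1]] <- fe
    }
  }
  state2 <- apply_transitions(state, burn_mask, fires, succ)
  list(state = state2, fires = fires, burn_mask = burn_mask)
}

#' Spin up a landscape to a quasi-stationary fire regime
#'
#' Iterates [step_year()] under a stationary baseline climate sampler so
#' stand ages and vegetation composition equilibrate with the fire regime
#' before scenario projections start. `years = 0` returns the initial state
#' unchanged.
#'
#' @param initial A `landscape_state`.
#' @param climate_sampler A function `(year, n_rows, n_cols) ->
#'   list(tas, pr)`, e.g. [baseline_climate_sampler()].
#' @param params A [flammability_params()].
#' @param years Number of spin-up years (>= 0).
#' @param succ A [succession_params()].
#' @param seed Optional integer seed (set before iterating).
#' @return The final `landscape_state` (its `year` counter is reset to 0 so
#'   projections start at simulation year 1).
#' @export
spin_up <- function(initial, climate_sampler, params, years,
                    succ = succession_params(), seed = NULL) {
  stopifnot(years >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- initial
  nr <- nrow(state$veg)
  nc <- ncol(state$veg)
  for (y in seq_len(years)) {
    clim <- climate_sampler(y, nr, nc)
    state <- step_year(state, clim, params, succ)$state
  }
  state$year <- 0L
  state
}

#' Run a replicate ensemble under one climate scenario
#'
#' Runs `n_runs` independent replicates of the annual model over the
#' scenario's climate cube. Each replicate gets its own child seed (derived
#' from `seed`), its own independently spun-up starting landscape, and its
#' own RNG stream, so the whole ensemble is reproducible from `seed` alone.
#'
#' @param initial A `landscape_state` (the pre-spin-up map; pass
#'   `spin_up_years = 0` to start all runs from it directly).
#' @param climate A `climate_cube`.
#' @param params A [flammability_params()].
#' @param n_runs Number of replicates (>= 1).
#' @param seed Master integer seed.
#' @param succ A [succession_params()].
#' @param spin_up_years Spin-up length per replicate (default 100).
#' @param spin_up_sampler Stationary sampler for spin-up; defaults to
#'   [baseline_climate_sampler()] around the scenario's own baseline
#'   parameters.
#' @param snapshot_every Store `(veg, age)` snapshots every this many years
#'   (1 = annual, the default; habitat series need at least decadal).
#' @return An object of class `fire_ensemble`: logical burn array
#'   `burn[run, year, row, col]`, a tibble `fires` (run, year, fire_id,
#'   ignition_row, ignition_col, size_km2, and a `cells` list-column),
#'   `snapshots[[run]][[year index]]`, the snapshot year grid, and
#'   provenance (`n_runs`, `n_years`, `pixel_area`, `scenario`).
#' @examples
#' land <- generate_landscape(landscape_config(12, 12, seed = 5))
#' cc <- generate_climate(climate_params("warm"), 10, 12, 12)
#' ens <- run_ensemble(land, cc, flammability_params(), n_runs = 2,
#'                     seed = 11, spin_up_years = 5)
#' ens
#' @export
run_ensemble <- function(initial, climate, params, n_runs, seed,
                         succ = succession_params(), spin_up_years = 100,
                         spin_up_sampler = baseline_climate_sampler(climate$params),
                         snapshot_every = 1) {
  stopifnot(inherits(climate, "climate_cube"), n_runs >= 1)
  nr <- nrow(initial$veg)
  nc <- ncol(initial$veg)
  if (nr != climate$n_rows || nc != climate$n_cols) {
    stop("climate cube shape does not match the landscape")
  }
  n_years <- climate$n_years
  run_seeds <- derive_seeds(seed, n_runs)
  snap_years <- seq_len(n_years)[seq_len(n_years) %% snapshot_every == 0]

  burn <- array(FALSE, dim = c(n_runs, n_years, nr, nc))
  fire_rows <- list()
  snapshots <- vector("list", n_runs)
  start_states <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    state <- spin_up(initial, spin_up_sampler, params, spin_up_years, succ)
    start_states[[r]] <- list(veg = state$veg, age = state$age)
    snapshots[[r]] <- vector("list", length(snap_years))
    for (y in seq_len(n_years)) {
      clim <- list(tas = matrix(climate$tas[y, , ], nr, nc),
                   pr = matrix(climate$pr[y, , ], nr, nc))
      out <- step_year(state, clim, params, succ)
      burn[r, y, , ] <- out$burn_mask
      if (length(out$fires) > 0) {
        fire_rows[[length(fire_rows) + 1]] <- tibble::tibble(
          run = r, year = y, fire_id = seq_along(out$fires),
          ignition_row = vapply(out$fires, function(f) f$ignition[1], 1),
          ignition_col = vapply(out$fires, function(f) f$ignition[2], 1),
          size_km2 = vapply(out$fires, function(f) f$size, 1),
          cells = lapply(out$fires, function(f) f$cells)
        )
      }
      state <- out$state
      if (y %in% snap_years) {
        snapshots[[r]][[match(y, snap_years)]] <-
          list(veg = state$veg, age = state$age)
      }
    }
  }
  fires <- if (length(fire_rows) > 0) {
    dplyr::bind_rows(fire_rows)
  } else {
    tibble::tibble(run = integer(), year = integer(), fire_id = integer(),
                   ignition_row = numeric(), ignition_col = numeric(),
                   size_km2 = numeric(), cells = list())
  }
  structure(
    list(burn = burn, fires = fires, snapshots = snapshots,
         start_states = start_states,
         snap_years = snap_years, n_runs = n_runs, n_years = n_years,
         pixel_area = initial$pixel_area,
         scenario = climate$params$label),
    class = "fire_ensemble"
  )
}

#' @export
print.fire_ensemble <- function(x, ...) {
  cat("<fire_ensemble> scenario '", x$scenario, "': ", x$n_runs,
      " runs x ", x$n_years, " years on ", dim(x$burn)[3], "x",
      dim(x$burn)[4], " pixels\n", sep = "")
  cat("  fires: ", nrow(x$fires), "; mean annual area burned: ",
      round(sum(x$fires$size_km2) / (x$n_runs * x$n_years), 2),
      " km2\n", sep = "")
  invisible(x)
}

#' Annual area burned, per run
#'
#' @param ensemble A `fire_ensemble`.
#' @return Numeric matrix `(n_runs, n_years)` of area burned in km^2.
#' @export
area_burned_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  ab <- apply(ensemble$burn, c(1, 2), sum) * ensemble$pixel_area
  matrix(ab, ensemble$n_runs, ensemble$n_years)
}
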