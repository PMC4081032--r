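#' Flammability parameters
#'
#' Per-cell annual flammability is
#' `clamp01( plogis(beta0 + beta_t * T + beta_p * P) * veg_scalar[veg] *
#' fuel(age) )` with `fuel(age) = min(1, age / fuel_age_scale)`, so
#' flammability rises with growing-season temperature, falls with
#' precipitation, is scaled per vegetation class (rock/ice is pinned to 0,
#' tundra burns less readily than spruce), and ramps up with time since fire
#' as fuel accumulates. A pixel that burned last year (age 0) cannot burn.
#' `fuel_age_scale <= 0` disables the ramp (`fuel == 1`), giving a
#' constant-hazard regime useful for stationarity checks.
#'
#' The regression behind the published model is not reproduced here; this
#' logistic parameterization preserves its stated dependencies (climate,
#' vegetation state, time since fire) with bounded output, and every
#' coefficient is exposed.
#'
#' @param beta0 Intercept of the logistic climate term.
#' @param beta_t Coefficient per degree C of growing-season temperature.
#' @param beta_p Coefficient per mm of growing-season precipitation
#'   (typically negative: wet years burn less).
#' @param veg_scalar Named multipliers in \[0, 1\] per class; `rock_ice`
#'   must be 0 and `tundra` must not exceed `black_spruce`.
#' @param fuel_age_scale Years to full fuel load (default 30); `<= 0`
#'   disables fuel limitation.
#' @param spread_factor Multiplier converting a neighbor's flammability into
#'   its spread (edge) probability, in `(0, Inf)`; 0 confines every fire to
#'   its ignition cell.
#' @param max_ignitions Cap on ignitions per year (`Inf` = no cap), applied
#'   by random subsampling.
#' @return An object of class `flammability_params`.
#' @examples
#' flammability_params()
#' @export
flammability_params <- function(beta0 = -7.4, beta_t = 0.15, beta_p = -0.006,
                                veg_scalar = c(rock_ice = 0, tundra = 0.25,
                                               black_spruce = 1,
                                               white_spruce = 0.8,
                                               deciduous = 0.4),
                                fuel_age_scale = 30, spread_factor = 150,
                                max_ignitions = Inf) {
  vs <- stats::setNames(numeric(5), names(veg_levels()))
  vs[names(veg_scalar)] <- veg_scalar
  if (vs[["rock_ice"]] != 0) stop("veg_scalar['rock_ice'] must be 0")
  if (vs[["tundra"]] > vs[["black_spruce"]]) {
    stop("tundra must not be more flammable than black spruce")
  }
  if (any(vs < 0 | vs > 1)) stop("veg_scalar entries must be in [0, 1]")
  if (spread_factor < 0) stop("spread_factor must be >= 0")
  structure(
    list(beta0 = beta0, beta_t = beta_t, beta_p = beta_p, veg_scalar = vs,
         fuel_age_scale = fuel_age_scale, spread_factor = spread_factor,
         max_ignitions = max_ignitions),
    class = "flammability_params"
  )
}

#' Per-cell flammability map
#'
#' @param state A `landscape_state`.
#' @param climate_year List with matrices `tas` and `pr` matching the
#'   landscape shape.
#' @param params A [flammability_params()].
#' @return Numeric matrix of flammability values in \[0, 1\]; 0 on rock/ice
#'   and on freshly burned (age-0) pixels when the fuel ramp is active.
#' @examples
#' land <- generate_landscape(landscape_config(10, 10, seed = 1))
#' clim <- list(tas = matrix(12, 10, 10), pr = matrix(150, 10, 10))
#' range(flammability_map(land, clim, flammability_params()))
#' @export
flammability_map <- function(state, climate_year, params) {
  stopifnot(inherits(state, "landscape_state"),
            inherits(params, "flammability_params"))
  tas <- climate_year$tas
  pr <- climate_year$pr
  if (!matrix_same_shape(state$veg, tas) || !matrix_same_shape(state$veg, pr)) {
    stop("climate grids must match the landscape shape")
  }
  if (anyNA(tas) || anyNA(pr)) stop("climate grids contain NA")
  lin <- params$beta0 + params$beta_t * tas + params$beta_p * pr
  f <- stats::plogis(lin) * params$veg_scalar[state$veg]
  if (params$fuel_age_scale > 0) {
    f <- f * pmin(1, pmax(0, state$age) / params$fuel_age_scale)
  }
  f[state$veg == VEG_ROCK] <- 0
  matrix(clamp01(f), nrow(tas), ncol(tas))
}

#' Random ignition
#'
#' Each cell ignites independently when a uniform draw falls below its
#' flammability; if more than `max_ignitions` cells ignite, a random subset
#' of that size is kept.
#'
#' @param flam Flammability matrix (entries in \[0, 1\]).
#' @param max_ignitions Cap (default `Inf`).
#' @return Two-column integer matrix of ignition cells `(row, col)`;
#'   zero rows when nothing ignites.
#' @export
ignite <- function(flam, max_ignitions = Inf) {
  stopifnot(all(flam >= 0 & flam <= 1))
  hit <- which(matrix(stats::runif(length(flam)), nrow(flam)) < flam)
  if (is.finite(max_ignitions) && length(hit) > max_ignitions) {
    hit <- sample(hit, max_ignitions)
  }
  nr <- nrow(flam)
  cbind(row = (hit - 1L) %% nr + 1L, col = (hit - 1L) %/% nr + 1L)
}
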