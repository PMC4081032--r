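#' Climate-scenario parameters
#'
#' Parameterizes one synthetic climate trajectory: a baseline growing-season
#' mean temperature and precipitation, linear decadal trends, white
#' interannual/spatial noise, and a latitudinal (per-row) temperature
#' gradient. Two trajectories generated as a pair with different warming
#' trends play the role of the contrasting "warm" and "hot" circulation
#' models.
#'
#' @param label `"warm"` or `"hot"`.
#' @param t0 Baseline growing-season mean temperature, degrees C.
#' @param t_trend Temperature trend, degrees C per decade.
#' @param p0 Baseline growing-season precipitation, mm.
#' @param p_trend Precipitation trend, mm per decade.
#' @param noise_sd_t,noise_sd_p Standard deviations of white noise (per
#'   pixel-year), degrees C and mm; must be >= 0.
#' @param spatial_gradient Temperature change per row index, degrees C
#'   (latitudinal proxy; negative means cooler toward high row numbers).
#' @param seed Integer seed.
#' @return An object of class `climate_params`.
#' @examples
#' climate_params("warm", t_trend = 0.3)
#' @export
climate_params <- function(label = c("warm", "hot"), t0 = 12, t_trend = 0.3,
                           p0 = 150, p_trend = 0, noise_sd_t = 0.8,
                           noise_sd_p = 25, spatial_gradient = -0.02,
                           seed = 1L) {
  label <- match.arg(label)
  if (noise_sd_t < 0 || noise_sd_p < 0) stop("noise SDs must be >= 0")
  structure(
    list(label = label, t0 = t0, t_trend = t_trend, p0 = p0,
         p_trend = p_trend, noise_sd_t = noise_sd_t, noise_sd_p = noise_sd_p,
         spatial_gradient = spatial_gradient, seed = as.integer(seed)),
    class = "climate_params"
  )
}

#' Generate an annual climate cube for one scenario
#'
#' For year `y` (1-based) and pixel `(r, c)`:
#' `temperature = t0 + t_trend * y / 10 + spatial_gradient * r + noise`,
#' and precipitation analogously (without the spatial gradient). Noise is
#' white in time and space. Precipitation is floored at 0 mm.
#'
#' @param params A [climate_params()].
#' @param n_years Number of years, >= 1.
#' @param n_rows,n_cols Lattice dimensions.
#' @return An object of class `climate_cube`: arrays `tas` and `pr` with
#'   dim `(n_years, n_rows, n_cols)`, plus the generating `params`.
#' @examples
#' cc <- generate_climate(climate_params("warm", noise_sd_t = 0, noise_sd_p = 0),
#'                        n_years = 5, n_rows = 4, n_cols = 4)
#' mean(cc$tas[5, , ])
#' @export
generate_climate <- function(params, n_years, n_rows, n_cols) {
  stopifnot(inherits(params, "climate_params"))
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 1) stop("n_years must be >= 1")
  set.seed(params$seed)
  tas <- array(0, dim = c(n_years, n_rows, n_cols))
  pr <- array(0, dim = c(n_years, n_rows, n_cols))
  row_grad <- params$spatial_gradient * seq_len(n_rows)
  for (y in seq_len(n_years)) {
    base_t <- params$t0 + params$t_trend * y / 10
    base_p <- params$p0 + params$p_trend * y / 10
    noise_t <- matrix(stats::rnorm(n_rows * n_cols, 0, params$noise_sd_t),
                      n_rows, n_cols)
    noise_p <- matrix(stats::rnorm(n_rows * n_cols, 0, params$noise_sd_p),
                      n_rows, n_cols)
    tas[y, , ] <- base_t + row_grad + noise_t
    pr[y, , ] <- pmax(0, base_p + noise_p)
  }
  structure(
    list(tas = tas, pr = pr, n_years = n_years, n_rows = n_rows,
         n_cols = n_cols, params = params),
    class = "climate_cube"
  )
}

#' @export
print.climate_cube <- function(x, ...) {
  cat("<climate_cube> scenario '", x$params$label, "': ", x$n_years,
      " years on ", x$n_rows, "x", x$n_cols, " pixels\n", sep = "")
  cat("  domain-mean T: ", round(mean(x$tas[1, , ]), 2), " -> ",
      round(mean(x$tas[x$n_years, , ]), 2), " degC\n", sep = "")
  invisible(x)
}

#' Tidy a climate cube into annual domain means
#'
#' @param x A `climate_cube`.
#' @param ... Unused.
#' @return A tibble with columns `year`, `scenario`, `tas_mean`, `pr_mean`.
#' @method tidy climate_cube
#' @export
tidy.climate_cube <- function(x, ...) {
  tibble::tibble(
    year = seq_len(x$n_years),
    scenario = x$params$label,
    tas_mean = apply(x$tas, 1, mean),
    pr_mean = apply(x$pr, 1, mean)
  )
}

#' Generate a paired warm/hot scenario
#'
#' Builds the two contrasting trajectories on identical noise (same seed),
#' differing only in their trend parameters, so the pair isolates the
#' warming contrast. The hot member must warm at least as fast as the warm
#' member.
#'
#' @param n_years,n_rows,n_cols Dimensions.
#' @param warm,hot [climate_params()] for the two members; `hot$t_trend`
#'   must be >= `warm$t_trend`.
#' @return Named list with `climate_cube` elements `warm` and `hot`.
#' @export
generate_climate_pair <- function(n_years, n_rows, n_cols,
                                  warm = climate_params("warm", t_trend = 0.3),
                                  hot = climate_params("hot", t_trend = 0.6,
                                                       seed = warm$seed)) {
  if (hot$t_trend < warm$t_trend) {
    stop("hot scenario must have t_trend >= warm scenario's t_trend")
  }
  list(warm = generate_climate(warm, n_years, n_rows, n_cols),
       hot = generate_climate(hot, n_years, n_rows, n_cols))
}

#' Stationary baseline climate sampler for spin-up
#'
#' Returns a function `(year, n_rows, n_cols) -> list(tas, pr)` that draws
#' trend-free climate fields around the scenario baseline; used to drive the
#' spin-up phase toward a quasi-stationary fire regime.
#'
#' @param params A [climate_params()]; its trends are ignored.
#' @return A sampler closure (consumes the current RNG stream).
#' @export
baseline_climate_sampler <- function(params = climate_params()) {
  force(params)
  function(year, n_rows, n_cols) {
    row_grad <- params$spatial_gradient * seq_len(n_rows)
    tas <- params$t0 + row_grad +
      matrix(stats::rnorm(n_rows * n_cols, 0, params$noise_sd_t),
             n_rows, n_cols)
    pr <- matrix(pmax(0, params$p0 +
                        stats::rnorm(n_rows * n_cols, 0, params$noise_sd_p)),
                 n_rows, n_cols)
    list(tas = tas, pr = pr)
  }
}
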