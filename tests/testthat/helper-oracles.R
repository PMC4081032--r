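# Brute-force oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (sorting, exhaustive loops) and independent
# of the package's implementation paths.

# --- fixtures ---------------------------------------------------------------

# A uniform single-class landscape (all ages equal unless given).
uniform_landscape <- function(nr, nc, class = "tundra", age = 100,
                              pixel_area = 1) {
  code <- veg_code(class)
  veg <- matrix(code, nr, nc)
  ages <- matrix(as.integer(age), nr, nc)
  ages[veg == veg_code("rock_ice")] <- -1L
  borealfire:::new_landscape_state(veg, ages, pixel_area = pixel_area)
}

# Landscape from explicit class-name and age matrices.
landscape_from <- function(veg_names, ages) {
  veg <- matrix(veg_code(veg_names), nrow(veg_names), ncol(veg_names))
  borealfire:::new_landscape_state(veg, ages)
}

# Constant-climate helpers.
const_climate <- function(nr, nc, t = 12, p = 150) {
  list(tas = matrix(t, nr, nc), pr = matrix(p, nr, nc))
}
const_sampler <- function(t = 12, p = 150) {
  function(year, nr, nc) const_climate(nr, nc, t, p)
}

# Hand-built ensemble: burn is (runs, years, nr, nc); snapshots optional.
toy_ensemble <- function(burn, snapshots = NULL, pixel_area = 1,
                         scenario = "warm", fires = NULL) {
  n_runs <- dim(burn)[1]
  n_years <- dim(burn)[2]
  if (is.null(fires)) {
    fires <- tibble::tibble(run = integer(), year = integer(),
                            fire_id = integer(), ignition_row = numeric(),
                            ignition_col = numeric(), size_km2 = numeric(),
                            cells = list())
  }
  structure(
    list(burn = burn, fires = fires, snapshots = snapshots,
         start_states = NULL, snap_years = seq_len(n_years),
         n_runs = n_runs, n_years = n_years, pixel_area = pixel_area,
         scenario = scenario),
    class = "fire_ensemble"
  )
}

# --- oracles ----------------------------------------------------------------

# Relative flammability by direct counting.
oracle_relative_flammability <- function(burn) {
  n_runs <- dim(burn)[1]
  n_years <- dim(burn)[2]
  out <- matrix(0, dim(burn)[3], dim(burn)[4])
  for (r in seq_len(n_runs)) {
    for (y in seq_len(n_years)) {
      out <- out + burn[r, y, , ]
    }
  }
  out / (n_runs * n_years)
}

# Representative run by exhaustive correlation against per-year medians.
oracle_representative_run <- function(m) {
  med <- apply(m, 2, stats::median)
  rs <- rep(NA_real_, nrow(m))
  for (r in seq_len(nrow(m))) {
    if (stats::sd(m[r, ]) > 0) rs[r] <- stats::cor(m[r, ], med)
  }
  best <- which(rs == max(rs, na.rm = TRUE))[1]
  list(run = best, r = rs[best], all_r = rs)
}

# Nearest-rank quantile by direct sorting.
oracle_quantile <- function(x, p) {
  sort(x)[max(1, ceiling(p * length(x)))]
}

# Top-fraction mask by full sort: threshold at the floor(fraction * n)-th
# largest value, ties included.
oracle_top_mask <- function(map, fraction, fuel = NULL) {
  if (is.null(fuel)) fuel <- matrix(TRUE, nrow(map), ncol(map))
  vals <- sort(map[fuel], decreasing = TRUE)
  thr <- vals[max(1, floor(fraction * length(vals)))]
  fuel & map >= thr
}

# Annual regime stats by looping over labelled fires.
oracle_regime_stats <- function(labels_by_year, keep, pixel_area = 1) {
  t(vapply(labels_by_year, function(lab) {
    ids <- setdiff(unique(as.vector(lab)), 0)
    areas <- vapply(ids, function(id) sum(lab == id & keep), numeric(1))
    areas <- areas[areas > 0] * pixel_area
    c(n = length(areas),
      mean = if (length(areas) > 0) mean(areas) else 0,
      total = sum(areas))
  }, numeric(3)))
}
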