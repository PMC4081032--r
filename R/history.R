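#' Generate a synthetic historical fire record
#'
#' Emulates a multi-decade burn-perimeter database on the synthetic
#' landscape: each year, ignitions occur on fuel (non-rock/ice) pixels with
#' probability `burn_rate / mean_fire_size` and grow into connected burned
#' patches whose sizes are geometric with mean `mean_fire_size` pixels, so
#' the expected burned fraction per year is `burn_rate`. Fires within a year
#' do not overlap.
#'
#' @param landscape A `landscape_state`; rock/ice pixels never burn.
#' @param years Integer vector of year labels (e.g. `1950:2012`) or a single
#'   count (expanded to `1:years`).
#' @param burn_rate Expected fraction of the domain burned per year, in
#'   \[0, 1\].
#' @param mean_fire_size Mean fire size in pixels (>= 1).
#' @param seed Integer seed.
#' @param forced_fires Optional list of `list(year, anchor = c(row, col),
#'   size)` entries; each is grown deterministically (no random accretion
#'   order beyond the seed) in its stated year in addition to — and before —
#'   the stochastic fires.
#' @return An object of class `fire_record`: `years`, per-year logical
#'   `burn_masks`, per-year integer `fire_labels` (0 outside fires), and
#'   `pixel_area`.
#' @examples
#' land <- generate_landscape(landscape_config(20, 20, seed = 3))
#' rec <- generate_historical_record(land, years = 10, burn_rate = 0.01,
#'                                   seed = 9)
#' sapply(rec$burn_masks, sum)
#' @export
generate_historical_record <- function(landscape, years, burn_rate,
                                       mean_fire_size = 5, seed = 1L,
                                       forced_fires = list()) {
  stopifnot(inherits(landscape, "landscape_state"))
  if (burn_rate < 0 || burn_rate > 1) stop("burn_rate must be in [0, 1]")
  if (mean_fire_size < 1) stop("mean_fire_size must be >= 1")
  if (length(years) == 1) years <- seq_len(years)
  set.seed(as.integer(seed))
  nr <- nrow(landscape$veg)
  nc <- ncol(landscape$veg)
  fuel <- landscape$veg != VEG_ROCK
  p_ign <- min(1, burn_rate / mean_fire_size)

  burn_masks <- vector("list", length(years))
  fire_labels <- vector("list", length(years))
  for (k in seq_along(years)) {
    mask <- matrix(FALSE, nr, nc)
    labels <- matrix(0L, nr, nc)
    next_id <- 0L

    yr_forced <- Filter(function(ff) ff$year == years[k], forced_fires)
    for (ff in yr_forced) {
      cells <- grow_patch(ff$anchor, ff$size, fuel & !mask, nr, nc)
      next_id <- next_id + 1L
      mask[cells] <- TRUE
      labels[cells] <- next_id
    }

    ign <- which(fuel & !mask & matrix(stats::runif(nr * nc) < p_ign, nr, nc))
    for (cell in sample(ign)) {          # random fire order
      if (mask[cell]) next
      size <- 1L + stats::rgeom(1, 1 / mean_fire_size)
      anchor <- c((cell - 1L) %% nr + 1L, (cell - 1L) %/% nr + 1L)
      cells <- grow_patch(anchor, size, fuel & !mask, nr, nc)
      next_id <- next_id + 1L
      mask[cells] <- TRUE
      labels[cells] <- next_id
    }
    burn_masks[[k]] <- mask
    fire_labels[[k]] <- labels
  }
  structure(
    list(years = years, burn_masks = burn_masks, fire_labels = fire_labels,
         pixel_area = landscape$pixel_area),
    class = "fire_record"
  )
}

# Grow an 8-connected patch of up to `size` cells from `anchor` inside
# `allowed` (logical matrix), by uniform random accretion on the frontier.
# Returns linear indices; may be smaller than `size` if boxed in.
grow_patch <- function(anchor, size, allowed, nr, nc) {
  if (!allowed[anchor[1], anchor[2]]) return(integer(0))
  taken <- matrix(FALSE, nr, nc)
  taken[anchor[1], anchor[2]] <- TRUE
  cells <- (anchor[2] - 1L) * nr + anchor[1]
  frontier <- cells
  while (length(cells) < size && length(frontier) > 0) {
    pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    i <- (pick - 1L) %% nr + 1L
    j <- (pick - 1L) %/% nr + 1L
    nb_r <- i + NEIGH8[, "dr"]
    nb_c <- j + NEIGH8[, "dc"]
    ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
    nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
    nb <- nb[allowed[nb] & !taken[nb]]
    if (length(nb) == 0) {
      frontier <- setdiff(frontier, pick)
      next
    }
    new_cell <- if (length(nb) == 1) nb else sample(nb, 1)
    taken[new_cell] <- TRUE
    cells <- c(cells, new_cell)
    frontier <- c(frontier, new_cell)
  }
  cells
}

#' @export
print.fire_record <- function(x, ...) {
  burned <- vapply(x$burn_masks, sum, integer(1))
  cat("<fire_record> ", length(x$years), " years; annual burned pixels: ",
      "mean ", round(mean(burned), 1), ", max ", max(burned), "\n", sep = "")
  invisible(x)
}

#' Tidy a fire record into a per-fire catalog
#'
#' @param x A `fire_record`.
#' @param ... Unused.
#' @return A tibble with columns `year`, `fire_id`, `size_km2`.
#' @method tidy fire_record
#' @export
tidy.fire_record <- function(x, ...) {
  rows <- purrr::map2_dfr(x$years, x$fire_labels, function(yr, lab) {
    ids <- sort(unique(lab[lab > 0]))
    tibble::tibble(
      year = yr,
      fire_id = ids,
      size_km2 = vapply(ids, function(id) sum(lab == id), integer(1)) *
        x$pixel_area
    )
  })
  rows
}
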