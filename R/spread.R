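#' Spread one fire from an ignition cell
#'
#' Breadth-first front growth on the 8-neighborhood: each newly burning cell
#' attempts each of its not-yet-burned neighbors exactly once, igniting it
#' with probability `clamp01(spread_factor * flam(neighbor))`; the fire ends
#' when the front is empty. A cell that resisted one neighbor may still be
#' ignited later by a different burning neighbor (its own edge). Cells in
#' `exclude` (e.g. burned earlier the same year by another fire) and
#' rock/ice cells never burn.
#'
#' @param state A `landscape_state`.
#' @param flam Flammability matrix.
#' @param ignition Length-2 integer `(row, col)`; must be fuel with
#'   positive flammability.
#' @param params A [flammability_params()] (only `spread_factor` is used).
#' @param exclude Optional logical matrix of cells unavailable this year.
#' @return An object of class `fire_event`: `year` (taken from the state),
#'   `ignition`, integer matrix `cells` (one row per burned cell, ignition
#'   first), and `size` in km^2.
#' @examples
#' land <- generate_landscape(landscape_config(10, 10, seed = 1))
#' clim <- list(tas = matrix(14, 10, 10), pr = matrix(120, 10, 10))
#' fl <- flammability_map(land, clim, flammability_params())
#' ig <- which(fl > 0, arr.ind = TRUE)[1, ]
#' spread_fire(land, fl, ig, flammability_params(spread_factor = 0))
#' @export
spread_fire <- function(state, flam, ignition, params, exclude = NULL) {
  stopifnot(inherits(state, "landscape_state"))
  nr <- nrow(flam)
  nc <- ncol(flam)
  i0 <- as.integer(ignition[1])
  j0 <- as.integer(ignition[2])
  if (state$veg[i0, j0] == VEG_ROCK) stop("ignition on rock/ice")
  if (flam[i0, j0] <= 0) stop("ignition cell has zero flammability")
  if (is.null(exclude)) exclude <- matrix(FALSE, nr, nc)

  burned <- matrix(FALSE, nr, nc)
  burned[i0, j0] <- TRUE
  cells <- matrix(c(i0, j0), ncol = 2)
  front <- cells
  p_edge <- clamp01(params$spread_factor * flam)
  p_edge[state$veg == VEG_ROCK] <- 0
  p_edge[exclude] <- 0
  while (nrow(front) > 0) {
    new_front <- matrix(integer(0), ncol = 2)
    for (k in seq_len(nrow(front))) {
      nb_r <- front[k, 1] + NEIGH8[, "dr"]
      nb_c <- front[k, 2] + NEIGH8[, "dc"]
      ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
      nb_r <- nb_r[ok]
      nb_c <- nb_c[ok]
      for (m in seq_along(nb_r)) {
        if (!burned[nb_r[m], nb_c[m]] && p_edge[nb_r[m], nb_c[m]] > 0 &&
            stats::runif(1) < p_edge[nb_r[m], nb_c[m]]) {
          burned[nb_r[m], nb_c[m]] <- TRUE
          new_front <- rbind(new_front, c(nb_r[m], nb_c[m]))
          cells <- rbind(cells, c(nb_r[m], nb_c[m]))
        }
      }
    }
    front <- new_front
  }
  colnames(cells) <- c("row", "col")
  structure(
    list(year = state$year, ignition = c(i0, j0), cells = cells,
         size = nrow(cells) * state$pixel_area),
    class = "fire_event"
  )
}

#' @export
print.fire_event <- function(x, ...) {
  cat("<fire_event> year ", x$year, ": ", nrow(x$cells), " cells (",
      x$size, " km2), ignited at (", x$ignition[1], ",", x$ignition[2],
      ")\n", sep = "")
  invisible(x)
}
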