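#' Generate synthetic herd-range masks
#'
#' Grows one connected blob per requested range around an anchor pixel until
#' it covers `round(target_fraction * n_pixels)` pixels (always within 1% of
#' the target). Growth is a greedy accretion: cells are added in order of
#' jittered Euclidean distance to the anchor, restricted to cells
#' 8-adjacent to the blob, which keeps the mask connected and roughly
#' elliptical. Masks are built in the order given; overlapping anchors
#' simply produce overlapping masks (construction order only matters for
#' reproducibility of the jitter).
#'
#' @param config A [landscape_config()] (only the grid shape is used).
#' @param ranges A list of lists with elements `name`, `target_fraction`
#'   (in (0, 1\]) and `anchor` (length-2 integer `(row, col)` inside the
#'   grid).
#' @param jitter_sd Standard deviation of the distance jitter, in pixels
#'   (0 gives a deterministic disc).
#' @param seed Integer seed.
#' @return A list of `range_mask` objects: `name` plus logical matrix
#'   `mask`.
#' @examples
#' cfg <- landscape_config(20, 20)
#' rk <- generate_range_masks(cfg, list(
#'   list(name = "north", target_fraction = 0.2, anchor = c(5, 10))))
#' sum(rk[[1]]$mask)
#' @export
generate_range_masks <- function(config, ranges, jitter_sd = 1.5, seed = 1L) {
  stopifnot(inherits(config, "domain_config"))
  set.seed(as.integer(seed))
  nr <- config$n_rows
  nc <- config$n_cols
  n <- nr * nc
  lapply(ranges, function(rg) {
    stopifnot(!is.null(rg$name), !is.null(rg$target_fraction),
              !is.null(rg$anchor))
    f <- rg$target_fraction
    if (f <= 0 || f > 1) stop("target_fraction must be in (0, 1]")
    a <- as.integer(rg$anchor)
    if (a[1] < 1 || a[1] > nr || a[2] < 1 || a[2] > nc) {
      stop("anchor outside grid")
    }
    target_n <- max(1L, round(f * n))
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    score <- sqrt((rows - a[1])^2 + (cols - a[2])^2) +
      stats::rnorm(n, 0, jitter_sd)
    ord <- order(score)
    mask <- matrix(FALSE, nr, nc)
    mask[a[1], a[2]] <- TRUE
    taken <- 1L
    # accrete in score order, skipping cells not yet adjacent to the blob;
    # repeat passes until the quota is met (always terminates: some skipped
    # cell becomes adjacent each pass)
    while (taken < target_n) {
      added <- FALSE
      for (idx in ord) {
        if (taken >= target_n) break
        i <- rows[idx]
        j <- cols[idx]
        if (mask[i, j]) next
        nb_r <- i + NEIGH8[, "dr"]
        nb_c <- j + NEIGH8[, "dc"]
        ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
        if (any(mask[cbind(nb_r[ok], nb_c[ok])])) {
          mask[i, j] <- TRUE
          taken <- taken + 1L
          added <- TRUE
        }
      }
      if (!added) break
    }
    structure(list(name = rg$name, mask = mask), class = "range_mask")
  })
}

#' @export
print.range_mask <- function(x, ...) {
  cat("<range_mask> '", x$name, "': ", sum(x$mask), " of ",
      length(x$mask), " pixels (",
      round(100 * mean(x$mask), 1), "%)\n", sep = "")
  invisible(x)
}
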