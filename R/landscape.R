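#' Domain configuration for synthetic landscapes
#'
#' Describes the rectangular lattice the whole pipeline runs on: grid size,
#' pixel area, target vegetation composition, initial mean stand age, and
#' the seed that makes every generated artifact reproducible.
#'
#' @param n_rows,n_cols Positive integers; `n_rows * n_cols >= 9`.
#' @param pixel_area Area of one pixel in km^2 (default 1, emulating the
#'   1-km model resolution).
#' @param veg_proportions Named numeric vector over the five classes of
#'   [veg_levels()]; must sum to 1 (tolerance 1e-9). Missing names default
#'   to 0.
#' @param mean_age Mean of the geometric initial stand-age distribution in
#'   years (default 80), the stationary time-since-fire distribution under a
#'   constant hazard of about 1/(mean_age + 1) per year.
#' @param seed Integer seed.
#' @return An object of class `domain_config` (a named list).
#' @examples
#' landscape_config(30, 30, veg_proportions = c(tundra = 0.6, black_spruce = 0.4))
#' @export
landscape_config <- function(n_rows, n_cols, pixel_area = 1,
                             veg_proportions = c(rock_ice = 0.05,
                                                 tundra = 0.40,
                                                 black_spruce = 0.25,
                                                 white_spruce = 0.10,
                                                 deciduous = 0.20),
                             mean_age = 80, seed = 1L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows <= 0 || n_cols <= 0) {
    stop("n_rows and n_cols must be positive integers")
  }
  if (n_rows * n_cols < 9) stop("domain must have at least 9 pixels")
  props <- stats::setNames(numeric(5), names(veg_levels()))
  bad <- setdiff(names(veg_proportions), names(props))
  if (length(bad) > 0) stop("unknown vegetation class(es): ",
                            paste(bad, collapse = ", "))
  props[names(veg_proportions)] <- veg_proportions
  if (any(props < 0)) stop("veg_proportions must be non-negative")
  if (abs(sum(props) - 1) > 1e-9) stop("veg_proportions must sum to 1")
  if (pixel_area <= 0) stop("pixel_area must be positive")
  if (mean_age <= 0) stop("mean_age must be positive")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_area = pixel_area,
         veg_proportions = props, mean_age = mean_age,
         seed = as.integer(seed)),
    class = "domain_config"
  )
}

# Internal constructor; validates the age/veg sentinel invariant.
new_landscape_state <- function(veg, age, year = 0L, pixel_area = 1,
                                sched_target = NULL, sched_due = NULL) {
  stopifnot(is.matrix(veg), is.matrix(age), matrix_same_shape(veg, age))
  if (!all((veg == VEG_ROCK) == (age == AGE_SENTINEL))) {
    stop("age must be -1 exactly on rock/ice pixels")
  }
  if (any(age < 0 & veg != VEG_ROCK)) stop("negative age on fuel pixel")
  if (is.null(sched_target)) sched_target <- matrix(0L, nrow(veg), ncol(veg))
  if (is.null(sched_due)) sched_due <- matrix(0L, nrow(veg), ncol(veg))
  structure(
    list(veg = veg, age = age, year = as.integer(year),
         pixel_area = pixel_area,
         sched_target = sched_target, sched_due = sched_due),
    class = "landscape_state"
  )
}

#' @export
print.landscape_state <- function(x, ...) {
  cat("<landscape_state> ", nrow(x$veg), "x", ncol(x$veg),
      " pixels, year ", x$year, "\n", sep = "")
  tab <- table(factor(veg_name(x$veg), levels = names(veg_levels())))
  comp <- round(100 * tab / length(x$veg), 1)
  cat("  composition (%):",
      paste(names(comp), comp, sep = "=", collapse = " "), "\n")
  fuel <- x$veg != VEG_ROCK
  if (any(fuel)) {
    cat("  stand age (fuel pixels): mean ", round(mean(x$age[fuel]), 1),
        " y, max ", max(x$age[fuel]), " y\n", sep = "")
  }
  invisible(x)
}

#' Tidy a landscape state into a per-pixel tibble
#'
#' @param x A `landscape_state`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `veg` (class name), `age`.
#' @method tidy landscape_state
#' @export
tidy.landscape_state <- function(x, ...) {
  nr <- nrow(x$veg)
  nc <- ncol(x$veg)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    veg = veg_name(as.vector(x$veg)),
    age = as.vector(x$age)
  )
}

# Majority filter: one smoothing pass; each pixel takes the modal class of
# its 3x3 neighborhood (ties keep the current class).
majority_filter_pass <- function(veg) {
  nr <- nrow(veg)
  nc <- ncol(veg)
  counts <- array(0L, dim = c(nr, nc, 5L))
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- veg
  for (dr in -1:1) {
    for (dc in -1:1) {
      win <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      for (k in 1:5) {
        counts[, , k] <- counts[, , k] + (win == k)
      }
    }
  }
  out <- veg
  best <- counts[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr),
                       as.vector(veg))]
  best <- matrix(best, nr, nc)
  for (k in 1:5) {
    better <- counts[, , k] > best
    out[better] <- k
    best[better] <- counts[, , k][better]
  }
  out
}

# Repair pass: nudge class counts back to their target quotas after
# smoothing by relabelling randomly chosen pixels of over-represented
# classes to under-represented ones.
repair_quotas <- function(veg, target_counts) {
  cur <- tabulate(veg, nbins = 5L)
  for (k in order(target_counts - cur)) {        # most over-represented first
    excess <- cur[k] - target_counts[k]
    if (excess <= 0) next
    deficit_classes <- which(cur < target_counts)
    if (length(deficit_classes) == 0) break
    idx <- which(veg == k)
    take <- sample(idx, min(excess, length(idx)))
    # assign to deficit classes proportionally to their deficits
    defs <- target_counts[deficit_classes] - cur[deficit_classes]
    assign_to <- rep(deficit_classes, defs)[seq_along(take)]
    veg[take] <- assign_to
    cur <- tabulate(veg, nbins = 5L)
  }
  veg
}

#' Generate a synthetic five-class landscape
#'
#' Places vegetation by a seeded multinomial draw, smooths it into patches
#' with three majority-filter passes (fire spread is degenerate on
#' salt-and-pepper maps), then repairs class quotas so empirical frequencies
#' stay within 2% of `veg_proportions`. Stand ages are drawn from a
#' geometric distribution with mean `mean_age`; rock/ice pixels carry the
#' sentinel age -1. Initial deciduous stands receive a pending succession
#' schedule (climax black or white spruce, equal odds) so they can mature
#' even if never burned.
#'
#' @param config A [landscape_config()].
#' @return A `landscape_state`: integer matrices `veg` and `age`, scalar
#'   `year` (0), `pixel_area`, and the pending-transition matrices
#'   `sched_target`, `sched_due`.
#' @examples
#' land <- generate_landscape(landscape_config(20, 20, seed = 42))
#' table(veg_name(land$veg))
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  set.seed(config$seed)
  nr <- config$n_rows
  nc <- config$n_cols
  n <- nr * nc
  props <- config$veg_proportions
  veg <- matrix(sample.int(5L, n, replace = TRUE, prob = props), nr, nc)
  for (pass in 1:3) veg <- majority_filter_pass(veg)
  target <- round(props * n)
  # rounding can leave the targets off by a pixel or two; absorb into the
  # largest class
  target[which.max(target)] <- target[which.max(target)] + (n - sum(target))
  veg <- repair_quotas(veg, target)

  p_age <- 1 / (config$mean_age + 1)
  age <- matrix(stats::rgeom(n, p_age), nr, nc)
  age[veg == VEG_ROCK] <- AGE_SENTINEL

  sched_target <- matrix(0L, nr, nc)
  sched_due <- matrix(0L, nr, nc)
  dec <- which(veg == VEG_DECID)
  if (length(dec) > 0) {
    sched_target[dec] <- sample(c(VEG_BLACK, VEG_WHITE), length(dec),
                                replace = TRUE)
    sched_due[dec] <- pmax(1L, as.integer(round(stats::runif(
      length(dec), 25, 75))))
  }
  new_landscape_state(veg, age, year = 0L, pixel_area = config$pixel_area,
                      sched_target = sched_target, sched_due = sched_due)
}
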