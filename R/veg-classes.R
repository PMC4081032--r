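#' Vegetation classes
#'
#' The model runs on five land-cover classes. Grids store them as integer
#' codes; `veg_levels()` gives the canonical code-to-name mapping, and
#' `veg_code()` converts names to codes.
#'
#' Rock/ice is non-fuel: it never ignites, never changes class, and carries a
#' sentinel stand age of -1 because "years since fire" is meaningless there.
#'
#' @return `veg_levels()` returns a named integer vector mapping class names
#'   to codes; `veg_code()` returns the integer code(s) for `name`.
#' @examples
#' veg_levels()
#' veg_code("black_spruce")
#' @export
veg_levels <- function() {
  c(rock_ice = 1L, tundra = 2L, black_spruce = 3L, white_spruce = 4L,
    deciduous = 5L)
}

#' @rdname veg_levels
#' @param name Character vector of class names.
#' @export
veg_code <- function(name) {
  lv <- veg_levels()
  bad <- setdiff(name, names(lv))
  if (length(bad) > 0) {
    stop("unknown vegetation class(es): ", paste(bad, collapse = ", "))
  }
  unname(lv[name])
}

#' @rdname veg_levels
#' @param code Integer vector of class codes.
#' @export
veg_name <- function(code) {
  lv <- veg_levels()
  names(lv)[match(code, lv)]
}

# internal shorthands
VEG_ROCK <- 1L
VEG_TUNDRA <- 2L
VEG_BLACK <- 3L
VEG_WHITE <- 4L
VEG_DECID <- 5L
AGE_SENTINEL <- -1L
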