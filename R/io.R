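#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text single-band raster I/O in the widely supported ESRI ASCII
#' grid format (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header, then rows from the top). A synthetic origin and a cell size
#' derived from the pixel area stand in for real georeferencing. Logical
#' grids are written as 0/1.
#'
#' @param grid Numeric, integer or logical matrix.
#' @param path Output file.
#' @param cellsize Cell edge length (default 1000, i.e. 1-km pixels).
#' @param nodata NODATA sentinel (default -1, the rock/ice age sentinel).
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a numeric matrix with `NODATA` as `NA`.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_ascii_grid(matrix(1:6, 2, 3), f)
#' read_ascii_grid(f)
#' @export
write_ascii_grid <- function(grid, path, cellsize = 1000, nodata = -1) {
  stopifnot(is.matrix(grid))
  storage <- grid
  if (is.logical(storage)) storage <- storage + 0L
  header <- c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(storage, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols")
  nr <- val("nrows")
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  m[m == nodata] <- NA
  m
}

#' Write a climate cube as tidy CSV
#'
#' Long format with one row per (year, row, col): columns `year`, `row`,
#' `col`, `tas_gs`, `pr_gs` (growing-season temperature and
#' precipitation).
#'
#' @param cube A `climate_cube`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(cube, path) {
  stopifnot(inherits(cube, "climate_cube"))
  grid <- expand.grid(row = seq_len(cube$n_rows), col = seq_len(cube$n_cols))
  df <- purrr::map_dfr(seq_len(cube$n_years), function(y) {
    tibble::tibble(year = y, row = grid$row, col = grid$col,
                   tas_gs = as.vector(cube$tas[y, , ]),
                   pr_gs = as.vector(cube$pr[y, , ]))
  })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble's fire catalog as CSV
#'
#' One row per fire: `run`, `year`, `fire_id`, `ignition_row`,
#' `ignition_col`, `size_km2` (the `cells` list-column is dropped).
#'
#' @param ensemble A `fire_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fire_catalog_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  df <- dplyr::select(ensemble$fires, -"cells")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transition schedule as CSV
#'
#' Serializes the pending deciduous-to-spruce transitions of a landscape
#' (columns `row`, `col`, `target`, `due_age`) so a run can be resumed.
#'
#' @param state A `landscape_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(state, path) {
  stopifnot(inherits(state, "landscape_state"))
  idx <- which(state$sched_due > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    target = veg_name(state$sched_target[idx]),
    due_age = state$sched_due[idx]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
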