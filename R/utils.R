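clamp01 <- function(x) pmax(pmin(x, 1), 0)  # x first so matrix dims survive

# 8-neighborhood offsets (row, col)
NEIGH8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Nearest-rank quantile
#'
#' Quantiles throughout the package (percentile envelopes, the
#' top-flammability threshold) use the nearest-rank convention: the `p`-th
#' quantile of `n` sorted values is the value at rank `ceiling(p * n)`
#' (rank 1 for `p = 0`). No interpolation is performed, so the result is
#' always an observed value.
#'
#' @param x Numeric vector (NAs removed).
#' @param p Probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, one per element of `p`.
#' @examples
#' nearest_rank_quantile(1:10, c(0.05, 0.5, 0.95))
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) stop("no non-missing values")
  stopifnot(all(p >= 0 & p <= 1))
  idx <- pmax(1L, as.integer(ceiling(p * n)))
  x[idx]
}

#' Map simulation years to calendar decade labels
#'
#' Simulation years are indexed `1..n_years` and correspond to the 90-year
#' projection horizon 2011-2100; decade `d` covers years `10(d-1)+1 .. 10d`
#' and is labelled `"2010s" .. "2090s"`.
#'
#' @param year Integer vector of simulation years (1-based).
#' @return Character vector of decade labels.
#' @examples
#' decade_label(c(1, 10, 11, 90))
#' @export
decade_label <- function(year) {
  stopifnot(all(year >= 1))
  d <- (as.integer(year) - 1L) %/% 10L
  paste0(2010L + 10L * d, "s")
}

# Independent child seeds derived from one master seed; keeps every stream
# below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Connected components of a logical matrix under the 8-neighborhood
# (flood fill). Returns an integer matrix: 0 outside, component id inside.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  next_id <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        next_id <- next_id + 1L
        stack <- matrix(c(i, j), ncol = 2)
        lab[i, j] <- next_id
        while (nrow(stack) > 0) {
          cur <- stack[nrow(stack), , drop = TRUE]
          stack <- stack[-nrow(stack), , drop = FALSE]
          nb_r <- cur[1] + NEIGH8[, "dr"]
          nb_c <- cur[2] + NEIGH8[, "dc"]
          ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
          nb_r <- nb_r[ok]
          nb_c <- nb_c[ok]
          for (k in seq_along(nb_r)) {
            if (mask[nb_r[k], nb_c[k]] && lab[nb_r[k], nb_c[k]] == 0L) {
              lab[nb_r[k], nb_c[k]] <- next_id
              stack <- rbind(stack, c(nb_r[k], nb_c[k]))
            }
          }
        }
      }
    }
  }
  lab
}

# TRUE iff all TRUE cells of `mask` form one 8-connected component.
is_connected8 <- function(mask) {
  lab <- label_components(mask)
  max(lab) <= 1L
}

matrix_same_shape <- function(a, b) {
  identical(dim(a), dim(b))
}
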