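#' Succession parameters
#'
#' Post-fire transition rules: burned spruce (black or white) resets to
#' early-successional deciduous and is scheduled to return to a climax
#' spruce class after a probabilistic delay; burned deciduous and tundra
#' self-replace; unburned deciduous matures into its climax spruce class
#' when stand age reaches the scheduled due age. Fire severity, proxied by
#' fire area, lengthens the sampled delay.
#'
#' @param spruce_target_prob Probability that a burned spruce stand's climax
#'   trajectory returns to its own spruce class (otherwise it switches to
#'   the other one). Default 0.9.
#' @param decid_to_spruce_range Length-2 numeric `(min, max)` years; the
#'   base deciduous-to-spruce delay is uniform on this window. Default
#'   `c(25, 75)`, bracketing the 60-year lichen-recovery horizon.
#' @param severity_k Severity coefficient `k >= 0` in the multiplier
#'   `1 + k * log10(fire_size_km2 + 1)` applied to the sampled delay;
#'   larger fires recover more slowly. Default 0.3.
#' @return An object of class `succession_params`.
#' @examples
#' succession_params()
#' @export
succession_params <- function(spruce_target_prob = 0.9,
                              decid_to_spruce_range = c(25, 75),
                              severity_k = 0.3) {
  if (spruce_target_prob < 0 || spruce_target_prob > 1) {
    stop("spruce_target_prob must be in [0, 1]")
  }
  r <- decid_to_spruce_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
    stop("decid_to_spruce_range must be positive and ordered (min, max)")
  }
  if (severity_k < 0) stop("severity_k must be >= 0")
  structure(
    list(spruce_target_prob = spruce_target_prob,
         decid_to_spruce_range = r, severity_k = severity_k),
    class = "succession_params"
  )
}

#' Sample a deciduous-to-spruce transition time
#'
#' Uniform draw on the base window, multiplied by the severity factor
#' `1 + k * log10(fire_size + 1)`, rounded to the nearest integer year and
#' floored at 1.
#'
#' @param fire_size Fire area in km^2 (>= 0).
#' @param params A [succession_params()].
#' @return Integer years until the climax spruce stage, >= 1.
#' @examples
#' p <- succession_params(decid_to_spruce_range = c(30, 30), severity_k = 0)
#' sample_transition_time(10, p)
#' @export
sample_transition_time <- function(fire_size, params) {
  stopifnot(fire_size >= 0)
  base <- stats::runif(1, params$decid_to_spruce_range[1],
                       params$decid_to_spruce_range[2])
  mult <- 1 + params$severity_k * log10(fire_size + 1)
  max(1L, as.integer(round(base * mult)))
}

#' Apply one year of post-fire transitions and aging
#'
#' The annual bookkeeping step after all fires have spread:
#' * burned black/white spruce becomes deciduous at age 0, with a pending
#'   climax-spruce transition (self-return with probability
#'   `spruce_target_prob`) due at a severity-scaled sampled age;
#' * burned deciduous self-replaces at age 0, keeping its climax target but
#'   resampling the due age (repeated burning pushes climax spruce back);
#' * burned tundra self-replaces at age 0;
#' * every unburned fuel pixel ages by one year; an unburned deciduous
#'   pixel whose age reaches its due age becomes its climax spruce class
#'   with age preserved (habitat classification runs on time since fire,
#'   not time in class);
#' * rock/ice never changes.
#'
#' @param state A `landscape_state`.
#' @param burn_mask Logical matrix of pixels burned this year (must exclude
#'   rock/ice).
#' @param fires List of `fire_event`s whose cells partition `burn_mask`;
#'   used only for per-fire severity. May be empty when `burn_mask` is all
#'   `FALSE`.
#' @param params A [succession_params()].
#' @return The advanced `landscape_state` (year incremented by 1).
#' @export
apply_transitions <- function(state, burn_mask, fires, params) {
  stopifnot(inherits(state, "landscape_state"),
            inherits(params, "succession_params"))
  if (!matrix_same_shape(state$veg, burn_mask)) stop("burn mask shape mismatch")
  if (any(burn_mask & state$veg == VEG_ROCK)) stop("burn mask touches rock/ice")

  veg <- state$veg
  age <- state$age
  tgt <- state$sched_target
  due <- state$sched_due

  # per-pixel fire size for severity scaling
  fire_size <- matrix(0, nrow(veg), ncol(veg))
  for (fe in fires) fire_size[fe$cells] <- fe$size

  burned_idx <- which(burn_mask)
  for (cell in burned_idx) {
    v <- veg[cell]
    if (v == VEG_BLACK || v == VEG_WHITE) {
      self_return <- stats::runif(1) < params$spruce_target_prob
      tgt[cell] <- if (self_return) v else (VEG_BLACK + VEG_WHITE - v)
      due[cell] <- sample_transition_time(fire_size[cell], params)
      veg[cell] <- VEG_DECID
    } else if (v == VEG_DECID) {
      if (tgt[cell] == 0L) {
        tgt[cell] <- if (stats::runif(1) < 0.5) VEG_BLACK else VEG_WHITE
      }
      due[cell] <- sample_transition_time(fire_size[cell], params)
    }
    # tundra self-replaces: class unchanged
    age[cell] <- 0L
  }

  unburned_fuel <- !burn_mask & veg != VEG_ROCK
  age[unburned_fuel] <- age[unburned_fuel] + 1L

  mature <- unburned_fuel & veg == VEG_DECID & due > 0L & age >= due
  if (any(mature)) {
    veg[mature] <- tgt[mature]
    tgt[mature] <- 0L
    due[mature] <- 0L
  }

  new_landscape_state(veg, age, year = state$year + 1L,
                      pixel_area = state$pixel_area,
                      sched_target = tgt, sched_due = due)
}
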