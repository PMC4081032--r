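# The stochastic annual fire model: flammability, ignition, spread,
# annual stepping, spin-up and ensembles.

test_that("flammability map follows the logistic x vegetation x fuel form", {
  # hand evaluation: L(.) = 0.5 via zero linear term, tundra scalar 0.2,
  # fuel ramp age 15 / 30 = 0.5 -> 0.05
  land <- uniform_landscape(3, 3, "tundra", age = 15)
  p <- flammability_params(beta0 = 0, beta_t = 0, beta_p = 0,
                           veg_scalar = c(tundra = 0.2, black_spruce = 0.2),
                           fuel_age_scale = 30)
  f <- flammability_map(land, const_climate(3, 3), p)
  expect_equal(unique(as.vector(f)), 0.05, tolerance = 1e-12)

  # rock/ice is always zero; age 0 (fresh burn) carries no fuel
  veg <- matrix("black_spruce", 2, 2)
  veg[1, 1] <- "rock_ice"
  ages <- matrix(c(-1L, 0L, 50L, 10L), 2, 2)
  land2 <- landscape_from(veg, ages)
  f2 <- flammability_map(land2, const_climate(2, 2), flammability_params())
  expect_identical(f2[1, 1], 0)
  expect_identical(f2[2, 1], 0)   # age 0
  expect_gt(f2[1, 2], 0)

  # shape and NA validation
  expect_error(flammability_map(land2, const_climate(3, 3),
                                flammability_params()), "shape")
  bad <- const_climate(2, 2)
  bad$tas[1, 1] <- NA
  expect_error(flammability_map(land2, bad, flammability_params()), "NA")
})

test_that("ignition is Bernoulli per cell with the binomial mean", {
  expect_identical(nrow(ignite(matrix(0, 5, 5))), 0L)

  set.seed(1)
  expect_identical(nrow(ignite(matrix(c(1, 0, 0, 0), 2, 2))), 1L)

  # 50x50 at constant 0.002 over many replicates: mean within 3 SE of 5
  flam <- matrix(0.002, 50, 50)
  set.seed(42)
  counts <- vapply(1:10000, function(i) nrow(ignite(flam)), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 5), 3 * se)

  # the cap subsamples
  set.seed(2)
  expect_lte(nrow(ignite(matrix(1, 4, 4), max_ignitions = 3)), 3)
})

test_that("fire spread is 8-neighborhood reachability-limited", {
  land <- uniform_landscape(5, 5, "black_spruce", age = 100)
  flam <- matrix(1, 5, 5)

  # spread factor 0: a 1-cell fire
  set.seed(1)
  fe0 <- spread_fire(land, flam, c(3, 3),
                     flammability_params(spread_factor = 0))
  expect_identical(nrow(fe0$cells), 1L)
  expect_identical(fe0$size, 1)

  # spread probability 1 everywhere: the whole 5x5 grid burns
  set.seed(1)
  fe1 <- spread_fire(land, flam, c(1, 1),
                     flammability_params(spread_factor = 1))
  expect_identical(nrow(fe1$cells), 25L)

  # middle column rock/ice: the right column is not 8-reachable from the
  # left (column distance 2), so only the left column burns
  veg <- matrix("black_spruce", 3, 3)
  veg[, 2] <- "rock_ice"
  ages <- matrix(100L, 3, 3)
  ages[, 2] <- -1L
  land3 <- landscape_from(veg, ages)
  flam3 <- matrix(1, 3, 3)
  flam3[, 2] <- 0
  set.seed(1)
  fe3 <- spread_fire(land3, flam3, c(1, 1),
                     flammability_params(spread_factor = 1))
  burned <- matrix(FALSE, 3, 3)
  burned[fe3$cells] <- TRUE
  # flood-fill oracle: reachable set from (1,1) on the fuel mask
  reach <- borealfire:::label_components(land3$veg != veg_code("rock_ice"))
  expect_identical(burned, reach == reach[1, 1])
  expect_identical(nrow(fe3$cells), 3L)

  # every fire is connected and avoids rock/ice
  expect_true(borealfire:::is_connected8(burned))
  expect_error(spread_fire(land3, flam3, c(1, 2), flammability_params()),
               "rock/ice|zero")
})

test_that("annual stepping resets burned ages and leaves the rest aging", {
  # zero flammability: no fires, ages increment
  land <- uniform_landscape(6, 6, "tundra", age = 10)
  p0 <- flammability_params(veg_scalar = c(tundra = 0, black_spruce = 0))
  out <- step_year(land, const_climate(6, 6), p0)
  expect_length(out$fires, 0)
  expect_true(all(out$state$age == 11L))
  expect_identical(out$state$year, land$year + 1L)

  # a guaranteed single ignition with spread 0: 1-cell fire, age 0 next year
  veg <- matrix("rock_ice", 4, 4)
  veg[2, 2] <- "tundra"
  ages <- matrix(-1L, 4, 4)
  ages[2, 2] <- 100L
  land1 <- landscape_from(veg, ages)
  p1 <- flammability_params(beta0 = 50, veg_scalar = c(tundra = 1,
                                                       black_spruce = 1),
                            fuel_age_scale = 0, spread_factor = 0)
  set.seed(3)
  out1 <- step_year(land1, const_climate(4, 4), p1)
  expect_length(out1$fires, 1)
  expect_identical(out1$fires[[1]]$cells, cbind(row = 2L, col = 2L))
  expect_identical(out1$state$age[2, 2], 0L)

  # colliding spreads: burned sets disjoint, union equals the burn mask
  land2 <- uniform_landscape(10, 10, "black_spruce", age = 100)
  p2 <- flammability_params(beta0 = 0, beta_t = 0, beta_p = 0,
                            veg_scalar = c(tundra = 0.3, black_spruce = 0.3),
                            fuel_age_scale = 0, spread_factor = 3)
  for (s in 1:5) {
    set.seed(s)
    out2 <- step_year(land2, const_climate(10, 10), p2)
    sizes <- vapply(out2$fires, function(f) nrow(f$cells), integer(1))
    expect_identical(sum(sizes), sum(out2$burn_mask))  # disjoint union
    for (f in out2$fires) {
      m <- matrix(FALSE, 10, 10)
      m[f$cells] <- TRUE
      expect_true(borealfire:::is_connected8(m))
    }
  }
})

test_that("spin-up is deterministic under a seed and a no-op at 0 years", {
  land <- generate_landscape(landscape_config(20, 20, seed = 3))
  smp <- const_sampler()
  expect_identical(spin_up(land, smp, flammability_params(), 0), land)
  a <- spin_up(land, smp, flammability_params(), 15, seed = 7)
  b <- spin_up(land, smp, flammability_params(), 15, seed = 7)
  expect_identical(a, b)
})

test_that("ensembles satisfy their structural invariants", {
  land <- generate_landscape(landscape_config(15, 15, seed = 8))
  cc <- generate_climate(climate_params("warm", seed = 2), 12, 15, 15)

  # zero flammability: burn array all false
  p0 <- flammability_params(veg_scalar = c(tundra = 0, black_spruce = 0,
                                           white_spruce = 0, deciduous = 0))
  e0 <- run_ensemble(land, cc, p0, n_runs = 1, seed = 4, spin_up_years = 2)
  expect_false(any(e0$burn))

  # same seed twice: bit-identical ensembles
  p <- flammability_params()
  e1 <- run_ensemble(land, cc, p, n_runs = 2, seed = 9, spin_up_years = 10)
  e2 <- run_ensemble(land, cc, p, n_runs = 2, seed = 9, spin_up_years = 10)
  expect_identical(e1$burn, e2$burn)
  expect_identical(e1$fires$size_km2, e2$fires$size_km2)

  # burn mask equals the union of the run-year's fire cells; rock/ice never
  # burns
  rock <- land$veg == veg_code("rock_ice")
  for (r in 1:2) {
    for (y in c(1, 6, 12)) {
      rows <- e1$fires[e1$fires$run == r & e1$fires$year == y, ]
      m <- matrix(FALSE, 15, 15)
      for (cl in rows$cells) m[cl] <- TRUE
      expect_identical(m, matrix(e1$burn[r, y, , ], 15, 15))
    }
    rock_burn <- vapply(1:12, function(y) {
      any(matrix(e1$burn[r, y, , ], 15, 15) & rock)
    }, logical(1))
    expect_false(any(rock_burn))
  }

  # tidiers
  td <- tidy(e1)
  expect_identical(nrow(td), 2L * 12L)
  expect_equal(sum(td$area_burned_km2), sum(e1$burn))
  expect_identical(nrow(glance(e1)), 1L)
})

test_that("mean area burned responds monotonically to temperature", {
  # paired seeds at three temperature levels under fixed vegetation
  land <- uniform_landscape(30, 30, "black_spruce", age = 100)
  p <- flammability_params(beta0 = -7.4, beta_t = 0.15,
                           fuel_age_scale = 0, spread_factor = 50)
  burned <- vapply(c(8, 14, 20), function(tmp) {
    rec <- simulate_fire_record(land, const_sampler(t = tmp), p,
                                years = 200, seed = 77)
    mean(vapply(rec$burn_masks, sum, integer(1)))
  }, numeric(1))
  expect_true(all(diff(burned) > 0))
})
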