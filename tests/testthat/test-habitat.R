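# Winter-habitat classification and the ensemble analytics.

test_that("habitat classification is strict on class and age threshold", {
  veg <- matrix(c("black_spruce", "deciduous", "tundra", "rock_ice"), 2, 2)
  ages <- matrix(c(61L, 200L, 60L, -1L), 2, 2)
  land <- landscape_from(veg, ages)
  hab <- classify_winter_habitat(land)
  expect_identical(hab, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))

  # configurable threshold
  hab50 <- classify_winter_habitat(land, habitat_config(age_threshold = 50))
  expect_true(hab50[1, 2])   # tundra at 60 qualifies under >50
  expect_error(habitat_config(age_threshold = 0), "threshold")
})

test_that("habitat series and envelopes match brute-force quantiles", {
  # hand-built 5-run, 4-year ensemble on a 4x4 all-tundra landscape with
  # deterministic snapshot ages
  nr <- 4; nc <- 4
  set.seed(30)
  burn <- array(FALSE, dim = c(5, 4, nr, nc))
  snapshots <- lapply(1:5, function(r) {
    lapply(1:4, function(y) {
      ages <- matrix(sample(40:90, nr * nc, replace = TRUE), nr, nc)
      list(veg = matrix(veg_code("tundra"), nr, nc), age = ages)
    })
  })
  ens <- toy_ensemble(burn, snapshots)
  mask <- structure(list(name = "all", mask = matrix(TRUE, nr, nc)),
                    class = "range_mask")
  hs <- habitat_timeseries(ens, mask)

  # per run-year areas against direct counting
  for (r in 1:5) {
    for (y in 1:4) {
      expected <- sum(snapshots[[r]][[y]]$age > 60)
      got <- hs$areas$total_km2[hs$areas$run == r & hs$areas$year == y]
      expect_identical(got, as.numeric(expected))
    }
  }
  # envelopes against a sort-based oracle
  for (y in 1:4) {
    v <- hs$areas$total_km2[hs$areas$year == y]
    env <- hs$envelope[hs$envelope$year == y, ]
    expect_identical(env$q05, oracle_quantile(v, 0.05))
    expect_identical(env$median, oracle_quantile(v, 0.5))
    expect_identical(env$q95, oracle_quantile(v, 0.95))
    expect_true(env$q05 <= env$median && env$median <= env$q95)
  }

  # single run: the envelope collapses onto the series
  ens1 <- toy_ensemble(array(burn[1, , , ], dim = c(1, 4, nr, nc)),
                       snapshots = snapshots[1])
  hs1 <- habitat_timeseries(ens1, mask)
  expect_identical(hs1$envelope$q05, hs1$areas$total_km2)
  expect_identical(hs1$envelope$q95, hs1$areas$total_km2)
})

test_that("zero-flammability ensembles have constant habitat", {
  land <- uniform_landscape(10, 10, "black_spruce", age = 100)
  cc <- generate_climate(climate_params("warm", seed = 2), 8, 10, 10)
  p0 <- flammability_params(veg_scalar = c(tundra = 0, black_spruce = 0,
                                           white_spruce = 0, deciduous = 0))
  ens <- run_ensemble(land, cc, p0, n_runs = 2, seed = 3,
                      spin_up_years = 0)
  mask <- structure(list(name = "all", mask = matrix(TRUE, 10, 10)),
                    class = "range_mask")
  hs <- habitat_timeseries(ens, mask)
  expect_true(all(hs$areas$total_km2 == 100))
  expect_true(all(hs$areas$spruce_km2 == 100))
})

test_that("representative-run selection matches the exhaustive oracle", {
  # a run identical to the per-year median series wins with r = 1
  m2 <- rbind(c(1, 2, 3, 4), c(0, 5, 1, 6), c(4, 0, 9, 2))
  expect_equal(apply(m2, 2, stats::median), m2[1, ])
  rr <- representative_run(m2)
  expect_identical(rr$run, 1L)
  expect_equal(rr$r, 1)

  # 3x4 toy matrix against the brute-force oracle
  toy <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 2, 3, 5))
  got <- representative_run(toy)
  orc <- oracle_representative_run(toy)
  expect_identical(got$run, orc$run)
  expect_equal(got$r, orc$r)
  expect_equal(got$all_r, orc$all_r)

  # ties break to the lower run index
  tie <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  expect_identical(representative_run(tie)$run, 1L)

  # degenerate inputs
  expect_error(representative_run(matrix(1, 3, 4)), "constant")
  expect_error(representative_run(matrix(1:4, 1, 4)), "2 runs")

  # property: the winner's r is >= every other run's r
  set.seed(77)
  for (i in 1:5) {
    mm <- matrix(rpois(5 * 8, 10), 5, 8)
    res <- representative_run(mm)
    expect_true(all(res$r >= res$all_r, na.rm = TRUE))
  }
})

test_that("relative flammability is the mean burn indicator", {
  set.seed(8)
  burn <- array(runif(3 * 4 * 5 * 5) < 0.3, dim = c(3, 4, 5, 5))
  ens <- toy_ensemble(burn)
  rf <- relative_flammability(ens)
  expect_equal(rf$map, oracle_relative_flammability(burn))
  expect_true(all(rf$map >= 0 & rf$map <= 1))

  # counting example: a pixel burned in 2 of 12 run-years
  burn2 <- array(FALSE, dim = c(3, 4, 2, 2))
  burn2[1, 2, 1, 1] <- TRUE
  burn2[3, 4, 1, 1] <- TRUE
  rf2 <- relative_flammability(toy_ensemble(burn2))
  expect_equal(rf2$map[1, 1], 2 / 12)
  expect_equal(rf2$map[2, 2], 0)
})

test_that("top-flammability masks include threshold ties", {
  # strictly increasing values: exactly the top 20
  m <- matrix(1:100, 10, 10)
  top <- top_flammability_mask(m, 0.2)
  expect_identical(sum(top), 20L)
  expect_true(all(m[top] > 80))

  # all-equal map: the whole fuel domain
  expect_true(all(top_flammability_mask(matrix(0.5, 5, 5), 0.2)))

  # toy map with ties at the threshold vs the sort-based oracle
  vals <- c(0, 0, 1, 1, 2, 2, 2, 3, 3, 5)
  mt <- matrix(vals, 2, 5)
  expect_identical(top_flammability_mask(mt, 0.3),
                   oracle_top_mask(mt, 0.3))

  # fuel-mask restriction: quantile over fuel pixels only
  fuel <- matrix(TRUE, 2, 5)
  fuel[1, 1] <- FALSE
  expect_identical(top_flammability_mask(mt, 0.3, fuel_mask = fuel),
                   oracle_top_mask(mt, 0.3, fuel))

  expect_error(top_flammability_mask(mt, 0), "fraction")
})

test_that("range overlaps and scenario differences are element-wise", {
  rg <- matrix(FALSE, 10, 100)
  rg[1:10, 1:100] <- TRUE           # 1000-pixel range
  flag <- matrix(FALSE, 10, 100)
  flag[1, 1:89] <- TRUE             # 89 flagged pixels inside
  expect_equal(range_overlap_percent(flag, rg), 8.9)

  expect_equal(range_overlap_percent(matrix(FALSE, 2, 2),
                                     matrix(TRUE, 2, 2)), 0)
  expect_equal(range_overlap_percent(matrix(TRUE, 2, 2),
                                     matrix(c(TRUE, FALSE, TRUE, FALSE),
                                            2, 2)), 100)
  expect_error(range_overlap_percent(matrix(TRUE, 2, 2),
                                     matrix(FALSE, 2, 2)), "empty")

  a <- matrix(runif(25), 5, 5)
  d0 <- flammability_difference(a, a)
  expect_true(all(d0$diff == 0))
  d1 <- flammability_difference(a, a + 0.1)
  expect_equal(unique(round(as.vector(d1$diff), 12)), 0.1)
  b <- matrix(runif(25), 5, 5)
  expect_equal(flammability_difference(a, b)$diff, b - a)
  expect_identical(d1$convention, "hot - warm")
})

test_that("percent change and composition follow the reporting rules", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 150), 50)
  expect_error(percent_change(0, 10), "area_start")

  # rounding helper: integers at |x| >= 1, one decimal below
  expect_equal(format_percent_change(5.06), 5)
  expect_equal(format_percent_change(-11.03), -11)
  expect_equal(format_percent_change(0.71), 0.7)
  expect_equal(format_percent_change(-0.44), -0.4)

  # composition worked example: (890.2, 110.8) -> 88.9 / 11.1
  hs <- structure(list(
    areas = tibble::tibble(run = 1L, year = 1L, range = "r",
                           tundra_km2 = 890.2, spruce_km2 = 110.8,
                           total_km2 = 1001),
    envelope = NULL, pixel_area = 1), class = "habitat_summary")
  comp <- composition_percent(hs)
  expect_equal(round(comp$tundra_pct, 1), 88.9)
  expect_equal(round(comp$spruce_pct, 1), 11.1)

  hs$areas$total_km2 <- 0
  expect_error(suppressWarnings(composition_percent(hs)), "no habitat")
})

test_that("forcing terminal burns cannot increase habitat", {
  set.seed(41)
  nr <- 6; nc <- 6
  ages <- matrix(sample(30:120, nr * nc, replace = TRUE), nr, nc)
  snap <- list(veg = matrix(veg_code("tundra"), nr, nc), age = ages)
  base_area <- sum(classify_winter_habitat(snap))
  # burn a subset in the final year: those ages drop to 0
  snap2 <- snap
  burn_cells <- sample(nr * nc, 10)
  snap2$age[burn_cells] <- 0L
  expect_lte(sum(classify_winter_habitat(snap2)), base_area)
})
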