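Package: borealfire
Title: Climate-Driven Fire-Succession Simulation and Caribou Winter-Habitat Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A stochastic annual lattice model of wildfire ignition, spread,
    and post-fire vegetation succession for boreal and arctic landscapes
    (rock/ice, tundra, black spruce, white spruce, deciduous), driven by
    contrasting climate trajectories. Includes a synthetic-data module for
    landscapes, two-scenario climate cubes, herd-range masks and historical
    fire records; fire-regime statistics and calibration diagnostics; and
    winter-habitat analytics for migratory tundra caribou (lichen-producing
    spruce and tundra stands older than 60 years): habitat time series with
    percentile envelopes, representative-run selection, relative-flammability
    mapping, top-flammability masks, range overlaps and scenario differencing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
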