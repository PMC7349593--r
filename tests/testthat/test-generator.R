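test_that("default scenario matches the documented campaign layout", {
  cfg <- default_scenario()
  expect_s3_class(cfg, "generator_config")
  expect_equal(sum(cfg$bottles_per_class), 28)
  expect_equal(cfg$bottles_per_class[["HQ"]], 5)
  expect_equal(cfg$bottles_per_class[["AQ"]], 4)
  expect_equal(cfg$bottles_per_class[["LQ"]], 13)
  expect_equal(cfg$bottles_per_class[["Ea"]], 6)
  expect_equal(cfg$phase_durations_s, c(10, 80, 90))
  expect_equal(cfg$sampling_rate_hz, 18.5)
  # AQ/Ea overlap by design: type-wise amplitude log-ratios within one
  # bottle-effect sd; HQ and LQ far apart
  lr <- abs(log(cfg$amplitude[, "AQ"] / cfg$amplitude[, "Ea"]))
  expect_true(all(lr < cfg$bottle_effect_sd))
  expect_true(all(cfg$amplitude[, "LQ"] / cfg$amplitude[, "HQ"] > 2))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error({cfg <- default_scenario(); cfg$amplitude <- matrix(1, 2, 4)
                validate_generator_config(cfg)}, "3 x 4")
  bad_tau <- default_scenario()
  expect_error({bad_tau$tau_ads_s[1, 1] <- -5; validate_generator_config(bad_tau)},
               "positive")
  expect_error({cfg <- default_scenario(); cfg$sensor_types <- c(1L,2L,3L,2L,1L,3L)
                validate_generator_config(cfg)}, "share")
  expect_error({cfg <- default_scenario()
                names(cfg$bottles_per_class)[1] <- "XX"
                validate_generator_config(cfg)}, "classes")
  expect_error(cv_config(test_fraction = 1.2), "test_fraction")
})

test_that("noise-free kinetics follow the first-order conductance model", {
  cfg <- noise_free(default_scenario())
  m <- generate_measurement(cfg, "LQ", bottle_factor = 1, seed = 1)
  G <- 1 / m$resistance
  idx <- enose:::phase_indices(m$time_s, m$phase_bounds_s)
  for (s in 1:6) {
    type <- cfg$sensor_types[s]
    A <- cfg$amplitude[type, "LQ"]
    tau <- cfg$tau_ads_s[type, "LQ"]
    G0 <- cfg$baseline_conductance[s]
    expect_equal(G[idx$baseline, s], rep(G0, length(idx$baseline)))
    # closed-form value at the end of adsorption
    t_end <- m$time_s[max(idx$ads)] - cfg$phase_durations_s[1]
    expect_equal(G[max(idx$ads), s] / G0, 1 + A * (1 - exp(-t_end / tau)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # long-time limit of the adsorption law is 1 + A
    expect_lt(abs(G[max(idx$ads), s] / G0 - (1 + A)), A)
    # monotone rise then monotone decay
    expect_true(all(diff(G[idx$ads, s]) >= -1e-12))
    expect_true(all(diff(G[idx$des, s]) <= 1e-12))
    # continuity at the adsorption/desorption boundary
    expect_equal(G[max(idx$ads), s], G[min(idx$des), s],
                 tolerance = 2 / cfg$sampling_rate_hz / tau + 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("zero-amplitude class gives a flat response at the baseline level", {
  cfg <- noise_free(default_scenario())
  cfg$amplitude[, "HQ"] <- 0
  m <- generate_measurement(cfg, "HQ", bottle_factor = 1, seed = 3)
  for (s in 1:6) {
    expect_equal(m$resistance[, s],
                 rep(1 / cfg$baseline_conductance[s], length(m$time_s)),
                 tolerance = 1e-5)
  }
})

test_that("measurement generation is deterministic given a seed", {
  cfg <- default_scenario()
  m1 <- generate_measurement(cfg, "AQ", 1.1, seed = 5)
  m2 <- generate_measurement(cfg, "AQ", 1.1, seed = 5)
  m3 <- generate_measurement(cfg, "AQ", 1.1, seed = 6)
  expect_identical(m1$resistance, m2$resistance)
  expect_false(identical(m1$resistance, m3$resistance))
  expect_error(generate_measurement(cfg, "AQ", -1), "bottle_factor")
  expect_error(generate_measurement(cfg, "XX", 1), "class_label")
})

test_that("generated datasets have the configured cohort structure", {
  ds <- small_dataset()
  cfg <- ds$config_used
  expect_equal(length(unique(ds$groups)), sum(cfg$bottles_per_class))
  expect_equal(length(ds$measurements), length(ds$labels))
  expect_equal(length(ds$measurements), length(ds$groups))
  counts <- table(ds$groups)
  expect_true(all(counts >= cfg$samples_per_bottle[1]))
  expect_true(all(counts <= cfg$samples_per_bottle[2]))
  # every bottle belongs to exactly one class
  expect_true(all(rowSums(table(ds$groups, ds$labels) > 0) == 1))
  # all resistances strictly positive
  expect_true(all(vapply(ds$measurements, function(m) all(m$resistance > 0), TRUE)))
})

test_that("default cohort has 28 bottles and 10-12 samples each", {
  cfg <- default_scenario(seed = 1)
  cfg$phase_durations_s <- c(3, 6, 6)   # shorten curves; cohort is what matters
  cfg$sampling_rate_hz <- 2
  ds <- generate_dataset(cfg)
  expect_equal(length(unique(ds$groups)), 28)
  expect_true(all(table(ds$groups) %in% 10:12))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$measurements[[1]]$resistance, ds2$measurements[[1]]$resistance)
  cfg$seed <- 2L
  ds3 <- generate_dataset(cfg)
  expect_equal(length(unique(ds3$groups)), 28)
  expect_false(identical(ds$measurements[[1]]$resistance,
                         ds3$measurements[[1]]$resistance))
})

test_that("bottle effect induces within-bottle correlation of amplitudes", {
  cfg <- default_scenario(seed = 8)
  cfg <- noise_free(cfg)
  cfg$bottle_effect_sd <- 0.5
  cfg$sample_noise_sd <- 0.02
  cfg$phase_durations_s <- c(5, 30, 30)
  cfg$sampling_rate_hz <- 4
  ds <- generate_dataset(cfg)
  keep <- ds$labels == "LQ"
  amp <- vapply(ds$measurements[keep], function(m) {
    g <- baseline_normalize(m)$g[, 1]
    max(g) - 1
  }, 0)
  grp <- ds$groups[keep]
  between <- stats::var(tapply(amp, grp, mean))
  within <- mean(tapply(amp, grp, stats::var))
  expect_gt(between, within)
})

test_that("generator config YAML round-trips", {
  cfg <- default_scenario(seed = 9)
  path <- tempfile(fileext = ".yml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$amplitude, cfg$amplitude)
  expect_equal(cfg2$tau_des_s, cfg$tau_des_s)
  expect_equal(cfg2$bottles_per_class, cfg$bottles_per_class)
  expect_equal(cfg2$sampling_rate_hz, cfg$sampling_rate_hz)
  expect_equal(cfg2$seed, cfg$seed)
})
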