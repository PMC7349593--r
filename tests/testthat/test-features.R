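test_that("the feature catalogue has exactly 828 structured ids", {
  ids <- feature_ids()
  expect_equal(nrow(ids), 828)
  expect_equal(anyDuplicated(ids$id), 0)
  expect_equal(nrow(feature_ids(sensors = 3)), 138)
  expect_equal(nrow(feature_ids(sensors = 3, signals = "G", segments = "ads")), 23)
  # 23 types per (sensor, signal, segment) cell
  expect_true(all(table(ids$sensor, ids$signal, ids$segment) == 23))
  expect_match(ids$id[1], "^S1\\|R\\|full\\|")
})

test_that("the EMA recurrence matches hand iteration", {
  expect_equal(ema_transform(c(0, 1, 2), alpha = 1), c(0, 1, 1))
  expect_equal(ema_transform(rep(3.7, 10), alpha = 0.4), rep(0, 10))
  x <- c(0, rep(1, 6))
  expect_equal(ema_transform(x, alpha = 0.5),
               c(0, 0.5, 0.25, 0.125, 0.0625, 0.03125, 0.015625))
  expect_error(ema_transform(x, alpha = 0), "alpha")
  expect_error(ema_transform(x, alpha = 1.5), "alpha")
})

test_that("fractional-range crossing times interpolate correctly", {
  ramp <- make_segment(seq(0, 1, length.out = 11), dt = 1)  # 0 -> 1 over 10 s
  expect_equal(crossing_time(ramp, 0.5), 5)
  expect_equal(crossing_time(ramp, 0.25), 2.5)
  flat <- make_segment(rep(2, 20))
  expect_equal(crossing_time(flat, 0.5), 0)
  # noiseless exponential rise, tau = 10 s: the half-range time is 10 ln 2
  t <- seq(0, 100, by = 0.05)
  expc <- make_segment(1 - exp(-t / 10), dt = 0.05)
  expect_equal(crossing_time(expc, 0.5), 10 * log(2), tolerance = 1e-4)
  # net-negative response uses the minimum as the extremum
  fall <- make_segment(seq(1, 0, length.out = 11), dt = 1)
  expect_equal(crossing_time(fall, 0.5), 5)
})

test_that("exponential fits recover known parameters", {
  t <- seq(0, 90, by = 1 / 18.5)
  seg <- make_segment(1 - 0.5 * exp(-t / 20), dt = 1 / 18.5)
  p <- fit_exponential(seg)
  expect_equal(p[["c"]], 1, tolerance = 1e-6)
  expect_equal(p[["A"]], -0.5, tolerance = 1e-5)
  expect_equal(p[["tau_s"]], 20, tolerance = 1e-5)
  const <- make_segment(rep(4.2, 50))
  pc <- fit_exponential(const)
  expect_equal(pc[["A"]], 0, tolerance = 1e-8)
  expect_equal(pc[["c"]], 4.2, tolerance = 1e-8)
  # 1% observation noise: tau recovered within 10% (fixed seed)
  set.seed(99)
  yv <- 1 + 0.8 * exp(-t / 30) + rnorm(length(t), 0, 0.01)
  pn <- fit_exponential(make_segment(yv, dt = 1 / 18.5))
  expect_lt(abs(pn[["tau_s"]] - 30) / 30, 0.1)
  expect_error(fit_exponential(make_segment(1:4)), "5 samples")
})

test_that("segment_features returns the 23 catalogue values in order", {
  v <- segment_features(make_segment(rep(1, 100), dt = 1))
  expect_length(v, 23)
  expect_identical(names(v), enose:::FEATURE_TYPES)
  expect_equal(v[["final"]], 1)
  expect_equal(v[["extremum"]], 1)
  expect_equal(v[["mean"]], 1)
  expect_equal(v[["sd"]], 0)
  expect_equal(v[["skewness"]], 0)
  expect_equal(v[["kurtosis"]], 0)
  expect_equal(v[["integral"]], 100)
  expect_equal(unname(v[grep("^ema", names(v))]), rep(0, 6))
  expect_equal(v[["dmax"]], 0)
  expect_equal(v[["t_frac50"]], 0)
  expect_equal(v[["exp_c"]], 1, tolerance = 1e-8)
  expect_true(all(is.finite(v)))
})

test_that("constant shifts move location features and leave shape features", {
  set.seed(14)
  t <- seq(0, 30, by = 0.2)
  y <- 1 + 2 * (1 - exp(-t / 6)) + rnorm(length(t), 0, 0.02)
  a <- segment_features(make_segment(y, dt = 0.2))
  b <- segment_features(make_segment(y + 5, dt = 0.2))
  shape <- c("sd", "skewness", "kurtosis", grep("^ema|^dm|^t_", names(a), value = TRUE))
  expect_equal(a[shape], b[shape], tolerance = 1e-6)
  expect_equal(b[["mean"]], a[["mean"]] + 5)
  expect_equal(b[["final"]], a[["final"]] + 5)
  expect_equal(b[["extremum"]], a[["extremum"]] + 5)
  expect_equal(b[["integral"]], a[["integral"]] + 5 * length(y) * 0.2)
  expect_equal(b[["exp_c"]], a[["exp_c"]] + 5, tolerance = 1e-4)
})

test_that("the full-curve integral is the sum of the phase integrals", {
  ds <- small_dataset()
  nc <- baseline_normalize(ds$measurements[[3]])
  for (s in c(1, 4)) for (sig in c("R", "G")) {
    fi <- segment_features(segment_curve(nc, s, sig, "full"))[["integral"]]
    ai <- segment_features(segment_curve(nc, s, sig, "ads"))[["integral"]]
    di <- segment_features(segment_curve(nc, s, sig, "des"))[["integral"]]
    expect_equal(fi, ai + di, tolerance = 1e-12)
  }
})

test_that("extract_features produces the advertised vector lengths", {
  m <- small_dataset()$measurements[[1]]
  v_all <- extract_features(m)
  expect_length(v_all, 828)
  expect_true(all(is.finite(v_all)))
  expect_length(extract_features(m, sensors = 2), 138)
  expect_length(extract_features(m, sensors = 2, signals = "G", segments = "ads"), 23)
  expect_identical(names(v_all), feature_ids()$id)
  # determinism
  expect_identical(v_all, extract_features(m))
})

test_that("feature tables carry labels and groups and stay finite", {
  tab <- small_table()
  ds <- small_dataset()
  expect_equal(dim(tab$values), c(length(ds$measurements), 828))
  expect_equal(anyDuplicated(tab$info$id), 0)
  expect_equal(as.character(tab$labels), as.character(ds$labels))
  expect_equal(tab$groups, ds$groups)
  expect_true(all(is.finite(tab$values)))
  tab2 <- build_feature_table(ds)
  expect_identical(tab$values, tab2$values)
})

test_that("structural subsetting restricts columns as requested", {
  tab <- small_table()
  g_ads <- subset_features(tab, signals = "G", segments = "ads")
  expect_equal(ncol(g_ads$values), 6 * 23)
  expect_true(all(g_ads$info$signal == "G"))
  expect_true(all(g_ads$info$segment == "ads"))
  s1 <- subset_features(tab, sensors = 1)
  expect_equal(ncol(s1$values), 138)
  expect_error(subset_features(tab, sensors = 99), "no features")
})

test_that("feature tables round-trip through CSV", {
  tab <- subset_features(small_table(), sensors = 1, signals = "G")
  path <- tempfile(fileext = ".csv")
  write_feature_table_csv(tab, path)
  tab2 <- read_feature_table_csv(path)
  expect_equal(tab2$values, tab$values, tolerance = 1e-12)
  expect_equal(as.character(tab2$labels), as.character(tab$labels))
  expect_equal(tab2$groups, tab$groups)
  expect_equal(tab2$info$sensor, tab$info$sensor)
  expect_equal(tab2$info$type, tab$info$type)
})
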