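# Shared fixtures, built once per test run and memoized across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

small_dataset <- function() {
  fixture("small_dataset", function() generate_dataset(scenario_small(seed = 42)))
}

small_table <- function() {
  fixture("small_table", function() build_feature_table(small_dataset()))
}

# A hand-built feature table with a controllable signal, for classifier and
# selection tests: 12 bottles (3 per class), 5 samples each.
make_toy_table <- function(n_noise = 4, signal_sd = 0.3, seed = 7,
                           samples_per_bottle = 5, bottles_per_class = 3) {
  set.seed(seed)
  classes <- c("HQ", "AQ", "LQ", "Ea")
  labels <- groups <- character(0)
  for (ci in seq_along(classes)) {
    for (b in seq_len(bottles_per_class)) {
      bid <- sprintf("%s_b%d", classes[ci], b)
      labels <- c(labels, rep(classes[ci], samples_per_bottle))
      groups <- c(groups, rep(bid, samples_per_bottle))
    }
  }
  n <- length(labels)
  ci <- match(labels, classes)
  X <- cbind(signal = ci + rnorm(n, 0, signal_sd),
             matrix(rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise)))))
  feature_table(X, labels = labels, groups = groups)
}

# Table whose informative signal comes in redundant correlated copies, so
# filter rankings pile up on near-duplicates while the wrapper can combine
# complementary ones.
make_redundant_table <- function(seed = 11, n_copies = 6, n_noise = 12) {
  set.seed(seed)
  classes <- c("HQ", "AQ", "LQ", "Ea")
  labels <- groups <- character(0)
  for (ci in seq_along(classes)) {
    for (b in 1:4) {
      labels <- c(labels, rep(classes[ci], 5))
      groups <- c(groups, rep(sprintf("%s_b%d", classes[ci], b), 5))
    }
  }
  n <- length(labels)
  ci <- match(labels, classes)
  # two weak complementary latent directions: neither alone separates all
  # classes, together they do
  lat1 <- (ci %in% c(3, 4)) + rnorm(n, 0, 0.4)
  lat2 <- (ci %in% c(2, 4)) + rnorm(n, 0, 0.4)
  copies1 <- sapply(seq_len(n_copies), function(i) lat1 + rnorm(n, 0, 0.1))
  copies2 <- sapply(seq_len(2), function(i) lat2 + rnorm(n, 0, 0.35))
  X <- cbind(copies1, copies2, matrix(rnorm(n * n_noise), n, n_noise))
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  feature_table(X, labels = labels, groups = groups)
}

# Noise-free single-sensor curve segment on a uniform grid, for feature-op
# unit tests.
make_segment <- function(values, dt = 1, sensor = 1L, signal = "G",
                         segment = "ads") {
  structure(list(sensor = sensor, signal = signal, segment = segment,
                 values = as.numeric(values),
                 time_s = (seq_along(values) - 1) * dt, dt_s = dt),
            class = "curve_segment")
}

noise_free <- function(cfg) {
  cfg$sensor_gain_sd <- 0
  cfg$bottle_effect_sd <- 0
  cfg$sample_noise_sd <- 0
  cfg$obs_noise_sd <- 0
  cfg
}
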