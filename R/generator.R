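#' Generator configuration for synthetic e-nose measurements
#'
#' Describes one simulated measurement campaign: the acquisition protocol
#' (sampling rate and phase durations), the cohort structure (bottles per odor
#' class and samples per bottle), the kinetic parameters of each sensor type
#' for each class, and the noise model. Defaults follow the wine-spoilage
#' campaign layout: a 6-sensor MOX array sampled at 18.5 Hz with a 10 s pure-air
#' baseline, 80 s gas adsorption, and 90 s desorption, and four odor classes
#' (high-, average-, low-quality wine and diluted ethanol).
#'
#' The kinetic model is first-order in conductance: during adsorption the
#' relative conductance rises as \eqn{G/G_0 = 1 + A (1 - e^{-t/\tau_{ads}})}
#' and during desorption it relaxes back exponentially with \eqn{\tau_{des}},
#' continuous at the phase boundary. The response amplitude of sensor \eqn{s}
#' to a sample of class \eqn{c} is
#' \eqn{A = g_s \, a(\mathrm{type}(s), c) \, b \, (1 + \epsilon)} where
#' \eqn{g_s} is a per-sensor-instance gain (lognormal, one draw per dataset),
#' \eqn{b} a per-bottle concentration factor (lognormal, one draw per bottle),
#' and \eqn{\epsilon} a per-measurement amplitude jitter shared by all six
#' sensors. Observation noise is multiplicative Gaussian on conductance.
#'
#' @param sampling_rate_hz sampling frequency in Hz.
#' @param phase_durations_s numeric length 3: baseline, adsorption, desorption
#'   durations in seconds.
#' @param bottles_per_class named integer vector over `HQ, AQ, LQ, Ea`.
#' @param samples_per_bottle integer range (length 2); per-bottle counts are
#'   drawn uniformly from it.
#' @param sensor_types integer length 6 mapping sensor slots to the 3 sensor
#'   types; paired slots (1,4), (2,5), (3,6) share a type.
#' @param baseline_conductance positive numeric length 6, baseline G0 per
#'   sensor slot (arbitrary consistent units).
#' @param amplitude 3 x 4 matrix, mean relative conductance rise
#'   `a(type, class)`; columns named by class.
#' @param tau_ads_s,tau_des_s 3 x 4 matrices of adsorption/desorption time
#'   constants in seconds per (type, class).
#' @param sensor_gain_sd lognormal sd of per-sensor-instance gain.
#' @param bottle_effect_sd lognormal sd of the per-bottle concentration factor.
#' @param sample_noise_sd relative sd of per-measurement amplitude jitter.
#' @param obs_noise_sd relative sd of per-point multiplicative noise on G.
#' @param seed integer seed for [generate_dataset()].
#' @return An object of class `generator_config`.
#' @seealso [default_scenario()], [generate_dataset()]
#' @export
generator_config <- function(sampling_rate_hz = 18.5,
                             phase_durations_s = c(10, 80, 90),
                             bottles_per_class = c(HQ = 5L, AQ = 4L, LQ = 13L, Ea = 6L),
                             samples_per_bottle = c(10L, 12L),
                             sensor_types = c(1L, 2L, 3L, 1L, 2L, 3L),
                             baseline_conductance = c(0.008, 0.020, 0.015,
                                                      0.010, 0.018, 0.013),
                             amplitude,
                             tau_ads_s,
                             tau_des_s,
                             sensor_gain_sd = 0.2,
                             bottle_effect_sd = 0.15,
                             sample_noise_sd = 0.05,
                             obs_noise_sd = 0.005,
                             seed = 1L) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    phase_durations_s = as.numeric(phase_durations_s),
    bottles_per_class = bottles_per_class,
    samples_per_bottle = as.integer(samples_per_bottle),
    sensor_types = as.integer(sensor_types),
    baseline_conductance = as.numeric(baseline_conductance),
    amplitude = amplitude,
    tau_ads_s = tau_ads_s,
    tau_des_s = tau_des_s,
    sensor_gain_sd = sensor_gain_sd,
    bottle_effect_sd = bottle_effect_sd,
    sample_noise_sd = sample_noise_sd,
    obs_noise_sd = obs_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$sampling_rate_hz) || cfg$sampling_rate_hz <= 0) {
    stopf("sampling_rate_hz must be a positive number")
  }
  if (length(cfg$phase_durations_s) != 3L || any(cfg$phase_durations_s <= 0)) {
    stopf("phase_durations_s must be 3 strictly positive durations")
  }
  if (!setequal(names(cfg$bottles_per_class), CLASS_LEVELS)) {
    stopf("bottles_per_class must cover exactly the classes %s",
          paste(CLASS_LEVELS, collapse = ", "))
  }
  if (any(cfg$bottles_per_class < 1L)) stopf("bottles_per_class must be >= 1")
  if (length(cfg$samples_per_bottle) != 2L ||
      cfg$samples_per_bottle[1] > cfg$samples_per_bottle[2] ||
      cfg$samples_per_bottle[1] < 1L) {
    stopf("samples_per_bottle must be an increasing positive integer range")
  }
  if (length(cfg$sensor_types) != 6L || !all(cfg$sensor_types %in% 1:3)) {
    stopf("sensor_types must assign 6 slots to types 1..3")
  }
  for (pair in list(c(1, 4), c(2, 5), c(3, 6))) {
    if (cfg$sensor_types[pair[1]] != cfg$sensor_types[pair[2]]) {
      stopf("paired sensor slots (%d,%d) must share a sensor type", pair[1], pair[2])
    }
  }
  if (length(cfg$baseline_conductance) != 6L || any(cfg$baseline_conductance <= 0)) {
    stopf("baseline_conductance must be 6 positive values")
  }
  for (nm in c("amplitude", "tau_ads_s", "tau_des_s")) {
    M <- cfg[[nm]]
    if (!is.matrix(M) || !identical(dim(M), c(3L, 4L)) ||
        !setequal(colnames(M), CLASS_LEVELS)) {
      stopf("%s must be a 3 x 4 matrix with columns named %s", nm,
            paste(CLASS_LEVELS, collapse = ", "))
    }
    if (nm != "amplitude" && any(M <= 0)) stopf("%s must be strictly positive", nm)
    if (nm == "amplitude" && any(M < 0)) stopf("%s must be nonnegative", nm)
  }
  for (nm in c("sensor_gain_sd", "bottle_effect_sd", "sample_noise_sd", "obs_noise_sd")) {
    if (cfg[[nm]] < 0) stopf("%s must be nonnegative", nm)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  sampling: %.3g Hz; phases (baseline/ads/des): %s s\n",
              x$sampling_rate_hz, paste(x$phase_durations_s, collapse = "/")))
  cat(sprintf("  cohort: %s (total %d bottles), %d-%d samples/bottle\n",
              paste(sprintf("%s:%d", names(x$bottles_per_class), x$bottles_per_class),
                    collapse = " "),
              sum(x$bottles_per_class), x$samples_per_bottle[1], x$samples_per_bottle[2]))
  cat(sprintf("  noise: gain %.3g, bottle %.3g, sample %.3g, obs %.3g; seed %d\n",
              x$sensor_gain_sd, x$bottle_effect_sd, x$sample_noise_sd,
              x$obs_noise_sd, x$seed))
  invisible(x)
}

kinetics_matrix <- function(v) {
  matrix(v, nrow = 3, ncol = 4, byrow = TRUE,
         dimnames = list(NULL, CLASS_LEVELS))
}

#' Default synthetic scenario
#'
#' The documented default measurement campaign: 28 bottles (5 HQ, 4 AQ, 13 LQ,
#' 6 Ea), 10-12 samples each, phases (10, 80, 90) s at 18.5 Hz. Amplitude
#' patterns separate HQ from LQ clearly, while the AQ and Ea patterns are set
#' to overlap (their type-wise amplitude means differ by less than one
#' bottle-effect sd), so those two classes are distinguishable mainly through
#' their slightly different response kinetics -- mirroring the overlap between
#' average-quality wine and diluted ethanol seen in real recordings.
#'
#' @param seed integer seed stored in the config.
#' @return A [generator_config()].
#' @export
default_scenario <- function(seed = 1L) {
  generator_config(
    #              HQ    AQ    LQ    Ea
    amplitude = kinetics_matrix(c(
      2.0, 3.5, 6.0, 3.8,    # type 1: MQ-3-like, alcohol-sensitive
      1.0, 1.8, 3.5, 1.7,    # type 2: MQ-4-like
      0.8, 1.5, 2.5, 1.6)),  # type 3: MQ-6-like
    tau_ads_s = kinetics_matrix(c(
      18, 15, 12, 14,
      22, 19, 16, 18,
      25, 22, 19, 21)),
    tau_des_s = kinetics_matrix(c(
      30, 26, 22, 25,
      36, 31, 27, 30,
      42, 37, 32, 35)),
    seed = seed
  )
}

#' Scenario with a single informative sensor type
#'
#' Only sensor type 1 (slots 1 and 4) carries class information: the other two
#' types have class-independent amplitudes and time constants. Used to study
#' sensor-array reduction when the class signal is concentrated in one sensor.
#'
#' @inheritParams default_scenario
#' @return A [generator_config()].
#' @export
scenario_single_informative_sensor <- function(seed = 1L) {
  generator_config(
    amplitude = kinetics_matrix(c(
      2.0, 3.5, 6.0, 3.8,
      2.0, 2.0, 2.0, 2.0,
      1.5, 1.5, 1.5, 1.5)),
    tau_ads_s = kinetics_matrix(c(
      18, 15, 12, 14,
      19, 19, 19, 19,
      23, 23, 23, 23)),
    tau_des_s = kinetics_matrix(c(
      30, 26, 22, 25,
      32, 32, 32, 32,
      38, 38, 38, 38)),
    seed = seed
  )
}

#' Scenario where only desorption kinetics separate the classes
#'
#' Amplitudes and adsorption time constants are identical across classes; only
#' the desorption time constants differ. Features computed from the adsorption
#' phase alone are then uninformative, while the desorption phase separates
#' the classes well. The cohort is balanced (6 bottles per class) so the
#' chance-level accuracy of an uninformative model is exactly 1/4.
#'
#' @inheritParams default_scenario
#' @return A [generator_config()].
#' @export
scenario_desorption_only <- function(seed = 1L) {
  generator_config(
    bottles_per_class = c(HQ = 6L, AQ = 6L, LQ = 6L, Ea = 6L),
    amplitude = kinetics_matrix(c(
      3.0, 3.0, 3.0, 3.0,
      2.0, 2.0, 2.0, 2.0,
      1.5, 1.5, 1.5, 1.5)),
    tau_ads_s = kinetics_matrix(c(
      15, 15, 15, 15,
      18, 18, 18, 18,
      21, 21, 21, 21)),
    tau_des_s = kinetics_matrix(c(
      12, 24, 45, 80,
      14, 28, 52, 90,
      16, 32, 60, 100)),
    seed = seed
  )
}

#' Small, fast scenario for examples and smoke runs
#'
#' Same structure as [default_scenario()] but with a reduced cohort
#' (2 bottles per class, 3-4 samples each) and a coarser, shorter acquisition
#' (5 Hz; 6/20/24 s phases). Kinetic time constants are scaled down with the
#' phase durations so the curves keep their shape.
#'
#' @inheritParams default_scenario
#' @return A [generator_config()].
#' @export
scenario_small <- function(seed = 1L) {
  cfg <- default_scenario(seed = seed)
  cfg$sampling_rate_hz <- 5
  cfg$phase_durations_s <- c(6, 20, 24)
  cfg$bottles_per_class <- c(HQ = 2L, AQ = 2L, LQ = 2L, Ea = 2L)
  cfg$samples_per_bottle <- c(3L, 4L)
  cfg$tau_ads_s <- cfg$tau_ads_s / 4
  cfg$tau_des_s <- cfg$tau_des_s / 4
  validate_generator_config(cfg)
  cfg
}

phase_grid <- function(cfg) {
  fs <- cfg$sampling_rate_hz
  n <- round(sum(cfg$phase_durations_s) * fs)
  t <- (seq_len(n) - 1) / fs
  list(time_s = t,
       baseline_end = cfg$phase_durations_s[1],
       adsorption_end = cfg$phase_durations_s[1] + cfg$phase_durations_s[2])
}

#' Generate one synthetic measurement
#'
#' Simulates the six-sensor transient resistance response of a single sample
#' using the first-order conductance kinetics described in
#' [generator_config()]. Draws amplitude jitter and observation noise from the
#' current RNG stream; wrap in `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param cfg a [generator_config()].
#' @param class_label one of `HQ, AQ, LQ, Ea`.
#' @param bottle_factor positive per-bottle concentration factor.
#' @param gains positive numeric length 6, per-sensor-instance gains
#'   (drawn once per dataset by [generate_dataset()]).
#' @param sample_id,bottle_id identifiers stored in the measurement.
#' @param seed optional integer; if given, the measurement is generated under
#'   a local RNG state seeded with it.
#' @return A [sensor_measurement()].
#' @export
generate_measurement <- function(cfg, class_label, bottle_factor,
                                 gains = rep(1, 6),
                                 sample_id = sprintf("%s_Syn_B00_R01", class_label),
                                 bottle_id = "B00", seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!class_label %in% CLASS_LEVELS) {
    stopf("class_label must be one of %s", paste(CLASS_LEVELS, collapse = ", "))
  }
  if (bottle_factor <= 0) stopf("bottle_factor must be > 0")
  with_seed(seed, {
    grid <- phase_grid(cfg)
    t <- grid$time_s
    n <- length(t)
    eps_sample <- stats::rnorm(1, 0, cfg$sample_noise_sd)
    R <- matrix(0, n, 6)
    in_base <- t <= grid$baseline_end + 1e-9
    in_ads <- !in_base & t <= grid$adsorption_end + 1e-9
    in_des <- !in_base & !in_ads
    t_ads <- t[in_ads] - grid$baseline_end
    t_des <- t[in_des] - grid$adsorption_end
    T_ads <- cfg$phase_durations_s[2]
    for (s in 1:6) {
      type <- cfg$sensor_types[s]
      G0 <- cfg$baseline_conductance[s]
      A <- gains[s] * cfg$amplitude[type, class_label] * bottle_factor *
        (1 + eps_sample)
      A <- max(A, 1e-6)  # amplitude floor: never a degenerate/negative response
      tau_a <- cfg$tau_ads_s[type, class_label]
      tau_d <- cfg$tau_des_s[type, class_label]
      G <- numeric(n)
      G[in_base] <- G0
      G[in_ads] <- G0 * (1 + A * (1 - exp(-t_ads / tau_a)))
      A_end <- A * (1 - exp(-T_ads / tau_a))  # continuity at the boundary
      G[in_des] <- G0 * (1 + A_end * exp(-t_des / tau_d))
      if (cfg$obs_noise_sd > 0) {
        G <- G * (1 + stats::rnorm(n, 0, cfg$obs_noise_sd))
      }
      G <- pmax(G, G0 * 1e-9)  # conductance stays strictly positive
      R[, s] <- 1 / G
    }
    sensor_measurement(
      sample_id = sample_id, class_label = class_label, bottle_id = bottle_id,
      time_s = t, resistance = R, sampling_rate_hz = cfg$sampling_rate_hz,
      phase_bounds_s = c(grid$baseline_end, grid$adsorption_end)
    )
  })
}

#' Generate a full synthetic dataset
#'
#' Draws one gain per sensor instance, one concentration factor per bottle and
#' a uniform number of samples per bottle, then emits every measurement.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return An object of class `enose_dataset`: a list with `measurements`
#'   (list of [sensor_measurement()]), `labels` (factor), `groups` (character
#'   bottle ids), and `config_used`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    gains <- stats::rlnorm(6, 0, cfg$sensor_gain_sd)
    measurements <- list()
    labels <- character()
    groups <- character()
    bottle_no <- 0L
    for (cls in CLASS_LEVELS) {
      for (b in seq_len(cfg$bottles_per_class[[cls]])) {
        bottle_no <- bottle_no + 1L
        bottle_id <- sprintf("B%02d", bottle_no)
        bottle_factor <- stats::rlnorm(1, 0, cfg$bottle_effect_sd)
        n_samples <- sample(seq(cfg$samples_per_bottle[1],
                                cfg$samples_per_bottle[2]), 1)
        for (r in seq_len(n_samples)) {
          sid <- sprintf("%s_Syn%02d_%s_R%02d", cls, bottle_no, bottle_id, r)
          m <- generate_measurement(cfg, cls, bottle_factor, gains = gains,
                                    sample_id = sid, bottle_id = bottle_id)
          measurements[[length(measurements) + 1L]] <- m
          labels <- c(labels, cls)
          groups <- c(groups, bottle_id)
        }
      }
    }
    structure(list(measurements = measurements,
                   labels = as_class_factor(labels),
                   groups = groups,
                   config_used = cfg),
              class = "enose_dataset")
  })
}

#' @export
print.enose_dataset <- function(x, ...) {
  cat(sprintf("<enose_dataset> %d measurements, %d bottles, classes: %s\n",
              length(x$measurements), length(unique(x$groups)),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Write a generator configuration as YAML
#'
#' Flat key/value serialization; matrices are stored row-wise with their class
#' column names.
#'
#' @param cfg a [generator_config()].
#' @param path output file path.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  out <- unclass(cfg)
  for (nm in c("amplitude", "tau_ads_s", "tau_des_s")) {
    M <- out[[nm]]
    out[[nm]] <- lapply(seq_len(nrow(M)), function(i) as.list(M[i, ]))
  }
  out$bottles_per_class <- as.list(out$bottles_per_class)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' @param path file written by [write_generator_config()].
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("amplitude", "tau_ads_s", "tau_des_s")) {
    rows <- raw[[nm]]
    M <- do.call(rbind, lapply(rows, function(r) unlist(r[CLASS_LEVELS])))
    colnames(M) <- CLASS_LEVELS
    raw[[nm]] <- M
  }
  bpc <- unlist(raw$bottles_per_class)
  raw$bottles_per_class <- stats::setNames(as.integer(bpc), names(bpc))
  do.call(generator_config, raw[names(raw) != ""])
}

#' Write a dataset as per-measurement CSV files plus a manifest
#'
#' @param dataset an `enose_dataset`.
#' @param dir output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "enose_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$measurements, function(m) {
    fname <- paste0(m$sample_id, ".csv")
    write_measurement_csv(m, file.path(dir, fname))
    data.frame(sample_id = m$sample_id, class = m$class_label,
               bottle_id = m$bottle_id, path = fname,
               baseline_end_s = m$phase_bounds_s[1],
               adsorption_end_s = m$phase_bounds_s[2],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
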