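#' One raw e-nose measurement
#'
#' A single sample's transient resistance time series for the 6-sensor array,
#' with its acquisition metadata. The measurement spans three phases: a pure-air
#' baseline, gas adsorption, and gas desorption; `phase_bounds_s` gives the end
#' of the baseline and the end of adsorption on the time axis.
#'
#' @param sample_id sample identifier string.
#' @param class_label odor class (`HQ`, `AQ`, `LQ`, `Ea`) or `"unknown"`.
#' @param bottle_id group identifier (the bottle the sample came from).
#' @param time_s strictly increasing time vector in seconds.
#' @param resistance `length(time_s) x 6` matrix of strictly positive
#'   resistances (arbitrary consistent units).
#' @param sampling_rate_hz sampling frequency in Hz.
#' @param phase_bounds_s numeric length 2: `(baseline_end, adsorption_end)`,
#'   with `0 < baseline_end < adsorption_end < max(time_s)`.
#' @return An object of class `sensor_measurement`.
#' @export
sensor_measurement <- function(sample_id, class_label, bottle_id, time_s,
                               resistance, sampling_rate_hz, phase_bounds_s) {
  resistance <- as.matrix(resistance)
  m <- structure(list(sample_id = as.character(sample_id),
                      class_label = as.character(class_label),
                      bottle_id = as.character(bottle_id),
                      time_s = as.numeric(time_s),
                      resistance = resistance,
                      sampling_rate_hz = sampling_rate_hz,
                      phase_bounds_s = as.numeric(phase_bounds_s)),
                 class = "sensor_measurement")
  validate_measurement(m)
  m
}

validate_measurement <- function(m) {
  if (ncol(m$resistance) != 6L) stopf("resistance must have 6 sensor columns")
  if (nrow(m$resistance) != length(m$time_s)) {
    stopf("resistance rows (%d) must match time points (%d)",
          nrow(m$resistance), length(m$time_s))
  }
  if (any(!is.finite(m$resistance)) || any(m$resistance <= 0)) {
    stopf("resistance must be finite and strictly positive")
  }
  if (any(diff(m$time_s) <= 0)) stopf("time_s must be strictly increasing")
  b <- m$phase_bounds_s
  if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] >= max(m$time_s)) {
    stopf("phase_bounds_s must satisfy 0 < baseline_end < adsorption_end < last time")
  }
  idx <- phase_indices(m$time_s, b)
  for (ph in names(idx)) {
    if (length(idx[[ph]]) < 3L) stopf("phase '%s' has fewer than 3 samples", ph)
  }
  invisible(m)
}

# Partition of sample indices into the three phases. The baseline ends at the
# sample at or immediately before baseline_end; same rule at adsorption_end.
phase_indices <- function(time_s, bounds, tol = 1e-9) {
  base <- which(time_s <= bounds[1] + tol)
  ads <- which(time_s > bounds[1] + tol & time_s <= bounds[2] + tol)
  des <- which(time_s > bounds[2] + tol)
  list(baseline = base, ads = ads, des = des)
}

#' @export
print.sensor_measurement <- function(x, ...) {
  cat(sprintf("<sensor_measurement> %s  class=%s bottle=%s  %d pts @ %.3g Hz, phases end %.4g/%.4g s\n",
              x$sample_id, x$class_label, x$bottle_id, length(x$time_s),
              x$sampling_rate_hz, x$phase_bounds_s[1], x$phase_bounds_s[2]))
  invisible(x)
}

parse_sample_filename <- function(fname) {
  base <- sub("\\.[Cc][Ss][Vv]$", "", basename(fname))
  # token pattern CLASS_name_Bnn_Rnn, e.g. AQ_Wine02_B04_R01
  m <- regmatches(base, regexec("^([A-Za-z]+)_.*_(B[0-9]+)_R[0-9]+$", base))[[1]]
  if (length(m) == 3L && m[2] %in% CLASS_LEVELS) {
    list(sample_id = base, class_label = m[2], bottle_id = m[3])
  } else {
    list(sample_id = base, class_label = NA_character_, bottle_id = NA_character_)
  }
}

#' Read a raw measurement CSV
#'
#' Expects columns `time_s, R1, ..., R6`. Class and bottle metadata are parsed
#' from a filename of the form `CLASS_name_Bnn_Rnn.csv` (e.g.
#' `AQ_Wine02_B04_R01.csv`); when the pattern does not match, the measurement
#' is loaded with an `"unknown"` label and a warning. Explicit `class_label` /
#' `bottle_id` arguments (e.g. from a manifest) override filename parsing.
#'
#' @param path CSV file path.
#' @param phase_bounds_s `(baseline_end, adsorption_end)` in seconds.
#' @param class_label,bottle_id optional metadata overriding the filename.
#' @param columns optional named list mapping the expected names
#'   (`time_s`, `R1`..`R6`) to the file's column names, for foreign layouts.
#' @return A [sensor_measurement()].
#' @export
read_measurement_csv <- function(path, phase_bounds_s = c(10, 90),
                                 class_label = NULL, bottle_id = NULL,
                                 columns = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE),
    error = function(e) stopf("malformed CSV '%s': %s", path, conditionMessage(e))
  )
  wanted <- c("time_s", paste0("R", 1:6))
  if (!is.null(columns)) {
    for (nm in names(columns)) names(df)[names(df) == columns[[nm]]] <- nm
  }
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols)) {
    stopf("'%s' is missing columns: %s", path, paste(missing_cols, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[wanted]))
  if (length(bad)) stopf("'%s': non-numeric or missing value at data line %d", path, bad[1])
  R <- as.matrix(df[paste0("R", 1:6)])
  if (any(R <= 0)) {
    stopf("'%s': non-positive resistance at data line %d", path,
          which(apply(R <= 0, 1, any))[1])
  }
  meta <- parse_sample_filename(path)
  if (is.null(class_label)) class_label <- meta$class_label
  if (is.null(bottle_id)) bottle_id <- meta$bottle_id
  if (is.na(class_label) || is.na(bottle_id)) {
    warning(sprintf("no class/bottle metadata for '%s'; loading with unknown label",
                    basename(path)), call. = FALSE)
    if (is.na(class_label)) class_label <- "unknown"
    if (is.na(bottle_id)) bottle_id <- "unknown"
  }
  dt <- stats::median(diff(df$time_s))
  sensor_measurement(sample_id = meta$sample_id, class_label = class_label,
                     bottle_id = bottle_id, time_s = df$time_s, resistance = R,
                     sampling_rate_hz = 1 / dt, phase_bounds_s = phase_bounds_s)
}

#' Write a measurement to CSV
#'
#' Header `time_s,R1,...,R6`; values are rendered with `%.17g` so the written
#' doubles round-trip exactly and the byte output is deterministic.
#'
#' @param meas a [sensor_measurement()].
#' @param path output file path.
#' @export
write_measurement_csv <- function(meas, path) {
  stopifnot(inherits(meas, "sensor_measurement"))
  M <- cbind(meas$time_s, meas$resistance)
  lines <- c("time_s,R1,R2,R3,R4,R5,R6",
             apply(M, 1, function(row) paste(sprintf("%.17g", row), collapse = ",")))
  con <- file(path, open = "wb")  # binary mode: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a dataset from a manifest CSV
#'
#' The manifest has columns `sample_id, class, bottle_id, path` with paths
#' relative to the manifest location, as written by [write_dataset_csv()].
#' Optional `baseline_end_s` / `adsorption_end_s` columns carry per-file
#' phase bounds; otherwise `phase_bounds_s` applies to every file.
#'
#' @param manifest_path manifest CSV path.
#' @param phase_bounds_s default bounds passed to [read_measurement_csv()]
#'   when the manifest has no bound columns.
#' @return An `enose_dataset`.
#' @export
read_dataset_csv <- function(manifest_path, phase_bounds_s = c(10, 90)) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "bottle_id", "path")
  if (!all(need %in% names(man))) {
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  }
  dir <- dirname(manifest_path)
  has_bounds <- all(c("baseline_end_s", "adsorption_end_s") %in% names(man))
  measurements <- lapply(seq_len(nrow(man)), function(i) {
    bounds <- if (has_bounds) {
      c(man$baseline_end_s[i], man$adsorption_end_s[i])
    } else {
      phase_bounds_s
    }
    read_measurement_csv(file.path(dir, man$path[i]), bounds,
                         class_label = man$class[i], bottle_id = man$bottle_id[i])
  })
  structure(list(measurements = measurements,
                 labels = as_class_factor(man$class),
                 groups = man$bottle_id,
                 config_used = NULL),
            class = "enose_dataset")
}

#' Baseline-normalize a measurement
#'
#' Computes the per-sensor baseline reference `R0` as the median resistance
#' over the baseline phase (median rather than mean, for robustness to
#' acquisition spikes) and returns both normalized views of the response:
#' \code{r = R/R0} and \code{g = G/G0 = R0/R}. Elementwise \code{r * g = 1} by construction,
#' and both are invariant to rescaling a sensor's raw resistance.
#'
#' @param meas a [sensor_measurement()].
#' @return An object of class `normalized_curves` with fields `r`, `g`
#'   (`n x 6` matrices), `R0`, `time_s`, `phase_bounds_s`, `sampling_rate_hz`.
#' @export
baseline_normalize <- function(meas) {
  stopifnot(inherits(meas, "sensor_measurement"))
  idx <- phase_indices(meas$time_s, meas$phase_bounds_s)
  R0 <- apply(meas$resistance[idx$baseline, , drop = FALSE], 2, stats::median)
  r <- sweep(meas$resistance, 2, R0, "/")
  structure(list(r = r, g = 1 / r, R0 = R0, time_s = meas$time_s,
                 phase_bounds_s = meas$phase_bounds_s,
                 sampling_rate_hz = meas$sampling_rate_hz),
            class = "normalized_curves")
}

#' @export
print.normalized_curves <- function(x, ...) {
  cat(sprintf("<normalized_curves> %d pts x 6 sensors, R0 = %s\n",
              nrow(x$r), paste(signif(x$R0, 4), collapse = ", ")))
  invisible(x)
}

#' Extract one segment of a normalized curve
#'
#' Segments partition the post-baseline response: `ads` is the adsorption
#' phase (ending at the sample at or immediately before `adsorption_end`),
#' `des` the desorption phase starting at the next sample, and `full` their
#' concatenation. The baseline itself is excluded from all three (features on
#' a flat reference window carry no odor information). Values are the raw
#' normalized ratio (no offset is subtracted).
#'
#' @param norm a [baseline_normalize()] result.
#' @param sensor sensor index 1-6.
#' @param signal `"R"` (resistance ratio `R/R0`) or `"G"` (conductance ratio).
#' @param segment `"full"`, `"ads"`, or `"des"`.
#' @return An object of class `curve_segment` with `values`, `time_s`, `dt_s`
#'   and the identifying fields.
#' @export
segment_curve <- function(norm, sensor, signal = c("R", "G"),
                          segment = c("full", "ads", "des")) {
  stopifnot(inherits(norm, "normalized_curves"))
  signal <- match.arg(signal)
  segment <- match.arg(segment)
  if (!(sensor %in% 1:6)) stopf("sensor must be in 1..6")
  idx <- phase_indices(norm$time_s, norm$phase_bounds_s)
  sel <- switch(segment, ads = idx$ads, des = idx$des, full = c(idx$ads, idx$des))
  if (length(sel) < 3L) stopf("segment '%s' has fewer than 3 samples", segment)
  vals <- if (signal == "R") norm$r[sel, sensor] else norm$g[sel, sensor]
  structure(list(sensor = as.integer(sensor), signal = signal, segment = segment,
                 values = as.numeric(vals), time_s = norm$time_s[sel],
                 dt_s = 1 / norm$sampling_rate_hz),
            class = "curve_segment")
}

#' @export
print.curve_segment <- function(x, ...) {
  cat(sprintf("<curve_segment> S%d|%s|%s  %d pts, dt = %.4g s\n",
              x$sensor, x$signal, x$segment, length(x$values), x$dt_s))
  invisible(x)
}
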