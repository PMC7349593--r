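#' The 23-item per-segment feature catalogue
#'
#' Each (sensor, signal, segment) combination yields 23 scalar features, so a
#' 6-sensor array with both signal views (R/R0, G/G0) and three segments
#' (full, ads, des) gives 6 x 2 x 3 x 23 = 828 features. In order:
#'
#' 1. `final` -- last value of the segment;
#' 2. `extremum` -- max for a net-positive response, min otherwise;
#' 3. `mean`; 4. `sd` (n-1 denominator); 5. `skewness` (sample, uncorrected);
#' 6. `kurtosis` (excess, uncorrected); 7. `integral` (left-Riemann sum x dt);
#' 8.-13. max and min of the exponential moving average of first differences
#'    at each smoothing alpha (default 0.1, 0.01, 0.001);
#' 14./15. max/min of the smoothed derivative; 16./17. their times;
#' 18.-20. time to reach 10/25/50 % of the response range;
#' 21.-23. exponential-fit amplitude `A`, time constant `tau`, offset `c`.
#'
#' @name feature_catalogue
NULL

FEATURE_TYPES <- c("final", "extremum", "mean", "sd", "skewness", "kurtosis",
                   "integral",
                   "ema_max_a0.1", "ema_min_a0.1",
                   "ema_max_a0.01", "ema_min_a0.01",
                   "ema_max_a0.001", "ema_min_a0.001",
                   "dmax", "dmin", "t_dmax", "t_dmin",
                   "t_frac10", "t_frac25", "t_frac50",
                   "exp_A", "exp_tau", "exp_c")
SIGNALS <- c("R", "G")
SEGMENTS <- c("full", "ads", "des")

#' EMA smoothing parameters
#'
#' @param alphas ordered smoothing parameters, each in (0, 1].
#' @return An object of class `ema_params`.
#' @export
ema_params <- function(alphas = c(0.1, 0.01, 0.001)) {
  if (any(alphas <= 0) || any(alphas > 1)) stopf("each alpha must be in (0, 1]")
  structure(list(alphas = as.numeric(alphas)), class = "ema_params")
}

#' Feature identifier catalogue
#'
#' Enumerates feature ids in the package's canonical order: sensors ascending,
#' then signal (R before G), then segment (full, ads, des), then the fixed
#' 23-type order of [feature_catalogue]. Ids render as
#' `"S{sensor}|{signal}|{segment}|{type}"`.
#'
#' @param sensors subset of 1:6.
#' @param signals subset of `c("R", "G")`.
#' @param segments subset of `c("full", "ads", "des")`.
#' @return A data.frame with columns `id`, `sensor`, `signal`, `segment`,
#'   `type`, one row per feature.
#' @export
feature_ids <- function(sensors = 1:6, signals = SIGNALS, segments = SEGMENTS) {
  sensors <- sort(unique(as.integer(sensors)))
  if (!length(sensors) || !all(sensors %in% 1:6)) stopf("sensors must be a subset of 1..6")
  signals <- SIGNALS[SIGNALS %in% signals]
  segments <- SEGMENTS[SEGMENTS %in% segments]
  if (!length(signals) || !length(segments)) stopf("signals and segments must be nonempty")
  grid <- expand.grid(type = FEATURE_TYPES, segment = segments, signal = signals,
                      sensor = sensors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sensor", "signal", "segment", "type")]
  grid$id <- sprintf("S%d|%s|%s|%s", grid$sensor, grid$signal, grid$segment, grid$type)
  rownames(grid) <- NULL
  grid[, c("id", "sensor", "signal", "segment", "type")]
}

#' Exponential moving average of first differences
#'
#' The transient-shape transform whose extrema serve as features:
#' `y[1] = 0; y[k] = (1 - alpha) * y[k-1] + alpha * (x[k] - x[k-1])`.
#' With `alpha = 1` it returns the raw increments; a constant input maps to
#' zero everywhere.
#'
#' @param values numeric vector, length >= 2.
#' @param alpha smoothing parameter in (0, 1].
#' @param dt_s sampling interval; accepted for interface symmetry, the
#'   recurrence itself is per-sample.
#' @return Numeric vector of the same length as `values`.
#' @export
ema_transform <- function(values, alpha, dt_s = NULL) {
  if (length(values) < 2L) stopf("values must have length >= 2")
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  inc <- alpha * diff(values)
  y <- stats::filter(inc, filter = 1 - alpha, method = "recursive")
  c(0, as.numeric(y))
}

# Truncated-window moving average (window w, centered); edges average over the
# available part of the window.
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n < 3L) return(x)
  kern <- rep(1, w)
  num <- stats::filter(x, kern / w, sides = 2)
  # renormalize edge cells where the window is truncated
  cnt <- stats::filter(rep(1, n), kern / w, sides = 2)
  out <- as.numeric(num / cnt)
  nas <- is.na(out)
  if (any(nas)) {  # stats::filter leaves NA at the extreme edges for even w
    half <- (w - 1L) %/% 2L
    for (i in which(nas)) {
      lo <- max(1L, i - half); hi <- min(n, i + w %/% 2L)
      out[i] <- mean(x[lo:hi])
    }
  }
  out
}

# Smoothed derivative: central finite differences of a moving-average-smoothed
# segment; one-sided at the ends.
smoothed_derivative <- function(values, dt_s, window = 15L) {
  s <- moving_average(values, min(window, length(values)))
  n <- length(s)
  d <- numeric(n)
  if (n >= 3L) {
    d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt_s)
  }
  d[1] <- (s[2] - s[1]) / dt_s
  d[n] <- (s[n] - s[n - 1]) / dt_s
  d
}

net_positive <- function(y) (max(y) - y[1]) >= (y[1] - min(y))

#' Time to reach a fraction of the response range
#'
#' The response range is `y_extremum - y_start`, with the extremum taken as
#' the maximum for a net-positive response and the minimum otherwise. Returns
#' the first time (from segment start, linearly interpolated between samples)
#' at which the curve crosses `y_start + fraction * range`. A degenerate
#' zero-range segment returns the documented fallback 0.
#'
#' @param seg a [segment_curve()] result.
#' @param fraction fraction of the range in (0, 1); the catalogue uses
#'   0.10, 0.25, 0.50.
#' @return Crossing time in seconds from segment start.
#' @export
crossing_time <- function(seg, fraction) {
  stopifnot(inherits(seg, "curve_segment"))
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  y <- seg$values
  t <- seg$time_s - seg$time_s[1]
  ext <- if (net_positive(y)) max(y) else min(y)
  rng <- ext - y[1]
  if (rng == 0) return(0)
  thr <- y[1] + fraction * rng
  if (rng > 0) {
    hit <- which(y >= thr)
  } else {
    hit <- which(y <= thr)
  }
  if (!length(hit)) return(t[length(t)])
  k <- hit[1]
  if (k == 1L) return(0)
  # linear interpolation between samples k-1 and k
  y0 <- y[k - 1]; y1 <- y[k]
  if (y1 == y0) return(t[k])
  t[k - 1] + (thr - y0) / (y1 - y0) * (t[k] - t[k - 1])
}

#' Exponential fit of a segment
#'
#' Least-squares fit of `y(t) = c + A * exp(-t / tau)` with `t` measured from
#' segment start, via Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#' Initialization is deterministic (`c = y_end`, `A = y_start - y_end`,
#' `tau = duration / 3`) and `tau` is bounded to `[dt, 10 x duration]`. The fit
#' never raises: on solver failure the initialization values are returned as
#' the documented fallback.
#'
#' @param seg a [segment_curve()] result with at least 5 samples.
#' @return Named numeric vector `c(A, tau_s, c)`.
#' @export
fit_exponential <- function(seg) {
  stopifnot(inherits(seg, "curve_segment"))
  y <- seg$values
  n <- length(y)
  if (n < 5L) stopf("exponential fit needs at least 5 samples")
  t <- seg$time_s - seg$time_s[1]
  dur <- t[n]
  init <- list(c0 = y[n], A = y[1] - y[n], tau = dur / 3)
  lo <- c(c0 = -Inf, A = -Inf, tau = seg$dt_s)
  hi <- c(c0 = Inf, A = Inf, tau = 10 * dur)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ c0 + A * exp(-t / tau), start = init,
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    p <- unlist(init)
  } else {
    p <- stats::coef(fit)
  }
  c(A = unname(p["A"]), tau_s = unname(p["tau"]), c = unname(p["c0"]))
}

# Sample skewness and excess kurtosis from uncorrected central moments with an
# (n-1)-denominator sd; zero-variance segments yield 0 for both.
sample_skewness <- function(y, s) {
  if (s == 0) return(0)
  mean((y - mean(y))^3) / s^3
}
sample_kurtosis <- function(y, s) {
  if (s == 0) return(0)
  mean((y - mean(y))^4) / s^4 - 3
}

#' Compute the 23 catalogue features of one segment
#'
#' Returns the features of [feature_catalogue] in their fixed order. Degenerate
#' inputs (constant segments, failed fits) take documented finite fallbacks,
#' never NaN/Inf.
#'
#' @param seg a [segment_curve()] result.
#' @param ema an [ema_params()] object.
#' @param deriv_window moving-average window (samples) used before the
#'   finite-difference derivative; about 0.8 s at 18.5 Hz.
#' @return Named numeric vector of length `3 + 2 * length(alphas) + 14`
#'   (23 with the default three alphas).
#' @export
segment_features <- function(seg, ema = ema_params(), deriv_window = 15L) {
  stopifnot(inherits(seg, "curve_segment"), inherits(ema, "ema_params"))
  y <- seg$values
  n <- length(y)
  t <- seg$time_s - seg$time_s[1]
  dt <- seg$dt_s
  s <- if (n > 1) stats::sd(y) else 0
  ext <- if (net_positive(y)) max(y) else min(y)
  out <- c(final = y[n], extremum = ext, mean = mean(y), sd = s,
           skewness = sample_skewness(y, s), kurtosis = sample_kurtosis(y, s),
           integral = sum(y) * dt)
  for (a in ema$alphas) {
    e <- ema_transform(y, a)
    out <- c(out, stats::setNames(c(max(e), min(e)),
                                  sprintf(c("ema_max_a%s", "ema_min_a%s"),
                                          format(a, scientific = FALSE))))
  }
  d <- smoothed_derivative(y, dt, deriv_window)
  out <- c(out,
           dmax = max(d), dmin = min(d),
           t_dmax = t[which.max(d)], t_dmin = t[which.min(d)],
           t_frac10 = crossing_time(seg, 0.10),
           t_frac25 = crossing_time(seg, 0.25),
           t_frac50 = crossing_time(seg, 0.50))
  out <- c(out, fit_exponential(seg))
  names(out)[length(out) - 2:0] <- c("exp_A", "exp_tau", "exp_c")
  out[!is.finite(out)] <- 0  # belt-and-braces: the table must stay finite
  out
}

#' Extract the feature vector of one measurement
#'
#' Baseline-normalizes the measurement, segments each requested
#' (sensor, signal, segment) combination, and concatenates the per-segment
#' features in canonical [feature_ids()] order. With everything enabled the
#' result has length 828.
#'
#' @param meas a [sensor_measurement()].
#' @param sensors,signals,segments subsets selecting the feature sources.
#' @param ema an [ema_params()] object.
#' @return Named numeric vector; names are rendered feature ids.
#' @export
extract_features <- function(meas, sensors = 1:6, signals = SIGNALS,
                             segments = SEGMENTS, ema = ema_params()) {
  stopifnot(inherits(meas, "sensor_measurement"))
  ids <- feature_ids(sensors, signals, segments)
  norm <- baseline_normalize(meas)
  combos <- unique(ids[, c("sensor", "signal", "segment")])
  vals <- numeric(0)
  for (i in seq_len(nrow(combos))) {
    seg <- segment_curve(norm, combos$sensor[i], combos$signal[i], combos$segment[i])
    vals <- c(vals, unname(segment_features(seg, ema)))
  }
  stats::setNames(vals, ids$id)
}

#' Build the feature table of a dataset
#'
#' One row per measurement, one column per feature id; class labels and bottle
#' ids are carried through. All values are finite by construction.
#'
#' @param dataset an `enose_dataset` (from [generate_dataset()] or
#'   [read_dataset_csv()]).
#' @inheritParams extract_features
#' @return An object of class `feature_table`: list with `values`
#'   (`n_samples x n_features` matrix, rownames = sample ids, colnames = ids),
#'   `info` (the [feature_ids()] frame), `labels`, `groups`.
#' @export
build_feature_table <- function(dataset, sensors = 1:6, signals = SIGNALS,
                                segments = SEGMENTS, ema = ema_params()) {
  stopifnot(inherits(dataset, "enose_dataset"))
  if (!length(dataset$measurements)) stopf("dataset has no measurements")
  info <- feature_ids(sensors, signals, segments)
  rows <- lapply(dataset$measurements, function(m) {
    v <- extract_features(m, sensors, signals, segments, ema)
    if (length(v) != nrow(info)) stopf("inconsistent measurement shapes")
    v
  })
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(dataset$measurements, `[[`, "", "sample_id")
  feature_table(values, info, dataset$labels, dataset$groups)
}

#' Construct a feature table
#'
#' Lower-level constructor used by [build_feature_table()] and by tests that
#' build tables directly.
#'
#' @param values numeric matrix, samples x features; column names must match
#'   `info$id`.
#' @param info a [feature_ids()]-shaped data.frame (or `NULL` to derive a
#'   minimal one from the column names).
#' @param labels class per sample.
#' @param groups bottle/group id per sample.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, info = NULL, labels, groups) {
  values <- as.matrix(values)
  if (is.null(info)) {
    if (is.null(colnames(values))) {
      colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
    }
    info <- data.frame(id = colnames(values), sensor = NA_integer_,
                       signal = NA_character_, segment = NA_character_,
                       type = NA_character_, stringsAsFactors = FALSE)
  }
  colnames(values) <- info$id
  if (anyDuplicated(info$id)) stopf("feature ids must be unique")
  if (nrow(values) != length(labels) || nrow(values) != length(groups)) {
    stopf("labels/groups must match the number of rows")
  }
  if (any(!is.finite(values))) stopf("feature values must be finite")
  structure(list(values = values, info = info,
                 labels = as_class_factor(labels),
                 groups = as.character(groups)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %d groups, classes: %s\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups)),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Restrict a feature table to a subset of its columns
#'
#' @param table a [feature_table()].
#' @param ids character feature ids or integer column indices; alternatively
#'   use `sensors`/`signals`/`segments` to restrict structurally.
#' @param sensors,signals,segments optional structural restrictions.
#' @return A `feature_table` with the selected columns, in table order.
#' @export
subset_features <- function(table, ids = NULL, sensors = NULL, signals = NULL,
                            segments = NULL) {
  stopifnot(inherits(table, "feature_table"))
  keep <- rep(TRUE, ncol(table$values))
  if (!is.null(sensors)) keep <- keep & table$info$sensor %in% sensors
  if (!is.null(signals)) keep <- keep & table$info$signal %in% signals
  if (!is.null(segments)) keep <- keep & table$info$segment %in% segments
  sel <- which(keep)
  if (!is.null(ids)) {
    sel0 <- if (is.numeric(ids)) as.integer(ids) else match(ids, table$info$id)
    if (anyNA(sel0)) stopf("unknown feature id(s)")
    sel <- intersect(sel0, sel)
  }
  if (!length(sel)) stopf("restriction leaves no features")
  feature_table(table$values[, sel, drop = FALSE], table$info[sel, ],
                table$labels, table$groups)
}

#' Write a feature table to CSV
#'
#' Columns `sample_id, class, bottle_id`, then one column per feature id.
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @export
write_feature_table_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = rownames(table$values) %||%
                     sprintf("sample%04d", seq_len(nrow(table$values))),
                   class = as.character(table$labels),
                   bottle_id = table$groups,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table_csv()]
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "class", "bottle_id")
  if (!all(meta %in% names(df))) stopf("not a feature table CSV: %s", path)
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(vals) <- df$sample_id
  ids <- colnames(vals)
  parsed <- regmatches(ids, regexec("^S([1-6])\\|(R|G)\\|(full|ads|des)\\|(.+)$", ids))
  ok <- lengths(parsed) == 5L
  info <- data.frame(
    id = ids,
    sensor = ifelse(ok, as.integer(vapply(parsed, function(p) if (length(p) == 5) p[2] else NA_character_, "")), NA_integer_),
    signal = ifelse(ok, vapply(parsed, function(p) if (length(p) == 5) p[3] else NA_character_, ""), NA_character_),
    segment = ifelse(ok, vapply(parsed, function(p) if (length(p) == 5) p[4] else NA_character_, ""), NA_character_),
    type = ifelse(ok, vapply(parsed, function(p) if (length(p) == 5) p[5] else NA_character_, ""), NA_character_),
    stringsAsFactors = FALSE)
  feature_table(vals, info, df$class, df$bottle_id)
}
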