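#' Feature-source restrictions
#'
#' The six named restrictions of the feature pool used in the source
#' comparison: `ALL` keeps both signal views and all segments; `ALL-G` /
#' `ALL-R` keep only conductance / resistance features; `ON` keeps only
#' adsorption-segment features; `ON-G` / `ON-R` combine both restrictions.
#'
#' @param name one of `"ALL", "ALL-G", "ALL-R", "ON", "ON-G", "ON-R"`.
#' @return A list with `name`, `signals`, `segments`.
#' @export
source_filter <- function(name = c("ALL", "ALL-G", "ALL-R", "ON", "ON-G", "ON-R")) {
  name <- match.arg(name)
  signals <- switch(name, `ALL-G` = "G", `ON-G` = "G",
                    `ALL-R` = "R", `ON-R` = "R", c("R", "G"))
  segments <- if (startsWith(name, "ON")) "ads" else c("full", "ads", "des")
  list(name = name, signals = signals, segments = segments)
}

#' Sensor-subset experiment
#'
#' Cross-validates the classifier on every nonempty subset of the six sensors
#' (63 runs), restricting the feature table to the subset's columns. With all
#' feature sources enabled each sensor contributes 138 columns.
#'
#' @param table a full 6-sensor [feature_table()].
#' @param cv_cfg a [cv_config()].
#' @return A data.frame with one row per subset: `sensors` (e.g. `"1+3+5"`),
#'   `n_sensors`, `n_features`, `mean_accuracy`, `std_accuracy`. The best row
#'   per subset size is attached as `attr(, "best_per_size")`.
#' @export
sensor_subset_experiment <- function(table, cv_cfg = cv_config(n_repeats = 25L)) {
  stopifnot(inherits(table, "feature_table"))
  if (!setequal(unique(table$info$sensor), 1:6)) {
    stopf("sensor_subset_experiment needs a full 6-sensor table")
  }
  subsets <- unlist(lapply(1:6, function(k) utils::combn(1:6, k, simplify = FALSE)),
                    recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    cols <- which(table$info$sensor %in% ss)
    res <- cross_validate(table, cols, cv_cfg)
    data.frame(sensors = paste(ss, collapse = "+"), n_sensors = length(ss),
               n_features = length(cols),
               mean_accuracy = res$mean_accuracy,
               std_accuracy = res$std_accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(out, out$n_sensors), function(d) {
    d[which.max(d$mean_accuracy), ]
  }))
  rownames(best) <- NULL
  attr(out, "best_per_size") <- best
  out
}

#' Forward selection on a restricted feature source
#'
#' Runs [forward_select()] on the columns surviving a [source_filter()]
#' restriction (and optionally a sensor restriction).
#'
#' @param table a [feature_table()].
#' @param source a [source_filter()] or its name.
#' @param sensors sensor subset (default all present).
#' @param max_k steps of forward selection.
#' @param cv_cfg a [cv_config()].
#' @param seed optional split seed override.
#' @return A `selection_trace` whose features all satisfy the restriction.
#' @export
source_restricted_selection <- function(table, source, sensors = NULL, max_k,
                                        cv_cfg = cv_config(n_repeats = 25L),
                                        seed = NULL) {
  if (is.character(source)) source <- source_filter(source)
  sub <- subset_features(table, sensors = sensors, signals = source$signals,
                         segments = source$segments)
  if (ncol(sub$values) < max_k) {
    stopf("restriction leaves %d features, fewer than max_k = %d",
          ncol(sub$values), max_k)
  }
  forward_select(sub, max_k, cv_cfg, seed = seed)
}

#' Single-sensor forward-selection sweep
#'
#' Forward selection restricted to each sensor's features in turn, reporting
#' the accuracy reached at selected feature counts.
#'
#' @param table a full 6-sensor [feature_table()].
#' @param max_k steps of forward selection per sensor.
#' @param cv_cfg a [cv_config()].
#' @param report_k feature counts summarized in the `summary` table
#'   (entries above `max_k` are dropped).
#' @param seed optional split seed override.
#' @return List with `traces` (one `selection_trace` per sensor) and `summary`
#'   (data.frame `sensor`, `k`, `mean_accuracy`, `std_accuracy`).
#' @export
single_sensor_sweep <- function(table, max_k, cv_cfg = cv_config(n_repeats = 25L),
                                report_k = c(5L, 10L, 15L), seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  report_k <- report_k[report_k <= max_k]
  traces <- lapply(1:6, function(s) {
    sub <- subset_features(table, sensors = s)
    forward_select(sub, max_k, cv_cfg, seed = seed)
  })
  summary <- do.call(rbind, lapply(1:6, function(s) {
    tr <- traces[[s]]
    data.frame(sensor = rep(s, length(report_k)), k = report_k,
               mean_accuracy = tr$step_mean_accuracy[report_k],
               std_accuracy = tr$step_std_accuracy[report_k])
  }))
  list(traces = traces, summary = summary)
}

#' Wrapper-vs-filter comparison
#'
#' For each feature count k in `k_grid`, cross-validates the model built on
#' the top-k features of each filter ranking (MI, Fisher, ReliefF) and on the
#' first k features of the forward-selection trace.
#'
#' @param table a [feature_table()].
#' @param k_grid feature counts to compare.
#' @param cv_cfg a [cv_config()] used for the accuracy estimates.
#' @param wrapper_trace optional precomputed `selection_trace`; if `NULL`,
#'   forward selection is run to `max(k_grid)`.
#' @param k_neighbors passed to [relieff_scores()].
#' @return A data.frame with `|k_grid| x 4` rows: `method`, `k`,
#'   `mean_accuracy`, `std_accuracy`.
#' @export
wrapper_vs_filter_experiment <- function(table, k_grid,
                                         cv_cfg = cv_config(n_repeats = 25L),
                                         wrapper_trace = NULL,
                                         k_neighbors = 10L) {
  stopifnot(inherits(table, "feature_table"))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > ncol(table$values))) {
    stopf("k_grid must lie in 1..%d", ncol(table$values))
  }
  if (is.null(wrapper_trace)) {
    wrapper_trace <- forward_select(table, max(k_grid), cv_cfg)
  }
  rankings <- list(
    RFS = NULL,
    MI = mutual_information_scores(table),
    FS = fisher_scores(table),
    RS = relieff_scores(table, k_neighbors = k_neighbors)
  )
  rows <- list()
  for (method in names(rankings)) {
    for (k in k_grid) {
      ids <- if (method == "RFS") {
        wrapper_trace$ordered_features[seq_len(k)]
      } else {
        filter_select(rankings[[method]], k)
      }
      res <- cross_validate(table, ids, cv_cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, k = k,
        mean_accuracy = res$mean_accuracy, std_accuracy = res$std_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' PCA view of selected features
#'
#' Projects samples onto the leading principal axes of the centered, z-scored
#' selected features -- the standard visualization of class structure (e.g.
#' the overlap of average-quality wine and ethanol samples).
#'
#' @param table a [feature_table()].
#' @param feature_subset ids or column indices, at least `n_components` of them.
#' @param n_components number of components returned.
#' @return A data.frame with `PC1..PCn`, `class`, `bottle_id`; component
#'   standard deviations are attached as `attr(, "sdev")`.
#' @export
pca_view <- function(table, feature_subset = NULL, n_components = 2L) {
  stopifnot(inherits(table, "feature_table"))
  cols <- resolve_subset(table, feature_subset)
  if (length(cols) < n_components) stopf("need at least %d features", n_components)
  X <- table$values[, cols, drop = FALSE]
  sds <- col_sds(X)
  X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  out <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  out$class <- table$labels
  out$bottle_id <- table$groups
  attr(out, "sdev") <- pc$sdev
  out
}

#' Run the full study harness
#'
#' Executes the whole pipeline on a synthetic scenario: dataset generation,
#' feature extraction, both cross-validation schemes on all features,
#' forward selection (averaged over outer seeds), the sensor-subset sweep,
#' the single-sensor sweep, the source-restriction comparison, the
#' wrapper-vs-filter comparison, and a PCA view of the best five features.
#' All tables are written as CSV, a summary as JSON, and (when ggplot2 is
#' installed and `plots = TRUE`) figure analogues as PNG. Fully reproducible
#' from the config and seed.
#'
#' @param scenario a [generator_config()] (e.g. [default_scenario()]).
#' @param out_dir output directory.
#' @param seed master seed; overrides `scenario$seed` and seeds every stage.
#' @param max_k forward-selection depth.
#' @param n_repeats inner cross-validation repeats; `full_scale = TRUE`
#'   restores the full 100 repeats and 5 outer seeds.
#' @param n_seeds outer forward-selection repetitions.
#' @param k_grid feature counts for the wrapper-vs-filter comparison.
#' @param full_scale run at the full study scale (slower).
#' @param plots write PNG figures (requires ggplot2).
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_full_study <- function(scenario = default_scenario(), out_dir, seed = 1L,
                           max_k = 10L, n_repeats = 25L, n_seeds = 2L,
                           k_grid = c(1L, 2L, 5L, 10L),
                           full_scale = FALSE, plots = FALSE) {
  stopifnot(inherits(scenario, "generator_config"))
  if (full_scale) { n_repeats <- 100L; n_seeds <- 5L }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario$seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("study stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  log_lines <- c(sprintf("seed: %d", seed),
                 sprintf("config hash: %s",
                         sum(utils::head(utils::object.size(scenario), 1))))
  dataset <- stage("generate", generate_dataset(scenario))
  table <- stage("extract", build_feature_table(dataset))
  cfg_sh <- cv_config("group_shuffle", n_repeats = if (full_scale) 100L else 50L,
                      seed = seed)
  cfg_logo <- cv_config("logo", seed = seed)
  logo <- stage("logo", cross_validate(table, NULL, cfg_logo))
  shuffle <- stage("group_shuffle", cross_validate(table, NULL, cfg_sh))
  inner <- cv_config("group_shuffle", n_repeats = n_repeats, seed = seed)
  sel <- stage("forward_selection",
               repeat_selection(table, max_k, inner, n_seeds = n_seeds))
  utils::write.csv(sel$curve, file.path(out_dir, "forward_selection_curve.csv"),
                   row.names = FALSE)
  for (i in seq_along(sel$traces)) {
    write_selection_trace(sel$traces[[i]],
                          file.path(out_dir, sprintf("trace_seed%d.csv", i)))
  }
  subsets <- stage("sensor_subsets", sensor_subset_experiment(table, inner))
  utils::write.csv(subsets, file.path(out_dir, "sensor_subsets.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(subsets, "best_per_size"),
                   file.path(out_dir, "sensor_subsets_best.csv"), row.names = FALSE)
  sweep_res <- stage("single_sensor",
                     single_sensor_sweep(table, max_k, inner,
                                         report_k = c(5L, 10L, 15L)))
  utils::write.csv(sweep_res$summary, file.path(out_dir, "single_sensor.csv"),
                   row.names = FALSE)
  sources <- stage("sources", {
    do.call(rbind, lapply(c("ALL", "ALL-G", "ALL-R", "ON", "ON-G", "ON-R"),
      function(nm) {
        tr <- source_restricted_selection(table, nm, max_k = min(max_k, 5L),
                                          cv_cfg = inner)
        data.frame(source = nm, k = min(max_k, 5L),
                   mean_accuracy = tr$step_mean_accuracy[min(max_k, 5L)],
                   std_accuracy = tr$step_std_accuracy[min(max_k, 5L)],
                   stringsAsFactors = FALSE)
      }))
  })
  utils::write.csv(sources, file.path(out_dir, "source_restriction.csv"),
                   row.names = FALSE)
  kn <- min(10L, min(table(table$labels)) - 1L)  # ReliefF needs > k per class
  wvf <- stage("wrapper_vs_filter",
               wrapper_vs_filter_experiment(table, k_grid, inner,
                                            wrapper_trace = sel$traces[[1]],
                                            k_neighbors = kn))
  utils::write.csv(wvf, file.path(out_dir, "wrapper_vs_filter.csv"),
                   row.names = FALSE)
  best5 <- sel$traces[[1]]$ordered_features[seq_len(min(5L, max_k))]
  pca <- stage("pca", pca_view(table, best5))
  utils::write.csv(pca, file.path(out_dir, "pca_view.csv"), row.names = FALSE)
  summary <- list(
    seed = seed,
    n_samples = nrow(table$values),
    n_features = ncol(table$values),
    logo = list(mean_accuracy = logo$mean_accuracy,
                std_accuracy = logo$std_accuracy),
    group_shuffle = list(mean_accuracy = shuffle$mean_accuracy,
                         std_accuracy = shuffle$std_accuracy),
    forward_selection = list(curve = sel$curve,
                             features_seed1 = sel$traces[[1]]$ordered_features),
    best_subset_per_size = attr(subsets, "best_per_size"),
    single_sensor = sweep_res$summary,
    sources = sources
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "study.log"))
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    save_study_plots(sel$curve, subsets, wvf, pca, out_dir)
  }
  invisible(summary)
}

save_study_plots <- function(curve, subsets, wvf, pca, out_dir) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  p1 <- gg(curve, aes(x = k, y = mean_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of selected features", y = "mean accuracy")
  ggplot2::ggsave(file.path(out_dir, "accuracy_vs_k.png"), p1,
                  width = 5, height = 3.5, dpi = 120)
  best <- attr(subsets, "best_per_size")
  p2 <- gg(best, aes(x = factor(n_sensors), y = mean_accuracy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "number of sensors (best subset)", y = "mean accuracy")
  ggplot2::ggsave(file.path(out_dir, "sensor_subsets.png"), p2,
                  width = 5, height = 3.5, dpi = 120)
  p3 <- gg(wvf, aes(x = k, y = mean_accuracy, colour = method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of features", y = "mean accuracy")
  ggplot2::ggsave(file.path(out_dir, "wrapper_vs_filter.png"), p3,
                  width = 5, height = 3.5, dpi = 120)
  p4 <- gg(pca, aes(x = PC1, y = PC2, colour = class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PC1", y = "PC2")
  ggplot2::ggsave(file.path(out_dir, "pca_view.png"), p4,
                  width = 5, height = 3.5, dpi = 120)
  invisible(NULL)
}
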