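#' Cross-validation configuration
#'
#' Two group-aware schemes are supported. `logo` (leave-one-group-out) holds
#' out all samples of one bottle per split, looping over bottles.
#' `group_shuffle` repeatedly partitions the *bottles* (not the samples) at
#' random, sending about `test_fraction` of them to validation; no bottle ever
#' spans both sides. The 75/25 split proportion is applied at the group level
#' because that is the only reading that guarantees the bottle restriction for
#' every cohort.
#'
#' @param scheme `"group_shuffle"` or `"logo"`.
#' @param test_fraction fraction of groups sent to validation (group shuffle).
#' @param n_repeats number of random splits (group shuffle).
#' @param seed master seed; split r is derived from it deterministically and
#'   does not depend on `n_repeats`.
#' @param standardize z-score features on each training fold (default TRUE).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(scheme = c("group_shuffle", "logo"), test_fraction = 0.25,
                      n_repeats = 100L, seed = 1L, standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0, 1)")
  if (n_repeats < 1L) stopf("n_repeats must be >= 1")
  structure(list(scheme = scheme, test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "cv_config")
}

#' Leave-one-group-out splits
#'
#' One split per distinct group: validation is that group's samples, training
#' is everything else.
#'
#' @param groups group (bottle) id per sample.
#' @return List of splits, each `list(train, val)` of integer indices.
#' @export
logo_splits <- function(groups) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 2L) stopf("need at least 2 distinct groups")
  lapply(gs, function(g) {
    val <- which(groups == g)
    list(train = setdiff(seq_along(groups), val), val = val)
  })
}

#' Group shuffle splits
#'
#' `n_repeats` independent random partitions of the group set; in each,
#' `max(1, round(test_fraction * n_groups))` groups go to validation and the
#' rest to training. Deterministic given `cfg$seed`, and split r is identical
#' regardless of how many repeats are requested.
#'
#' @param groups group (bottle) id per sample.
#' @param cfg a [cv_config()].
#' @return List of splits, each `list(train, val)` of integer indices.
#' @export
group_shuffle_splits <- function(groups, cfg) {
  stopifnot(inherits(cfg, "cv_config"))
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 4L) stopf("need at least 4 distinct groups, got %d", length(gs))
  n_val <- max(1L, round(cfg$test_fraction * length(gs)))
  if (n_val >= length(gs)) stopf("test_fraction leaves no training groups")
  seeds <- derive_seeds(cfg$seed, cfg$n_repeats)
  lapply(seq_len(cfg$n_repeats), function(r) {
    val_groups <- with_seed(seeds[r], sample(gs, n_val))
    val <- which(groups %in% val_groups)
    list(train = setdiff(seq_along(groups), val), val = val)
  })
}

build_splits <- function(groups, cfg) {
  if (cfg$scheme == "logo") logo_splits(groups) else group_shuffle_splits(groups, cfg)
}

cv_result <- function(split_accuracies, cfg) {
  structure(list(split_accuracies = split_accuracies,
                 mean_accuracy = mean(split_accuracies),
                 std_accuracy = if (length(split_accuracies) > 1)
                   stats::sd(split_accuracies) else 0,
                 n_splits = length(split_accuracies),
                 config_used = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.4f (sd %.4f) over %d splits\n",
              x$config_used$scheme, x$mean_accuracy, x$std_accuracy, x$n_splits))
  invisible(x)
}

# Fast inner loop shared by cross_validate and the wrapper: per split,
# standardize on the training fold, fit, score on validation. Narrow column
# sets run entirely in C++; wide ones fall back to train_classifier/glmnet.
cv_split_accuracies <- function(X, y, cols, splits, standardize, lambda = 1.0) {
  y <- factor(y)
  if (length(cols) <= 60L) {
    tr <- lapply(splits, function(s) s$train - 1L)
    va <- lapply(splits, function(s) s$val - 1L)
    as.numeric(.cv_accuracy_cpp(X, as.integer(y) - 1L, nlevels(y),
                                as.integer(cols) - 1L, tr, va,
                                standardize, lambda, 100L, 1e-9))
  } else {
    vapply(splits, function(s) {
      model <- train_classifier(X[s$train, cols, drop = FALSE], y[s$train],
                                lambda = lambda, standardize = standardize)
      accuracy(y[s$val], predict(model, X[s$val, cols, drop = FALSE]))
    }, 0)
  }
}

#' Cross-validate a feature subset
#'
#' For each split of the chosen scheme: standardize on the training fold, fit
#' the multinomial logistic classifier, and score accuracy on the validation
#' fold. Nothing from the validation fold enters standardization or fitting.
#'
#' @param table a [feature_table()].
#' @param feature_subset character ids or integer column indices
#'   (`NULL` = all features).
#' @param cfg a [cv_config()].
#' @param lambda L2 penalty strength passed to the classifier.
#' @return A `cv_result` with `split_accuracies`, `mean_accuracy`,
#'   `std_accuracy`, `n_splits`, `config_used`.
#' @export
cross_validate <- function(table, feature_subset = NULL, cfg = cv_config(),
                           lambda = 1.0) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "cv_config"))
  cols <- resolve_subset(table, feature_subset)
  if (!length(cols)) stopf("feature_subset must be nonempty")
  splits <- build_splits(table$groups, cfg)
  acc <- cv_split_accuracies(table$values, table$labels, cols, splits,
                             cfg$standardize, lambda)
  cv_result(acc, cfg)
}

resolve_subset <- function(table, feature_subset) {
  if (is.null(feature_subset)) return(seq_len(ncol(table$values)))
  if (is.numeric(feature_subset)) {
    cols <- as.integer(feature_subset)
    if (any(cols < 1L | cols > ncol(table$values))) stopf("feature index out of range")
  } else {
    cols <- match(as.character(feature_subset), table$info$id)
    if (anyNA(cols)) {
      stopf("unknown feature id(s): %s",
            paste(feature_subset[is.na(cols)], collapse = ", "))
    }
  }
  cols
}

#' Write a cross-validation result to CSV and JSON
#'
#' The CSV holds one row per split; the JSON a summary (mean, sd, config).
#'
#' @param result a `cv_result`.
#' @param path_csv,path_json output paths (`NULL` to skip either).
#' @export
write_cv_result <- function(result, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(result, "cv_result"))
  if (!is.null(path_csv)) {
    utils::write.csv(data.frame(split = seq_len(result$n_splits),
                                accuracy = result$split_accuracies),
                     path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(mean_accuracy = result$mean_accuracy,
           std_accuracy = result$std_accuracy,
           n_splits = result$n_splits,
           config = unclass(result$config_used)),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
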