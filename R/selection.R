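#' Recursive forward (wrapper) feature selection
#'
#' Greedy wrapper: step 1 cross-validates every single feature and keeps the
#' best; step k+1 cross-validates every unchosen feature appended to the
#' current set and keeps the best. Candidate scores are mean cross-validated
#' accuracies under the given group-aware scheme; ties break deterministically
#' by column order, so the only stochastic ingredient is the split seed.
#'
#' @param table a [feature_table()].
#' @param max_k number of features to select.
#' @param cv_cfg a [cv_config()]; its `n_repeats` is the *inner* repeat count
#'   used to score every candidate (default 25 here -- each step scores
#'   hundreds of candidates, and the inner estimate only needs to rank them).
#' @param seed optional; overrides `cv_cfg$seed` for this run (the outer
#'   repetition seed of [repeat_selection()]).
#' @param lambda L2 penalty strength.
#' @return An object of class `selection_trace`: `ordered_features` (ids),
#'   `ordered_columns`, `step_mean_accuracy`, `step_std_accuracy`,
#'   `cv_config_used`, `seed`.
#' @export
forward_select <- function(table, max_k, cv_cfg = cv_config(n_repeats = 25L),
                           seed = NULL, lambda = 1.0) {
  stopifnot(inherits(table, "feature_table"), inherits(cv_cfg, "cv_config"))
  p <- ncol(table$values)
  if (max_k < 1L || max_k > p) stopf("max_k must be in 1..%d", p)
  if (!is.null(seed)) cv_cfg$seed <- as.integer(seed)
  splits <- build_splits(table$groups, cv_cfg)
  X <- table$values
  y <- table$labels
  chosen <- integer(0)
  mean_acc <- sd_acc <- numeric(max_k)
  remaining <- seq_len(p)
  for (k in seq_len(max_k)) {
    best_m <- -Inf; best_j <- NA_integer_; best_sd <- NA_real_
    for (j in remaining) {
      acc <- cv_split_accuracies(X, y, c(chosen, j), splits,
                                 cv_cfg$standardize, lambda)
      m <- mean(acc)
      if (m > best_m + 1e-12) {  # strict improvement; ties keep earlier column
        best_m <- m; best_j <- j
        best_sd <- if (length(acc) > 1) stats::sd(acc) else 0
      }
    }
    chosen <- c(chosen, best_j)
    remaining <- setdiff(remaining, best_j)
    mean_acc[k] <- best_m
    sd_acc[k] <- best_sd
  }
  structure(list(ordered_features = table$info$id[chosen],
                 ordered_columns = chosen,
                 step_mean_accuracy = mean_acc,
                 step_std_accuracy = sd_acc,
                 cv_config_used = cv_cfg,
                 seed = cv_cfg$seed),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d steps (seed %d), final accuracy %.4f\n",
              length(x$ordered_features), x$seed,
              x$step_mean_accuracy[length(x$step_mean_accuracy)]))
  for (k in seq_along(x$ordered_features)) {
    cat(sprintf("  %2d. %-28s %.4f (sd %.4f)\n", k, x$ordered_features[k],
                x$step_mean_accuracy[k], x$step_std_accuracy[k]))
  }
  invisible(x)
}

#' Repeat forward selection over several seeds
#'
#' Runs [forward_select()] with `n_seeds` distinct split seeds derived from
#' `cv_cfg$seed` and averages the per-step accuracy curves. Because many
#' features are strongly correlated, different seeds may choose different,
#' similarly performing feature sets; the averaged curve is the stable summary.
#'
#' @inheritParams forward_select
#' @param n_seeds number of outer repetitions (default 5).
#' @return List with `curve` (data.frame `k`, `mean_accuracy`, `sd_accuracy`
#'   across seeds) and `traces` (the individual `selection_trace` objects).
#' @export
repeat_selection <- function(table, max_k, cv_cfg = cv_config(n_repeats = 25L),
                             n_seeds = 5L, lambda = 1.0) {
  if (n_seeds < 1L) stopf("n_seeds must be >= 1")
  seeds <- derive_seeds(cv_cfg$seed + 1000L, n_seeds)
  traces <- lapply(seeds, function(s) {
    forward_select(table, max_k, cv_cfg, seed = s, lambda = lambda)
  })
  M <- do.call(rbind, lapply(traces, `[[`, "step_mean_accuracy"))
  curve <- data.frame(k = seq_len(max_k),
                      mean_accuracy = colMeans(M),
                      sd_accuracy = apply(M, 2, function(v)
                        if (length(v) > 1) stats::sd(v) else 0))
  list(curve = curve, traces = traces)
}

filter_ranking <- function(method, scores, ids) {
  ord <- order(-scores, ids)  # descending score, ties by id string
  structure(list(method = method,
                 scores = stats::setNames(scores, ids),
                 ranked_ids = ids[ord]),
            class = "filter_ranking")
}

#' @export
print.filter_ranking <- function(x, ...) {
  top <- utils::head(x$ranked_ids, 5)
  cat(sprintf("<filter_ranking> %s over %d features; top: %s\n",
              x$method, length(x$scores), paste(top, collapse = ", ")))
  invisible(x)
}

filter_xy <- function(X, y) {
  if (inherits(X, "feature_table")) {
    list(X = X$values, y = factor(X$labels), ids = X$info$id)
  } else {
    X <- as.matrix(X)
    ids <- colnames(X) %||% sprintf("F%03d", seq_len(ncol(X)))
    list(X = X, y = factor(y), ids = ids)
  }
}

#' Fisher scores
#'
#' Ratio of between-class to within-class variance per feature:
#' \deqn{F_j = \sum_c n_c (\mu_{cj} - \mu_j)^2 / \sum_c n_c \sigma^2_{cj}}
#' with class sample variances (n-1 denominator). A zero denominator yields
#' score 0. Scale-invariant and independent of any classifier.
#'
#' @param X feature matrix or [feature_table()].
#' @param y class labels (ignored when `X` is a feature table).
#' @return A `filter_ranking` (method `"Fisher"`).
#' @export
fisher_scores <- function(X, y = NULL) {
  d <- filter_xy(X, y)
  y <- droplevels(d$y)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  mu <- colMeans(d$X)
  between <- numeric(ncol(d$X))
  within <- numeric(ncol(d$X))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    n_c <- length(rows)
    Xc <- d$X[rows, , drop = FALSE]
    mu_c <- colMeans(Xc)
    between <- between + n_c * (mu_c - mu)^2
    v_c <- if (n_c > 1) col_sds(Xc)^2 else rep(0, ncol(d$X))
    within <- within + n_c * v_c
  }
  scores <- ifelse(within > 0, between / within, 0)
  filter_ranking("Fisher", scores, d$ids)
}

#' Mutual-information scores
#'
#' Plug-in mutual information (in bits) between each feature, discretized by
#' deterministic quantile bins, and the class label. The quantile-bin plug-in
#' estimator is chosen over nearest-neighbor estimators for exact
#' reproducibility; the bin count is exposed. Constant features score 0.
#'
#' @inheritParams fisher_scores
#' @param n_bins number of quantile bins (>= 2).
#' @return A `filter_ranking` (method `"MI"`).
#' @export
mutual_information_scores <- function(X, y = NULL, n_bins = 8L) {
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  d <- filter_xy(X, y)
  y <- droplevels(d$y)
  n <- length(y)
  scores <- vapply(seq_len(ncol(d$X)), function(j) {
    x <- d$X[, j]
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                    names = FALSE, type = 7))
    if (length(edges) < 2L) return(0)
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(b, y)
    pxy <- tab / n
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  }, 0)
  filter_ranking("MI", pmax(scores, 0), d$ids)
}

#' ReliefF scores
#'
#' Standard multi-class ReliefF with Manhattan distance on min-max-scaled
#' features. Every instance is used in deterministic row order (m = n, no
#' sampling); for each instance the k nearest same-class hits and, per other
#' class, the k nearest misses update the weights, with miss contributions
#' weighted by the class prior relative to the complement of the instance's
#' class. Feature differences are normalized by the feature range, so a
#' constant feature has weight exactly 0.
#'
#' @inheritParams fisher_scores
#' @param k_neighbors neighbors per hit/miss set; every class must have more
#'   than `k_neighbors` members.
#' @return A `filter_ranking` (method `"ReliefF"`).
#' @export
relieff_scores <- function(X, y = NULL, k_neighbors = 10L) {
  d <- filter_xy(X, y)
  y <- droplevels(d$y)
  n <- nrow(d$X); p <- ncol(d$X)
  counts <- table(y)
  if (any(counts <= k_neighbors)) {
    stopf("every class must have more than k_neighbors = %d members", k_neighbors)
  }
  rng <- apply(d$X, 2, function(v) diff(range(v)))
  scl <- ifelse(rng > 0, rng, 1)
  Z <- sweep(sweep(d$X, 2, apply(d$X, 2, min), "-"), 2, scl, "/")
  Z[, rng == 0] <- 0
  D <- as.matrix(stats::dist(Z, method = "manhattan"))
  priors <- counts / n
  W <- numeric(p)
  k <- as.integer(k_neighbors)
  for (i in seq_len(n)) {
    yi <- as.character(y[i])
    for (cl in levels(y)) {
      rows <- which(y == cl & seq_len(n) != i)
      ord <- rows[order(D[i, rows], rows)][seq_len(k)]  # ties by row index
      diffs <- colSums(abs(Z[ord, , drop = FALSE] -
                             matrix(Z[i, ], k, p, byrow = TRUE))) / (n * k)
      if (cl == yi) {
        W <- W - diffs
      } else {
        W <- W + (priors[[cl]] / (1 - priors[[yi]])) * diffs
      }
    }
  }
  filter_ranking("ReliefF", W, d$ids)
}

#' Top-k features of a filter ranking
#'
#' @param ranking a `filter_ranking`.
#' @param k number of features, `k <= n_features`.
#' @return Character vector: the first `k` of `ranked_ids`.
#' @export
filter_select <- function(ranking, k) {
  stopifnot(inherits(ranking, "filter_ranking"))
  if (k < 1L || k > length(ranking$ranked_ids)) {
    stopf("k must be in 1..%d", length(ranking$ranked_ids))
  }
  ranking$ranked_ids[seq_len(k)]
}

#' Serialize a selection trace to CSV
#'
#' @param trace a `selection_trace`.
#' @param path output CSV path.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  utils::write.csv(data.frame(step = seq_along(trace$ordered_features),
                              feature = trace$ordered_features,
                              mean_accuracy = trace$step_mean_accuracy,
                              std_accuracy = trace$step_std_accuracy),
                   path, row.names = FALSE)
  invisible(path)
}
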