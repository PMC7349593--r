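test_that("accuracy is the exact fraction of correct labels", {
  expect_equal(accuracy(c("a", "b", "a", "b"), c("a", "b", "a", "a")), 0.75)
  expect_equal(accuracy(letters[1:5], letters[1:5]), 1.0)
  expect_equal(accuracy(rep("a", 4), rep("b", 4)), 0.0)
  expect_error(accuracy(1:3, 1:4), "mismatch")
  expect_error(accuracy(character(0), character(0)), "empty")
})

test_that("the classifier separates separable classes and is deterministic", {
  set.seed(21)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  y <- rep(c("lo", "hi"), each = 20)
  m <- train_classifier(X, y)
  expect_equal(accuracy(y, predict(m, X)), 1.0)
  m2 <- train_classifier(X, y, seed = 123)
  expect_identical(predict(m, X), predict(m2, X))
  expect_true(all(as.character(predict(m, X)) %in% y))
  expect_error(train_classifier(X, rep("one", 40)), "2 classes")
  expect_error(train_classifier(cbind(c(1, NA, 3)), c("a", "b", "a")), "finite")
})

test_that("the Newton solver agrees with glmnet on the same ridge objective", {
  set.seed(22)
  n <- 120
  y <- factor(sample(c("HQ", "AQ", "LQ", "Ea"), n, TRUE))
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 1] <- X[, 1] + 1.5 * as.integer(y)
  m <- train_classifier(X, y)          # p = 5 -> Newton engine
  expect_equal(m$fit$engine, "newton")
  Xs <- scale(X)
  g <- glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                      lambda = 1 / n, standardize = FALSE)
  pg <- factor(as.vector(predict(g, Xs, type = "class")), levels = m$levels)
  expect_gte(mean(predict(m, X) == pg), 0.99)
  # wide path dispatches to glmnet and still predicts sensibly
  Xw <- cbind(X, matrix(rnorm(n * 70), n, 70))
  mw <- train_classifier(Xw, y)
  expect_equal(mw$fit$engine, "glmnet")
  expect_gt(accuracy(y, predict(mw, Xw)), 0.8)
})

test_that("LOGO splits hold out each bottle exactly once", {
  groups <- rep(sprintf("B%02d", 1:28), times = rep(3, 28))
  splits <- logo_splits(groups)
  expect_length(splits, 28)
  val_all <- sort(unlist(lapply(splits, `[[`, "val")))
  expect_equal(val_all, seq_along(groups))  # each sample in exactly one val set
  for (s in splits) {
    expect_equal(sort(c(s$train, s$val)), seq_along(groups))
    expect_length(intersect(s$train, s$val), 0)
    expect_equal(length(unique(groups[s$val])), 1)
  }
  expect_error(logo_splits(rep("B1", 5)), "2 distinct")
})

test_that("group shuffle splits respect the bottle restriction", {
  groups <- rep(sprintf("B%d", 1:4), times = c(3, 4, 5, 3))
  cfg <- cv_config("group_shuffle", test_fraction = 0.25, n_repeats = 20, seed = 3)
  splits <- group_shuffle_splits(groups, cfg)
  expect_length(splits, 20)
  for (s in splits) {
    expect_equal(length(unique(groups[s$val])), 1)  # round(0.25 * 4) = 1 group
    expect_length(intersect(unique(groups[s$train]), unique(groups[s$val])), 0)
  }
  expect_error(group_shuffle_splits(rep(c("a", "b"), 5), cfg), "4 distinct")
})

test_that("split r does not depend on how many repeats are requested", {
  groups <- rep(sprintf("B%02d", 1:12), each = 4)
  s100 <- group_shuffle_splits(groups, cv_config(n_repeats = 100, seed = 9))
  s10 <- group_shuffle_splits(groups, cv_config(n_repeats = 10, seed = 9))
  expect_identical(s100[1:10], s10)
  s10b <- group_shuffle_splits(groups, cv_config(n_repeats = 10, seed = 9))
  expect_identical(s10, s10b)
  s_other <- group_shuffle_splits(groups, cv_config(n_repeats = 10, seed = 10))
  expect_false(identical(s10, s_other))
})

test_that("a perfectly separating feature yields accuracy 1 in both schemes", {
  # 4 bottles per class so a random validation draw cannot swallow a whole
  # class; weak penalty: the check is about the CV machinery, not about how
  # strongly a middle class is shrunk on a single ordinal axis
  tab <- make_toy_table(signal_sd = 0, seed = 31, bottles_per_class = 4)
  for (scheme in c("logo", "group_shuffle")) {
    res <- cross_validate(tab, "signal", cv_config(scheme, n_repeats = 20, seed = 1),
                          lambda = 0.01)
    expect_equal(res$mean_accuracy, 1.0)
    expect_equal(res$n_splits, if (scheme == "logo") 16 else 20)
    expect_equal(res$std_accuracy, stats::sd(res$split_accuracies))
  }
})

test_that("shuffled labels score at the permutation-null level", {
  tab <- make_toy_table(signal_sd = 0, seed = 32)
  set.seed(5)
  perm <- feature_table(tab$values, tab$info,
                        sample(as.character(tab$labels)), tab$groups)
  res <- cross_validate(perm, NULL, cv_config(n_repeats = 60, seed = 2))
  expect_lt(abs(res$mean_accuracy - 0.25), 0.12)
})

test_that("standardization and fitting use only the training fold", {
  tab <- make_toy_table(seed = 33)
  cfg <- cv_config(n_repeats = 8, seed = 4)
  res <- cross_validate(tab, NULL, cfg)
  # replaying each split manually through train_classifier (train rows only)
  # must reproduce the reported split accuracies exactly
  splits <- group_shuffle_splits(tab$groups, cfg)
  manual <- vapply(splits, function(s) {
    m <- train_classifier(tab$values[s$train, ], tab$labels[s$train])
    accuracy(tab$labels[s$val], predict(m, tab$values[s$val, ]))
  }, 0)
  expect_equal(res$split_accuracies, manual, tolerance = 1e-10)
  # a pure-noise feature cannot beat the null
  noise_tab <- feature_table(matrix(rnorm(nrow(tab$values)), ncol = 1),
                             labels = tab$labels, groups = tab$groups)
  null_res <- cross_validate(noise_tab, NULL, cv_config(n_repeats = 40, seed = 6))
  expect_lt(null_res$mean_accuracy, 0.45)
})

test_that("LOGO and group shuffle agree on well-separated data", {
  tab <- make_toy_table(signal_sd = 0.2, n_noise = 2, seed = 34,
                        bottles_per_class = 4)
  a_logo <- cross_validate(tab, NULL, cv_config("logo", seed = 1),
                           lambda = 0.01)$mean_accuracy
  a_shuf <- cross_validate(tab, NULL,
                           cv_config("group_shuffle", n_repeats = 40, seed = 1),
                           lambda = 0.01)$mean_accuracy
  expect_lt(abs(a_logo - a_shuf), 0.1)
  expect_gt(a_logo, 0.9)
})

test_that("cv results serialize to CSV and JSON", {
  tab <- make_toy_table(seed = 35)
  res <- cross_validate(tab, NULL, cv_config(n_repeats = 5, seed = 1))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_cv_result(res, csv, js)
  df <- read.csv(csv)
  expect_equal(nrow(df), 5)
  expect_equal(df$accuracy, res$split_accuracies)
  j <- jsonlite::read_json(js)
  expect_equal(j$mean_accuracy, res$mean_accuracy)
  expect_equal(j$config$n_repeats, 5)
})
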