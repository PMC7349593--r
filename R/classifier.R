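#' Train the multinomial logistic classifier
#'
#' Fits a ridge-penalized (L2, strength 1 in the summed-log-likelihood
#' convention) multinomial logistic regression on z-scored features. The
#' standardization parameters are estimated from `X` only, so the model can be
#' applied to held-out data without leakage. The fit is deterministic: narrow
#' models (`p <= 60`) use the package's damped-Newton solver for the exact
#' penalized likelihood, wide models are delegated to [glmnet::glmnet()] at
#' the equivalent penalty (`lambda = strength / n`); both optimize the same
#' objective and agree on predictions.
#'
#' @param X numeric feature matrix (samples x features), finite.
#' @param y class labels (factor or character), at least two classes present.
#' @param seed accepted for interface stability; the fit itself is
#'   deterministic and does not consume random numbers.
#' @param lambda L2 penalty strength (default 1.0).
#' @param standardize z-score features before fitting (default TRUE).
#' @return An object of class `enose_model`.
#' @export
train_classifier <- function(X, y, seed = NULL, lambda = 1.0, standardize = TRUE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("X must contain only finite values")
  y <- factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) < 2L) stopf("need at least 2 classes, got %d", length(lev))
  y <- factor(as.character(y), levels = lev)
  if (nrow(X) != length(y)) stopf("X rows must match length(y)")
  mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
  if (standardize) {
    mu <- colMeans(X)
    sd <- col_sds(X)
    sd[sd <= 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  if (ncol(Xs) <= 60L) {
    B <- .ridge_multinom_cpp(Xs, as.integer(y) - 1L, length(lev), lambda,
                             100L, 1e-9)
    fit <- list(engine = "newton", B = B)
  } else {
    # short decreasing lambda path (warm starts) for reliable convergence at
    # the small target penalty; predictions are taken at the target value
    target <- lambda / nrow(Xs)
    path <- exp(seq(log(target * 1000), log(target), length.out = 8))
    g <- withCallingHandlers(
      glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                     lambda = path, standardize = FALSE, maxit = 300000),
      # routine on small resampling folds; the fold accuracy is still valid
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    fit <- list(engine = "glmnet", g = g, s = target)
  }
  structure(list(fit = fit, levels = lev, mu = mu, sd = sd, lambda = lambda,
                 standardize = standardize),
            class = "enose_model")
}

#' @export
predict.enose_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$mu, "-"), 2, object$sd, "/")
  if (object$fit$engine == "newton") {
    idx <- .rml_predict_cpp(object$fit$B, Xs)
    factor(object$levels[idx], levels = object$levels)
  } else {
    p <- predict(object$fit$g, Xs, type = "class", s = object$fit$s)
    factor(as.vector(p), levels = object$levels)
  }
}

#' @export
print.enose_model <- function(x, ...) {
  cat(sprintf("<enose_model> multinomial logistic (ridge %.3g, %s engine), %d classes, %d features\n",
              x$lambda, x$fit$engine, length(x$levels), length(x$mu)))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of properly classified records.
#'
#' @param y_true,y_pred equal-length nonempty label vectors.
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(y_true, y_pred) {
  if (!length(y_true)) stopf("empty label vectors")
  if (length(y_true) != length(y_pred)) {
    stopf("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  mean(as.character(y_true) == as.character(y_pred))
}
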