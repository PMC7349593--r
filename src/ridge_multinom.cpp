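#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Ridge-penalized multinomial logistic regression by damped Newton iteration.
//
// Objective (scikit-learn C = 1/lambda convention, full softmax
// parameterization): sum_i -log p(y_i | x_i) + 0.5 * lambda * ||slopes||^2.
// Intercepts carry a 1e-6 ridge only to remove the softmax shift
// non-identifiability from the Hessian; the slope penalty already pins the
// slopes to the minimum-norm (sum-to-zero) representative.

static double rml_objective(const mat& Xa, const mat& Y, const vec& pen,
                            const vec& b, int d, int C) {
  mat B(const_cast<double*>(b.memptr()), d, C, false, true);
  mat Eta = Xa * B;
  vec m = max(Eta, 1);
  vec lse = m + log(sum(exp(Eta.each_col() - m), 1));
  return -accu(Eta % Y) + accu(lse) + 0.5 * dot(pen, b % b);
}

static mat rml_fit(const mat& X, const uvec& yi, int C, double lambda,
                   int maxit, double tol) {
  int n = X.n_rows, p = X.n_cols, d = p + 1;
  mat Xa = join_horiz(ones(n), X);
  mat Y(n, C, fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, yi[i]) = 1.0;
  vec pen(d * C);
  for (int c = 0; c < C; ++c) {
    pen[c * d] = 1e-6;
    for (int j = 1; j < d; ++j) pen[c * d + j] = lambda;
  }
  vec b(d * C, fill::zeros);
  double f0 = rml_objective(Xa, Y, pen, b, d, C);
  for (int it = 0; it < maxit; ++it) {
    mat B(b.memptr(), d, C, false, true);
    mat Eta = Xa * B;
    vec m = max(Eta, 1);
    mat P = exp(Eta.each_col() - m);
    P.each_col() /= sum(P, 1);
    vec g = vectorise(Xa.t() * (P - Y)) + pen % b;
    mat H(d * C, d * C, fill::zeros);
    for (int a = 0; a < C; ++a) {
      for (int c2 = a; c2 < C; ++c2) {
        vec w = (a == c2) ? vec(P.col(a) % (1.0 - P.col(a)))
                          : vec(-P.col(a) % P.col(c2));
        mat blk = Xa.t() * (Xa.each_col() % w);
        H.submat(a * d, c2 * d, (a + 1) * d - 1, (c2 + 1) * d - 1) = blk;
        if (a != c2)
          H.submat(c2 * d, a * d, (c2 + 1) * d - 1, (a + 1) * d - 1) = blk;
      }
    }
    H.diag() += pen;
    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) step = g / H.diag().max();
    // step halving guards the rare overshoot on near-separable folds
    double t = 1.0, fn = f0;
    vec bn = b;
    while (true) {
      bn = b - t * step;
      fn = rml_objective(Xa, Y, pen, bn, d, C);
      if (fn <= f0 + 1e-12 || t < 1e-4) break;
      t *= 0.5;
    }
    b = bn;
    bool converged = std::fabs(f0 - fn) < tol * (std::fabs(f0) + 1.0);
    f0 = fn;
    if (converged) break;
  }
  return mat(b.memptr(), d, C);
}

// [[Rcpp::export(name = ".ridge_multinom_cpp")]]
arma::mat ridge_multinom_cpp(const arma::mat& X, const arma::uvec& yi, int n_classes,
                             double lambda, int maxit = 100, double tol = 1e-9) {
  return rml_fit(X, yi, n_classes, lambda, maxit, tol);
}

// [[Rcpp::export(name = ".rml_predict_cpp")]]
arma::uvec rml_predict_cpp(const arma::mat& B, const arma::mat& X) {
  mat Eta = join_horiz(ones(X.n_rows), X) * B;
  return index_max(Eta, 1) + 1;  // 1-based class index
}

// Per-split cross-validated accuracy for one candidate column set.
// Standardization (train-fold statistics only) and fitting both happen here so
// the wrapper's inner loop pays a single R-to-C++ call per candidate.
// [[Rcpp::export(name = ".cv_accuracy_cpp")]]
arma::vec cv_accuracy_cpp(const arma::mat& X, const arma::uvec& yi, int n_classes,
                          const arma::uvec& cols, const Rcpp::List& train_sets,
                          const Rcpp::List& val_sets, bool standardize,
                          double lambda, int maxit = 100, double tol = 1e-9) {
  int S = train_sets.size();
  vec acc(S);
  mat Xc = X.cols(cols);
  for (int s = 0; s < S; ++s) {
    uvec tr = Rcpp::as<uvec>(train_sets[s]);
    uvec va = Rcpp::as<uvec>(val_sets[s]);
    mat Xtr = Xc.rows(tr);
    mat Xva = Xc.rows(va);
    if (standardize) {
      rowvec mu = mean(Xtr, 0);
      rowvec sd = stddev(Xtr, 0, 0);
      sd.elem(find(sd <= 0)).fill(1.0);
      Xtr.each_row() -= mu; Xtr.each_row() /= sd;
      Xva.each_row() -= mu; Xva.each_row() /= sd;
    }
    uvec ytr = yi.elem(tr);
    mat B = rml_fit(Xtr, ytr, n_classes, lambda, maxit, tol);
    mat Eta = join_horiz(ones(Xva.n_rows), Xva) * B;
    uvec pred = index_max(Eta, 1);
    uvec yva = yi.elem(va);
    acc[s] = mean(conv_to<vec>::from(pred == yva));
  }
  return acc;
}
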