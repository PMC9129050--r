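// Compiled kernels for the permutation-heavy paths: the graphical lasso
// (blockwise coordinate descent, Friedman-style) and the iterated-GLS
// meta-regression slope recomputed for thousands of assignment columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso: maximise log det(Theta) - tr(S Theta) - rho ||Theta||_1
// (off-diagonal penalty applied to all entries, as in the reference
// algorithm). Returns the precision matrix Theta and covariance W.
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      double tol = 1e-4, int maxit = 200) {
  const int p = S.n_rows;
  mat W = S;
  W.diag() += rho;
  mat B(p, p, fill::zeros);  // lasso coefficients, column j = beta for block j

  if (p == 1) {
    mat Theta(1, 1);
    Theta(0, 0) = 1.0 / W(0, 0);
    return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                              Rcpp::Named("w") = W,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  const double thr = tol * mean(mean(abs(S - diagmat(S.diag()))));
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double dw_max = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      for (int k = 0, c = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);
      // coordinate descent on 0.5 b'W11 b - b's12 + rho |b|_1
      for (int cd = 0; cd < 1000; ++cd) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12(k) - dot(W11.row(k), beta) + W11(k, k) * beta(k);
          double bnew = soft(r, rho) / W11(k, k);
          double d = std::abs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < 1e-7) break;
      }
      vec w12 = W11 * beta;
      for (int k = 0, c = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::abs(W(k, j) - w12(c));
        if (d > dw_max) dw_max = d;
        W(k, j) = w12(c);
        W(j, k) = w12(c);
        B(idx(c), j) = beta(c);
        ++c;
      }
    }
    if (dw_max < thr || thr == 0.0) { converged = true; break; }
  }

  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (int k = 0, c = 0; k < p; ++k) if (k != j) idx(c++) = k;
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (int c = 0; c < p - 1; ++c) Theta(idx(c), j) = -beta(c) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged);
}

// Meta-regression (random-effects) slope of a binary indicator, refit for
// every assignment column. Model: y_i = b0 + b1 w_i + u_i + e_i with
// Var(e_i) = se2_i known and Var(u_i) = s2u estimated by iterated
// method-of-moments; GLS weights 1/(se2_i + s2u).
// [[Rcpp::export(name = ".betta_slope_cols")]]
arma::vec betta_slope_cols(const arma::vec& y, const arma::vec& se2,
                           const arma::mat& Wcols,
                           double tol = 1e-8, int maxit = 100) {
  const int n = y.n_elem;
  const int L = Wcols.n_cols;
  vec out(L);
  const double mse2 = mean(se2);
  for (int l = 0; l < L; ++l) {
    vec x = Wcols.col(l);
    double s2u = 0.0, b1 = 0.0;
    for (int it = 0; it < maxit; ++it) {
      vec denom = se2 + s2u;
      vec w;
      if (denom.max() <= 0.0) w = vec(n, fill::ones); else w = 1.0 / denom;
      double sw = accu(w);
      double swx = dot(w, x), swy = dot(w, y);
      double swxx = dot(w, x % x), swxy = dot(w, x % y);
      double det = sw * swxx - swx * swx;
      b1 = (sw * swxy - swx * swy) / det;
      double b0 = (swy - b1 * swx) / sw;
      vec r = y - b0 - b1 * x;
      double s2u_new = accu(r % r) / std::max(n - 2, 1) - mse2;
      if (s2u_new < 0.0) s2u_new = 0.0;
      if (std::abs(s2u_new - s2u) < tol * (1.0 + s2u)) { s2u = s2u_new; break; }
      s2u = s2u_new;
    }
    out(l) = b1;
  }
  return out;
}
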