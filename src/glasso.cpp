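#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-threshold operator.
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso with unpenalized diagonal, by block coordinate descent
// (lasso regression per column of the working covariance W).  Maximizes
//   log det K - trace(S K) - lambda * sum_{i != j} |K_ij|
// Convergence is declared on the duality gap
//   trace(S K) + lambda * ||K||_{1,off} - log det K - log det W - p,
// where W is the working covariance (dual feasible after the first sweep:
// every off-diagonal satisfies |W_ij - S_ij| <= lambda by the lasso KKT
// conditions and the diagonal is fixed at diag(S)).  The gap is zero at
// the optimum and bounds the primal suboptimality from above.
//
// W_init / B_init allow warm starts along a penalty path; pass warm = false
// to start from W = S, B = 0.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int max_iter, double tol,
                      arma::mat W_init, arma::mat B_init, bool warm) {
  const int p = S.n_rows;
  if (p == 1) {
    mat K(1, 1); K(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("K") = K,
                              Rcpp::Named("W") = S,
                              Rcpp::Named("B") = mat(0, 1, fill::zeros),
                              Rcpp::Named("gap") = 0.0,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  mat W = warm ? W_init : mat(S);
  W.diag() = S.diag();                 // diagonal never penalized
  mat B = warm ? B_init : mat(p - 1, p, fill::zeros);

  const double inner_tol = 1e-9;
  const int inner_max = 1000;

  mat K(p, p, fill::zeros);
  double gap = datum::inf;
  int it = 0;
  bool converged = false;

  // index helper: rows of the j-th subproblem are 0..p-1 without j
  std::vector<uword> idx(p - 1);

  for (it = 1; it <= max_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx[c++] = k;
      uvec ii(idx);

      mat V = W.submat(ii, ii);
      vec s12 = S.col(j); s12.shed_row(j);
      vec beta = B.col(j);

      for (int inner = 0; inner < inner_max; ++inner) {
        double delta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12(k) - dot(V.col(k), beta) + V(k, k) * beta(k);
          double bnew = soft(r, lambda) / V(k, k);
          double d = std::fabs(bnew - beta(k));
          if (d > delta) delta = d;
          beta(k) = bnew;
        }
        if (delta < inner_tol) break;
      }

      B.col(j) = beta;
      vec w12 = V * beta;
      for (int k = 0; k < p - 1; ++k) {
        W(ii(k), j) = w12(k);
        W(j, ii(k)) = w12(k);
      }
    }

    // assemble the precision matrix from the column solutions
    for (int j = 0; j < p; ++j) {
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx[c++] = k;
      uvec ii(idx);
      vec beta = B.col(j);
      vec w12(p - 1);
      for (int k = 0; k < p - 1; ++k) w12(k) = W(ii(k), j);
      double denom = W(j, j) - dot(w12, beta);
      if (denom <= 0.0)
        Rcpp::stop("graphical lasso failed: nonpositive conditional variance (input not positive definite?)");
      double kjj = 1.0 / denom;
      K(j, j) = kjj;
      for (int k = 0; k < p - 1; ++k) K(ii(k), j) = -beta(k) * kjj;
    }
    K = 0.5 * (K + K.t());

    double ldK, ldW, sgn;
    bool okK = log_det(ldK, sgn, K);
    bool okW = log_det(ldW, sgn, W);
    if (okK && okW) {
      double l1_off = accu(abs(K)) - accu(abs(K.diag()));
      gap = accu(S % K) + lambda * l1_off - ldK - ldW
            - static_cast<double>(p);
      if (std::fabs(gap) < tol) { converged = true; break; }
    }
  }

  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("gap") = gap,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
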