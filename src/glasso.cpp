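#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for the lasso-penalised quadratic subproblem
//   min_b  0.5 b'Vb - u'b + lambda ||b||_1
// V is symmetric positive definite with strictly positive diagonal.
static void lasso_cd(const mat& V, const vec& u, vec& b, double lambda,
                     int maxit, double tol, const uvec& free_coord) {
  const uword m = V.n_rows;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < m; ++j) {
      if (!free_coord(j)) { b(j) = 0.0; continue; }
      const double bj_old = b(j);
      // partial residual: u_j - sum_{k != j} V_jk b_k
      const double r = u(j) - dot(V.col(j), b) + V(j, j) * bj_old;
      double bj = 0.0;
      if (r > lambda)       bj = (r - lambda) / V(j, j);
      else if (r < -lambda) bj = (r + lambda) / V(j, j);
      b(j) = bj;
      const double d = std::fabs(bj - bj_old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) break;
  }
}

// Graphical lasso by block coordinate descent over rows/columns of the
// working covariance W (Friedman-style sweeps). The L1 penalty applies to
// off-diagonal precision elements only unless penalize_diagonal is set.
// `mask` optionally forces off-diagonal precision entries to zero
// (mask(i,j) == 0): with lambda = 0 this yields the MLE restricted to a
// given support, used for EBIC evaluation and unshrunk partial correlations.
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, bool penalize_diagonal,
                     int maxit, double tol,
                     Rcpp::Nullable<Rcpp::IntegerMatrix> mask = R_NilValue) {
  const uword p = S.n_rows;
  umat free_entry(p, p, fill::ones);
  if (mask.isNotNull()) {
    Rcpp::IntegerMatrix m_(mask);
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        free_entry(i, j) = m_(i, j) != 0 ? 1 : 0;
    free_entry.diag().ones();
  }
  mat W = S;
  if (penalize_diagonal) W.diag() += lambda;

  mat B(p - 1, p, fill::zeros);   // lasso coefficients per target column
  std::vector<uvec> others(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword k = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(k++) = i;
    others[j] = idx;
  }

  double sweep_change = datum::inf;
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxit; ++iter) {
    sweep_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = others[j];
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      uvec fc(p - 1);
      for (uword k = 0; k < p - 1; ++k) fc(k) = free_entry(idx(k), j);
      lasso_cd(V, s12, b, lambda, 1000, tol * 0.1, fc);
      B.col(j) = b;
      vec w12 = V * b;
      for (uword k = 0; k < p - 1; ++k) {
        const double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > sweep_change) sweep_change = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (sweep_change < tol) { converged = true; break; }
  }

  // Recover the precision matrix from the final (W, B) pair.
  mat Omega(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& idx = others[j];
    vec b = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    const double theta22 = 1.0 / (W(j, j) - dot(w12, b));
    Omega(j, j) = theta22;
    for (uword k = 0; k < p - 1; ++k)
      Omega(idx(k), j) = -b(k) * theta22;
  }
  Omega = 0.5 * (Omega + Omega.t());

  return Rcpp::List::create(
    Rcpp::Named("omega") = Omega,
    Rcpp::Named("w") = W,
    Rcpp::Named("iterations") = iter > maxit ? maxit : iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("max_change") = sweep_change);
}
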