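// Graphical lasso with an element-wise penalty matrix.
//
// Minimizes over positive-definite Theta:
//     tr(S Theta) - log det Theta + sum_{i != j} P_ij |Theta_ij|
// by block coordinate descent on the covariance estimate W (Friedman-style):
// each column update solves a lasso subproblem
//     min_beta 1/2 beta' W11 beta - s12' beta + sum p12 |beta|
// by cyclic coordinate descent with soft-thresholding. The penalty is
// per-entry, which is what genomic-distance penalization needs; a scalar
// penalty is the special case of a constant matrix.
//
// Zeros are exact: soft-thresholded beta coefficients are exactly zero, and
// Theta is reassembled from the betas, so the sparsity pattern carries no
// round-off.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// cyclic coordinate descent for one lasso subproblem, warm-started in beta
static void lasso_cd(const mat& W11, const vec& s12, const vec& p12,
                     vec& beta, double tol, int max_sweeps) {
  const uword q = s12.n_elem;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = beta(k);
      // residual gradient excluding k
      double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
      double bnew;
      if (r > p12(k)) {
        bnew = (r - p12(k)) / W11(k, k);
      } else if (r < -p12(k)) {
        bnew = (r + p12(k)) / W11(k, k);
      } else {
        bnew = 0.0;
      }
      if (bnew != old) {
        beta(k) = bnew;
        double d = std::abs(bnew - old);
        if (d > max_delta) max_delta = d;
      }
    }
    if (max_delta < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List glasso_penalized_cpp(const arma::mat& S, const arma::mat& P,
                                double tol, int max_iter) {
  const uword p = S.n_rows;
  mat W = S;                 // diagonal stays S_ii (penalty diagonal is zero)
  mat B(p > 1 ? p - 1 : 1, p, fill::zeros);  // warm-started betas per column
  bool converged = false;

  if (p == 1) {
    mat Theta(1, 1);
    Theta(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("W") = W,
                              Rcpp::Named("Theta") = Theta,
                              Rcpp::Named("converged") = true,
                              Rcpp::Named("iterations") = 0);
  }

  const double inner_tol = tol / 10.0;
  const int inner_sweeps = 200;
  // scale for the outer convergence test: mean absolute off-diagonal of S
  double s_offdiag = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) s_offdiag += std::abs(S(i, j));
  s_offdiag /= (double)(p * (p - 1));
  const double thresh = tol * std::max(s_offdiag, 1e-12);

  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);  s12.shed_row(j);
      vec p12 = P.col(j);  p12.shed_row(j);
      vec beta = B.col(j);
      lasso_cd(W11, s12, p12, beta, inner_tol, inner_sweeps);
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > max_change) max_change = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_change < thresh) { converged = true; break; }
  }

  // reassemble Theta from the final betas:
  //   theta_jj = 1 / (w_jj - w12' beta),  theta_12 = -beta * theta_jj
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    vec beta = B.col(j);
    vec w12 = W.col(j);  w12.shed_row(j);
    double denom = W(j, j) - dot(w12, beta);
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p - 1; ++k) {
      Theta(idx(k), j) = -beta(k) * tjj;
    }
  }
  // symmetrize without destroying exact zeros: a pair is zero iff both
  // triangles are zero; otherwise average
  for (uword i = 0; i < p; ++i) {
    for (uword j = i + 1; j < p; ++j) {
      if (Theta(i, j) == 0.0 && Theta(j, i) == 0.0) continue;
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = iter);
}
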