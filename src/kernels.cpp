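// Compiled hot paths: SNIP baseline clipping and Lawson-Hanson NNLS on
// normal equations (applied column-wise for whole-image unmixing).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// SNIP iterative peak clipping, one spectrum per row of Y.
// Window half-width grows p = 1..iterations; each pass uses the previous
// pass's values (simultaneous update); out-of-range indices clamp to the
// nearest valid channel.
// [[Rcpp::export(name = ".snip_rows")]]
NumericMatrix snip_rows(NumericMatrix Y, int iterations) {
  const int n = Y.nrow(), m = Y.ncol();
  NumericMatrix B(n, m);
  std::vector<double> buf(m), tmp(m);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < m; ++i) buf[i] = Y(r, i);
    for (int p = 1; p <= iterations; ++p) {
      for (int i = 0; i < m; ++i) {
        // shrink the window symmetrically near the edges so that linear
        // (and convex) baselines are fixed points everywhere
        const int pe = std::min(p, std::min(i, m - 1 - i));
        const double avg = 0.5 * (buf[i - pe] + buf[i + pe]);
        tmp[i] = std::min(buf[i], avg);
      }
      buf.swap(tmp);
    }
    for (int i = 0; i < m; ++i) B(r, i) = buf[i];
  }
  return B;
}

// Lawson-Hanson active-set NNLS for one RHS, working on the normal
// equations (EtE, Etb precomputed by the caller).
static arma::vec nnls_normal(const arma::mat& EtE, const arma::vec& Etb,
                             double tol) {
  const arma::uword p = EtE.n_rows;
  arma::vec x(p, arma::fill::zeros);
  std::vector<bool> passive(p, false);
  arma::vec w = Etb;  // gradient at x = 0
  for (int outer = 0; outer < 30 * (int)p; ++outer) {
    // pick the most violating free variable
    int j = -1; double wmax = tol;
    for (arma::uword i = 0; i < p; ++i)
      if (!passive[i] && w(i) > wmax) { wmax = w(i); j = (int)i; }
    if (j < 0) break;
    passive[j] = true;
    for (;;) {
      arma::uvec P;
      { std::vector<arma::uword> idx;
        for (arma::uword i = 0; i < p; ++i) if (passive[i]) idx.push_back(i);
        P = arma::uvec(idx); }
      arma::vec s = arma::solve(EtE.submat(P, P), Etb.elem(P),
                                arma::solve_opts::likely_sympd);
      if (s.min() > 0) {
        x.zeros();
        x.elem(P) = s;
        break;
      }
      double alpha = 1.0;
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        if (s(k) <= 0) {
          const double xi = x(P(k));
          const double a = xi / (xi - s(k));
          if (a < alpha) alpha = a;
        }
      }
      for (arma::uword k = 0; k < P.n_elem; ++k)
        x(P(k)) += alpha * (s(k) - x(P(k)));
      for (arma::uword k = 0; k < P.n_elem; ++k)
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0; }
    }
    w = Etb - EtE * x;
  }
  return x;
}

// Batch NNLS: columns of B are spectra, columns of the result are the
// non-negative coefficient vectors; second row block returns residual norms.
// [[Rcpp::export(name = ".nnls_batch")]]
List nnls_batch(const arma::mat& E, const arma::mat& B) {
  const arma::mat EtE = E.t() * E;
  const arma::mat EtB = E.t() * B;
  const double tol = 10.0 * arma::datum::eps * arma::norm(EtE, 1) *
                     (double)EtE.n_rows;
  arma::mat X(E.n_cols, B.n_cols);
  arma::vec resid(B.n_cols);
  for (arma::uword c = 0; c < B.n_cols; ++c) {
    arma::vec x = nnls_normal(EtE, EtB.col(c), tol);
    X.col(c) = x;
    resid(c) = arma::norm(B.col(c) - E * x, 2);
  }
  return List::create(Named("coefficients") = X, Named("residual") = resid);
}
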