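#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
// Deterministic; returns exact zeros for passive variables, which is what the
// effective-ensemble-size bookkeeping relies on.
static vec nnls_lawson_hanson(const mat& A, const vec& b, double tol, int maxit) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * b;
  int iter = 0;
  bool warned = false;

  while (true) {
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0 || wmax <= tol) break;
    passive[t] = true;

    while (true) {
      if (++iter > maxit) {
        if (!warned) Rcpp::warning("NNLS iteration cap reached; returning current feasible solution");
        return x;
      }
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast);
      if (!ok) z = pinv(A.cols(P)) * b;

      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step back to the feasible boundary, drop variables that hit zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword k = 0; k < np; ++k) x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < np; ++k) {
        if (x(P(k)) <= 0) { x(P(k)) = 0.0; passive[P(k)] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// Gradient tolerance must scale with the data: the optimality gradient
// A'(b - Ax) carries the squared scale of the augmented system.
static double nnls_tol(const mat& A, const vec& b) {
  return 100.0 * datum::eps * norm(A, "fro") * norm(b, 2);
}

// [[Rcpp::export(name = ".nnls_cpp")]]
arma::vec nnls_cpp(const arma::mat& A, const arma::vec& b) {
  return nnls_lawson_hanson(A, b, nnls_tol(A, b),
                            50 * static_cast<int>(A.n_cols) + 500);
}

// Population assignment for one candidate ensemble: weighted system augmented
// with a sum-to-one row of value lambda.
static void eval_members(const mat& predT, const vec& wd, const vec& w,
                         const uvec& idx0, double lambda,
                         vec& pops, double& rmsd, int& neff) {
  const uword k = idx0.n_elem, n = predT.n_rows;
  mat A(n + 1, k);
  for (uword j = 0; j < k; ++j) {
    A.col(j).head(n) = w % predT.col(idx0(j));
    A(n, j) = lambda;
  }
  vec d(n + 1);
  d.head(n) = wd;
  d(n) = lambda;
  pops = nnls_lawson_hanson(A, d, nnls_tol(A, d), 50 * static_cast<int>(k) + 500);
  // populations below 1e-9 are numerical residue of a degenerate solve
  // (the active set returns exact zeros otherwise) and count as zero
  for (uword j = 0; j < k; ++j) if (pops(j) <= 1e-9) pops(j) = 0.0;
  vec fit(n, fill::zeros);
  for (uword j = 0; j < k; ++j) if (pops(j) > 0) fit += pops(j) * (w % predT.col(idx0(j)));
  rmsd = std::sqrt(mean(square(wd - fit)));
  neff = 0;
  for (uword j = 0; j < k; ++j) if (pops(j) > 0) ++neff;
}

// [[Rcpp::export(name = ".nnls_populations_cpp")]]
Rcpp::List nnls_populations_cpp(const arma::mat& predT, const arma::vec& data,
                                const arma::vec& weights, const arma::uvec& members,
                                double lambda) {
  vec wd = weights % data;
  vec pops;
  double rmsd;
  int neff;
  eval_members(predT, wd, weights, members - 1, lambda, pops, rmsd, neff);
  return Rcpp::List::create(Rcpp::Named("populations") = pops,
                            Rcpp::Named("rmsd") = rmsd,
                            Rcpp::Named("n_eff") = neff);
}

// Batch scoring used by the genetic algorithm: each column of `members` is a
// candidate ensemble (1-based pool indices, duplicates allowed and collapsed).
// [[Rcpp::export(name = ".score_ensembles_cpp")]]
Rcpp::List score_ensembles_cpp(const arma::mat& predT, const arma::vec& data,
                               const arma::vec& weights, const arma::imat& members,
                               double lambda) {
  const uword npop = members.n_cols;
  vec wd = weights % data;
  Rcpp::NumericVector rmsd(npop);
  Rcpp::IntegerVector neff(npop);
  Rcpp::List pops(npop), uniq(npop);
  for (uword c = 0; c < npop; ++c) {
    std::vector<int> m(members.colptr(c), members.colptr(c) + members.n_rows);
    std::sort(m.begin(), m.end());
    m.erase(std::unique(m.begin(), m.end()), m.end());
    uvec idx0(m.size());
    for (size_t j = 0; j < m.size(); ++j) idx0(j) = m[j] - 1;
    vec p;
    double r;
    int ne;
    eval_members(predT, wd, weights, idx0, lambda, p, r, ne);
    rmsd[c] = r;
    neff[c] = ne;
    pops[c] = p;
    uniq[c] = Rcpp::IntegerVector(m.begin(), m.end());
  }
  return Rcpp::List::create(Rcpp::Named("rmsd") = rmsd, Rcpp::Named("n_eff") = neff,
                            Rcpp::Named("populations") = pops,
                            Rcpp::Named("members") = uniq);
}
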