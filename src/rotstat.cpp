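#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Uniform random rotation from a random unit quaternion drawn with R's RNG,
// so results are reproducible through set.seed().
static mat33 random_rotation() {
  double q0 = R::norm_rand(), q1 = R::norm_rand(), q2 = R::norm_rand(), q3 = R::norm_rand();
  double nrm = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
  q0 /= nrm; q1 /= nrm; q2 /= nrm; q3 /= nrm;
  mat33 R;
  R(0, 0) = 1 - 2 * (q2 * q2 + q3 * q3);
  R(0, 1) = 2 * (q1 * q2 - q0 * q3);
  R(0, 2) = 2 * (q1 * q3 + q0 * q2);
  R(1, 0) = 2 * (q1 * q2 + q0 * q3);
  R(1, 1) = 1 - 2 * (q1 * q1 + q3 * q3);
  R(1, 2) = 2 * (q2 * q3 - q0 * q1);
  R(2, 0) = 2 * (q1 * q3 - q0 * q2);
  R(2, 1) = 2 * (q2 * q3 + q0 * q1);
  R(2, 2) = 1 - 2 * (q1 * q1 + q2 * q2);
  return R;
}

// [[Rcpp::export(name = ".random_rotations_cpp")]]
Rcpp::NumericVector random_rotations_cpp(int n) {
  Rcpp::NumericVector out(9 * n);
  for (int i = 0; i < n; ++i) {
    mat33 R = random_rotation();
    std::copy(R.memptr(), R.memptr() + 9, out.begin() + 9 * i);
  }
  out.attr("dim") = Rcpp::IntegerVector::create(3, 3, n);
  return out;
}

// Monte-Carlo frequency of one metal's rotational-ensemble order parameter
// exceeding `ratio` times the other's, both metals sharing the same random
// rotations with equal populations. Order parameters are compared as |S|.
// [[Rcpp::export(name = ".rotation_order_stat_cpp")]]
double rotation_order_stat_cpp(const arma::mat& chiA, const arma::mat& chiB,
                               int n_rot, double ratio, double n_trials) {
  vec wA, wB;
  eig_sym(wA, chiA);  // ascending eigenvalues
  eig_sym(wB, chiB);
  const double sA2 = dot(wA, wA), sB2 = dot(wB, wB);
  double count = 0;
  mat33 avgA, avgB;
  for (double t = 0; t < n_trials; ++t) {
    avgA.zeros();
    avgB.zeros();
    for (int k = 0; k < n_rot; ++k) {
      mat33 R = random_rotation();
      avgA += R * chiA * R.t();
      avgB += R * chiB * R.t();
    }
    avgA /= n_rot;
    avgB /= n_rot;
    vec wa, wb;
    eig_sym(wa, avgA);
    eig_sym(wb, avgB);
    double SA = std::fabs(dot(wa, wA) / sA2);
    double SB = std::fabs(dot(wb, wB) / sB2);
    if (SA > ratio * SB) ++count;
  }
  return count;
}
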