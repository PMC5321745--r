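#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood of observed annual occupancy transitions under
// the discrete-time SPOM: an empty patch is colonized with probability
// 1 - exp(-c * S_i(t)) where S_i(t) = A_i^im sum_j O_j(t) A_j^em e^{-alpha d_ij},
// and an occupied patch goes extinct with probability
// 1 - exp(-e * A_i^{-ex} * exp(-y * Q_i)).
// O is coded 1 occupied, 0 empty, -1 unsurveyed; transitions with either
// endpoint unsurveyed are skipped, and unsurveyed sources contribute no
// immigrants (their occupancy is unknown and treated as 0).
// pars = (e, c, ex, im, em, alpha, y).
// [[Rcpp::export]]
double spom_transition_loglik(NumericVector pars, NumericVector A,
                              NumericVector Q, NumericMatrix D,
                              IntegerMatrix O) {
  const double e = pars[0], c = pars[1], ex = pars[2], im = pars[3],
               em = pars[4], alpha = pars[5], y = pars[6];
  const int n = A.size(), T = O.ncol();
  if (D.nrow() != n || O.nrow() != n) stop("dimension mismatch");

  std::vector<double> Aem(n), Aim(n), logPext(n), log1mPext(n);
  for (int i = 0; i < n; ++i) {
    Aem[i] = std::pow(A[i], em);
    Aim[i] = std::pow(A[i], im);
    double E = e * std::pow(A[i], -ex) * std::exp(-y * Q[i]);
    double pext = -std::expm1(-E);            // 1 - exp(-E)
    if (pext <= 0) pext = 1e-300;
    if (pext >= 1) pext = 1 - 1e-12;
    logPext[i] = std::log(pext);
    log1mPext[i] = -E;
  }

  // kernel weighted by source emigration factor, zero diagonal
  std::vector<double> K((size_t)n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      K[(size_t)j * n + i] = (i == j) ? 0.0 : Aem[j] * std::exp(-alpha * D(i, j));

  double ll = 0.0;
  std::vector<double> R(n);
  for (int t = 0; t < T - 1; ++t) {
    std::fill(R.begin(), R.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (O(j, t) != 1) continue;
      const double *col = &K[(size_t)j * n];
      for (int i = 0; i < n; ++i) R[i] += col[i];
    }
    for (int i = 0; i < n; ++i) {
      int from = O(i, t), to = O(i, t + 1);
      if (from < 0 || to < 0) continue;
      if (from == 0) {
        double cs = c * Aim[i] * R[i];
        if (to == 1) {
          double pcol = -std::expm1(-cs);
          ll += (pcol > 0) ? std::log(pcol) : -690.0;  // log(1e-300)
        } else {
          ll += -cs;
        }
      } else {
        ll += (to == 0) ? logPext[i] : log1mPext[i];
      }
    }
  }
  return ll;
}
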