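#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Supervised admixture EM, one independent run per animal.
//
// For animal i with genotypes g_j in {0,1,2} and fixed breed frequencies
// f_kj (clamped away from 0/1 by the caller), the EM update is
//   q_k <- (1/2M) * sum_j [ g_j q_k f_kj / p_j + (2-g_j) q_k (1-f_kj) / (1-p_j) ]
// with p_j = sum_k q_k f_kj. Writing w1 = g_j/p_j and w0 = (2-g_j)/(1-p_j),
// the bracket is q_k [ (w1 - w0) f_kj + w0 ], so each locus costs one
// K-length dot product and one K-length fused multiply-add. The
// log-likelihood
//   LL = sum_j [ g_j log p_j + (2-g_j) log(1-p_j) ]
// is non-decreasing under the update; it is evaluated every
// `check_interval` updates (1 = every iteration) both to test convergence
// (improvement since the last evaluation < tol) and to assert
// monotonicity.
//
// [[Rcpp::export]]
List em_admixture_cpp(NumericMatrix G, NumericMatrix F, double tol,
                      int max_iter, int check_interval) {
  const int n = G.nrow(), M = G.ncol(), K = F.nrow();
  if (F.ncol() != M) stop("dimension mismatch between G and F");
  if (check_interval < 1) check_interval = 1;
  NumericMatrix Q(n, K);
  NumericVector ll_out(n);
  IntegerVector iters(n);
  LogicalVector conv(n);
  const double *Gp = REAL(G), *Fp = REAL(F);
  std::vector<double> q(K), a(K);

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) q[k] = 1.0 / K;
    double ll_prev = R_NegInf;
    double llv = R_NegInf;
    int done = 0;
    bool converged = false;

    while (true) {
      const bool check = (done % check_interval == 0) || done >= max_iter;
      std::fill(a.begin(), a.end(), 0.0);
      double ll_acc = 0.0, w0_sum = 0.0;
      for (int j = 0; j < M; ++j) {
        const double *fj = Fp + (size_t)j * K;   // F is K x M, column j
        double p = 0.0;
        for (int k = 0; k < K; ++k) p += q[k] * fj[k];
        const double g = Gp[(size_t)j * n + i];  // G is n x M
        double w, w0;                            // one division per locus
        if (g == 0.0) {
          w0 = 2.0 / (1.0 - p);
          w = -w0;
          if (check) ll_acc += 2.0 * std::log1p(-p);
        } else if (g == 2.0) {
          w0 = 0.0;
          w = 2.0 / p;
          if (check) ll_acc += 2.0 * std::log(p);
        } else {
          const double inv = 1.0 / (p * (1.0 - p));
          w0 = p * inv;
          w = (1.0 - p) * inv - w0;
          if (check) ll_acc += std::log(p) + std::log1p(-p);
        }
        w0_sum += w0;
        for (int k = 0; k < K; ++k) a[k] += w * fj[k];
      }
      if (check) {
        llv = ll_acc;
        if (ll_prev > R_NegInf &&
            llv < ll_prev - 1e-8 * (std::fabs(ll_prev) + 1.0)) {
          stop("EM log-likelihood decreased: numerical failure");
        }
        if (ll_prev > R_NegInf && llv - ll_prev < tol) {
          converged = true;
          break;
        }
        if (done >= max_iter) break;
        ll_prev = llv;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        q[k] *= (a[k] + w0_sum) / (2.0 * M);
        s += q[k];
      }
      for (int k = 0; k < K; ++k) q[k] /= s;  // guard simplex drift
      ++done;
    }
    for (int k = 0; k < K; ++k) Q(i, k) = q[k];
    ll_out[i] = llv;
    iters[i] = done;
    conv[i] = converged;
  }
  return List::create(_["Q"] = Q, _["loglik"] = ll_out,
                      _["iterations"] = iters, _["converged"] = conv);
}
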