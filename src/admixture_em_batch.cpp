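#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <vector>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Batch supervised-admixture EM: all animals iterated together so the two
// rate-limiting products per update, P = Q F and A = W1 F' + W0 (1-F)',
// run through BLAS dgemm on preallocated buffers. Every animal keeps being
// refined until all have converged (block log-likelihood improvement over
// `check_interval` updates below tol) or `max_iter` is reached; the
// log-likelihood is asserted non-decreasing at every evaluation.
//
// G is n x M (animals x loci, values 0/1/2), F is K x M (breeds x loci,
// clamped away from 0 and 1).
//
// [[Rcpp::export]]
List em_admixture_batch_cpp(NumericMatrix G, NumericMatrix F, double tol,
                            int max_iter, int check_interval) {
  const int n = G.nrow(), M = G.ncol(), K = F.nrow();
  if (F.ncol() != M) stop("dimension mismatch between G and F");
  if (check_interval < 1) check_interval = 1;
  const double *Gp = REAL(G), *Fp = REAL(F);

  NumericMatrix Q(n, K);
  NumericVector llv(n);
  IntegerVector iters(n);
  LogicalVector conv(n);
  double *Qp = REAL(Q);
  std::fill(Qp, Qp + (size_t)n * K, 1.0 / K);

  std::vector<double> P((size_t)n * M), W1((size_t)n * M),
      W0((size_t)n * M), A((size_t)n * K), ll_prev(n, R_NegInf);
  std::vector<double> Ft((size_t)M * K), F1t((size_t)M * K);
  // F' and (1-F)' as M x K so both dgemms are plain 'N','N'
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < K; ++k) {
      const double f = Fp[(size_t)j * K + k];
      Ft[(size_t)k * M + j] = f;
      F1t[(size_t)k * M + j] = 1.0 - f;
    }

  const double one = 1.0, zero = 0.0;
  int done = 0;
  int n_left = n;
  while (true) {
    // P = Q F  (n x M)
    F77_CALL(dgemm)("N", "N", &n, &M, &K, &one, Qp, &n, Fp, &K, &zero,
                    P.data(), &n FCONE FCONE);
    const bool check = (done % check_interval == 0) || done >= max_iter;
    if (check) {
      for (int i = 0; i < n; ++i) {
        if (conv[i]) continue;
        double acc = 0.0;
        for (int j = 0; j < M; ++j) {
          const double p = P[(size_t)j * n + i];
          const double g = Gp[(size_t)j * n + i];
          if (g == 0.0)      acc += 2.0 * std::log1p(-p);
          else if (g == 2.0) acc += 2.0 * std::log(p);
          else               acc += std::log(p) + std::log1p(-p);
        }
        if (ll_prev[i] > R_NegInf &&
            acc < ll_prev[i] - 1e-8 * (std::fabs(ll_prev[i]) + 1.0)) {
          stop("EM log-likelihood decreased: numerical failure");
        }
        llv[i] = acc;
        if (ll_prev[i] > R_NegInf && acc - ll_prev[i] < tol) {
          conv[i] = true;
          iters[i] = done;
          --n_left;
        } else {
          ll_prev[i] = acc;
        }
      }
      if (n_left == 0 || done >= max_iter) {
        for (int i = 0; i < n; ++i) if (!conv[i]) iters[i] = done;
        break;
      }
    }
    // W1 = G / P, W0 = (2 - G) / (1 - P); one division per element
    for (size_t t = 0; t < (size_t)n * M; ++t) {
      const double p = P[t], g = Gp[t];
      const double inv = 1.0 / (p * (1.0 - p));
      W1[t] = g * (1.0 - p) * inv;
      W0[t] = (2.0 - g) * p * inv;
    }
    // A = W1 F' + W0 (1-F)'  (n x K)
    F77_CALL(dgemm)("N", "N", &n, &K, &M, &one, W1.data(), &n, Ft.data(),
                    &M, &zero, A.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &n, &K, &M, &one, W0.data(), &n, F1t.data(),
                    &M, &one, A.data(), &n FCONE FCONE);
    // Q <- Q * A / (2M), then renormalise each row onto the simplex
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = Qp[(size_t)k * n + i] * A[(size_t)k * n + i] / (2.0 * M);
        Qp[(size_t)k * n + i] = v;
        s += v;
      }
      for (int k = 0; k < K; ++k) Qp[(size_t)k * n + i] /= s;
    }
    ++done;
  }
  return List::create(_["Q"] = Q, _["loglik"] = llv,
                      _["iterations"] = iters, _["converged"] = conv);
}
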