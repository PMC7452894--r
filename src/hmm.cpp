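#include <Rcpp.h>
using namespace Rcpp;

static inline double gauss(double x, double m, double s) {
  double z = (x - m) / s;
  double v = std::exp(-0.5 * z * z) / (s * 2.5066282746310002);
  return (v > 1e-300) ? v : 1e-300;
}

// Pooled E-step for a Gaussian-emission HMM over a list of traces.
// Returns the log-likelihood and the pooled sufficient statistics
// (expected initial counts, expected transition counts, occupancies and
// first/second moments per state) for the shared-parameter M-step.
// [[Rcpp::export]]
List hmm_estep_cpp(List ys, NumericVector means, NumericVector sds,
                   NumericMatrix A, NumericVector pi) {
  const int K = means.size();
  double loglik = 0.0;
  NumericMatrix trans(K, K);
  NumericVector occ(K), m1(K), m2(K), init(K);

  for (int tr = 0; tr < ys.size(); ++tr) {
    NumericVector y = ys[tr];
    const int T = y.size();
    if (T == 0) continue;
    NumericMatrix B(T, K), alpha(T, K), beta(T, K);
    NumericVector c(T);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = gauss(y[t], means[k], sds[k]);

    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        a *= B(t, k);
        alpha(t, k) = a; s += a;
      }
      c[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        double b = 0.0;
        for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
        beta(t, j) = b / c[t + 1];
      }

    for (int t = 0; t < T; ++t) {
      loglik += std::log(c[t]);
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k);
        if (t == 0) init[k] += g;
        occ[k] += g;
        m1[k] += g * y[t];
        m2[k] += g * y[t] * y[t];
      }
    }
    for (int t = 0; t + 1 < T; ++t)
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          trans(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) *
                         beta(t + 1, k) / c[t + 1];
  }

  return List::create(_["loglik"] = loglik, _["init"] = init,
                      _["trans"] = trans, _["occ"] = occ,
                      _["m1"] = m1, _["m2"] = m2);
}

// Viterbi decoding (most likely state path); ties break toward the lower
// state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector means,
                              NumericVector sds, NumericMatrix A,
                              NumericVector pi) {
  const int K = means.size();
  const int T = y.size();
  IntegerVector path(T);
  if (T == 0) return path;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(pi[k] > 0 ? pi[k] : 1e-300) +
                  std::log(gauss(y[0], means[k], sds[k]));
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) +
                   std::log(A(j, k) > 0 ? A(j, k) : 1e-300);
        if (v > best) { best = v; arg = j; }   // strict: ties keep lower j
      }
      delta(t, k) = best + std::log(gauss(y[t], means[k], sds[k]));
      psi(t, k) = arg;
    }
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi(t + 1, path[t + 1] - 1) + 1;
  return path;
}
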