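#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward over independently chained segments.
// logdens: T x K per-sample state log-densities.
// boundaries: 0-based segment start offsets plus final T (length n_seg + 1);
// the chain restarts (from `initial`) at every segment start.
// [[Rcpp::export]]
List forward_backward_cpp(const NumericMatrix& logdens,
                          const NumericMatrix& transition,
                          const NumericVector& initial,
                          const IntegerVector& boundaries) {
  const int T = logdens.nrow(), K = logdens.ncol();
  const int nseg = boundaries.size() - 1;
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector start_gamma(K);
  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> beta(static_cast<size_t>(T) * K);
  std::vector<double> b(static_cast<size_t>(T) * K);
  std::vector<double> cscale(T), mshift(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    mshift[t] = m;
    for (int k = 0; k < K; ++k)
      b[static_cast<size_t>(t) * K + k] = std::exp(logdens(t, k) - m);
  }

  for (int s = 0; s < nseg; ++s) {
    const int t0 = boundaries[s], t1 = boundaries[s + 1];
    // forward
    for (int t = t0; t < t1; ++t) {
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        double a;
        if (t == t0) {
          a = initial[k];
        } else {
          a = 0.0;
          for (int i = 0; i < K; ++i)
            a += alpha[static_cast<size_t>(t - 1) * K + i] * transition(i, k);
        }
        a *= b[static_cast<size_t>(t) * K + k];
        alpha[static_cast<size_t>(t) * K + k] = a;
        c += a;
      }
      if (c <= 0.0) stop("numerical underflow in forward recursion");
      cscale[t] = c;
      for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(t) * K + k] /= c;
      loglik += std::log(c) + mshift[t];
    }
    // backward
    for (int k = 0; k < K; ++k) beta[static_cast<size_t>(t1 - 1) * K + k] = 1.0;
    for (int t = t1 - 2; t >= t0; --t) {
      for (int i = 0; i < K; ++i) {
        double v = 0.0;
        for (int j = 0; j < K; ++j)
          v += transition(i, j) * b[static_cast<size_t>(t + 1) * K + j] *
               beta[static_cast<size_t>(t + 1) * K + j];
        beta[static_cast<size_t>(t) * K + i] = v / cscale[t + 1];
      }
    }
    // gamma and xi
    for (int t = t0; t < t1; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = alpha[static_cast<size_t>(t) * K + k] *
                   beta[static_cast<size_t>(t) * K + k];
        gamma(t, k) = v;
        g += v;
      }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }
    for (int k = 0; k < K; ++k) start_gamma[k] += gamma(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int i = 0; i < K; ++i) {
        const double ai = alpha[static_cast<size_t>(t - 1) * K + i];
        for (int j = 0; j < K; ++j) {
          xi(i, j) += ai * transition(i, j) *
                      b[static_cast<size_t>(t) * K + j] *
                      beta[static_cast<size_t>(t) * K + j] / cscale[t];
        }
      }
    }
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["start_gamma"] = start_gamma,
                      _["loglik"] = loglik);
}

// Log-domain Viterbi decoding over independently chained segments.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(const NumericMatrix& logdens,
                          const NumericMatrix& log_transition,
                          const NumericVector& log_initial,
                          const IntegerVector& boundaries) {
  const int T = logdens.nrow(), K = logdens.ncol();
  const int nseg = boundaries.size() - 1;
  IntegerVector path(T);
  std::vector<double> delta(static_cast<size_t>(T) * K);
  std::vector<int> psi(static_cast<size_t>(T) * K);

  for (int s = 0; s < nseg; ++s) {
    const int t0 = boundaries[s], t1 = boundaries[s + 1];
    for (int k = 0; k < K; ++k)
      delta[static_cast<size_t>(t0) * K + k] = log_initial[k] + logdens(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int j = 0; j < K; ++j) {
        double best = delta[static_cast<size_t>(t - 1) * K] +
                      log_transition(0, j);
        int arg = 0;
        for (int i = 1; i < K; ++i) {
          const double v = delta[static_cast<size_t>(t - 1) * K + i] +
                           log_transition(i, j);
          if (v > best) { best = v; arg = i; }
        }
        delta[static_cast<size_t>(t) * K + j] = best + logdens(t, j);
        psi[static_cast<size_t>(t) * K + j] = arg;
      }
    }
    int arg = 0;
    double best = delta[static_cast<size_t>(t1 - 1) * K];
    for (int k = 1; k < K; ++k) {
      const double v = delta[static_cast<size_t>(t1 - 1) * K + k];
      if (v > best) { best = v; arg = k; }
    }
    path[t1 - 1] = arg + 1;
    for (int t = t1 - 2; t >= t0; --t) {
      arg = psi[static_cast<size_t>(t + 1) * K + arg];
      path[t] = arg + 1;
    }
  }
  return path;
}
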