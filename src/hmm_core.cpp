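// Log-space forward-backward and Viterbi recursions for a homogeneous
// HMM given precomputed per-observation emission log-densities.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// logB: T x k emission log-densities, logpi: length k, logA: k x k.
// Returns the sequence log-likelihood, posterior state probabilities
// (gamma, T x k) and summed transition posteriors (xi, k x k).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), k = logB.ncol();
  NumericMatrix la(T, k), lb(T, k);
  std::vector<double> tmp(k);

  for (int j = 0; j < k; ++j) la(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < k; ++j) {
      double m = -INFINITY;
      for (int i = 0; i < k; ++i) {
        tmp[i] = la(t - 1, i) + logA(i, j);
        if (tmp[i] > m) m = tmp[i];
      }
      if (m == -INFINITY) { la(t, j) = -INFINITY; continue; }
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += std::exp(tmp[i] - m);
      la(t, j) = m + std::log(s) + logB(t, j);
    }
  }
  double ll;
  {
    double m = -INFINITY;
    for (int j = 0; j < k; ++j) if (la(T - 1, j) > m) m = la(T - 1, j);
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(la(T - 1, j) - m);
    ll = m + std::log(s);
  }

  for (int j = 0; j < k; ++j) lb(T - 1, j) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < k; ++i) {
      double m = -INFINITY;
      for (int j = 0; j < k; ++j) {
        tmp[j] = logA(i, j) + logB(t + 1, j) + lb(t + 1, j);
        if (tmp[j] > m) m = tmp[j];
      }
      if (m == -INFINITY) { lb(t, i) = -INFINITY; continue; }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(tmp[j] - m);
      lb(t, i) = m + std::log(s);
    }
  }

  NumericMatrix gamma(T, k);
  for (int t = 0; t < T; ++t) {
    double m = -INFINITY;
    for (int j = 0; j < k; ++j) {
      double v = la(t, j) + lb(t, j);
      if (v > m) m = v;
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) {
      double v = la(t, j) + lb(t, j);
      gamma(t, j) = (v == -INFINITY) ? 0.0 : std::exp(v - m);
      s += gamma(t, j);
    }
    for (int j = 0; j < k; ++j) gamma(t, j) /= s;
  }

  NumericMatrix xi(k, k);
  std::vector<double> lx(k * k);
  for (int t = 0; t + 1 < T; ++t) {
    double m = -INFINITY;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) {
        double v = la(t, i) + logA(i, j) + logB(t + 1, j) + lb(t + 1, j);
        lx[i * k + j] = v;
        if (v > m) m = v;
      }
    double s = 0.0;
    for (int q = 0; q < k * k; ++q)
      s += (lx[q] == -INFINITY) ? 0.0 : std::exp(lx[q] - m);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (lx[i * k + j] != -INFINITY)
          xi(i, j) += std::exp(lx[i * k + j] - m) / s;
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Maximum-probability state path; ties broken toward the lower state
// index. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), k = logB.ncol();
  NumericMatrix delta(T, k);
  IntegerMatrix psi(T, k);

  for (int j = 0; j < k; ++j) delta(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < k; ++j) {
      double best = -INFINITY;
      int arg = 0;
      for (int i = 0; i < k; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }

  IntegerVector path(T);
  double best = -INFINITY;
  int arg = 0;
  for (int j = 0; j < k; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
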