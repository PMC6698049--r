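#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
// B: T x K matrix of per-window emission likelihoods P(x_t | state k),
// pi: length-K initial distribution, A: K x K row-stochastic transitions.
// Returns posterior marginals gamma (T x K), accumulated transition
// expectations xi_sum (K x K), and the sequence log-likelihood.
// [[Rcpp::export]]
List fb_scaled(NumericMatrix B, NumericVector pi, NumericMatrix A) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("zero forward probability at window 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    if (s <= 0.0) stop("zero forward probability at window %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward (scaled by the forward constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  // posteriors and transition expectations
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["loglik"] = ll);
}

// Viterbi decoding in log space; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericMatrix logB, NumericVector logpi, NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
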