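#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a fixed-parameter HMM.
// emit: T x K matrix of emission densities (linear scale, may be unnormalized),
// Pi: K x K transition matrix, pi0: initial distribution.
// Returns per-frame posteriors gamma (T x K), summed transition posteriors
// xi (K x K) and the log-likelihood.
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix emit, NumericMatrix Pi,
                          NumericVector pi0) {
  const int T = emit.nrow(), K = emit.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);
  double loglik = 0.0;

  // forward with scaling
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi0[k] * emit(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("zero forward probability at frame 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  loglik += std::log(s);

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * Pi(j, k);
      a *= emit(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero forward probability (numerical underflow)");
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    loglik += std::log(s);
  }

  // backward, same scaling constants
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += Pi(j, k) * emit(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      double aj = alpha(t, j);
      if (aj == 0.0) continue;
      for (int k = 0; k < K; ++k) {
        xi(j, k) += aj * Pi(j, k) * emit(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Viterbi decoding (log space). Returns 1-based state path.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix logemit, NumericMatrix logPi,
                          NumericVector logpi0) {
  const int T = logemit.nrow(), K = logemit.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi0[k] + logemit(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logPi(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logemit(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Standard forward-filter backward-sample: n independent path draws from the
// exact posterior p(s | y, Pi, pi0). Returns n x T matrix of 1-based states.
// [[Rcpp::export]]
IntegerMatrix cpp_ffbs(NumericMatrix emit, NumericMatrix Pi,
                       NumericVector pi0, int n) {
  const int T = emit.nrow(), K = emit.ncol();
  NumericMatrix alpha(T, K);
  double s;

  s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * emit(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("zero forward probability at frame 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * Pi(j, k);
      a *= emit(t, k);
      alpha(t, k) = a; s += a;
    }
    if (s <= 0.0) stop("zero forward probability (numerical underflow)");
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  IntegerMatrix out(n, T);
  NumericVector w(K);
  for (int d = 0; d < n; ++d) {
    // sample s_T
    double u = unif_rand(), acc = 0.0;
    int st = K - 1;
    for (int k = 0; k < K; ++k) { acc += alpha(T - 1, k); if (u <= acc) { st = k; break; } }
    out(d, T - 1) = st + 1;
    for (int t = T - 2; t >= 0; --t) {
      double tot = 0.0;
      for (int j = 0; j < K; ++j) { w[j] = alpha(t, j) * Pi(j, st); tot += w[j]; }
      u = unif_rand() * tot; acc = 0.0;
      st = K - 1;
      for (int j = 0; j < K; ++j) { acc += w[j]; if (u <= acc) { st = j; break; } }
      out(d, t) = st + 1;
    }
  }
  return out;
}

// Beam-sampler conditional path draw: transitions enter only through the
// slice indicators I(Pi[j,k] > u_t); emission weights are carried by emit.
// s0 is the (1-based) state conditioned on before frame 1. Returns one path.
// [[Rcpp::export]]
IntegerVector cpp_ffbs_beam(NumericMatrix emit, NumericMatrix Pi,
                            NumericVector u, int s0) {
  const int T = emit.nrow(), K = emit.ncol();
  NumericMatrix alpha(T, K);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = (Pi(s0 - 1, k) > u[0]) ? emit(0, k) : 0.0;
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("beam: empty support at frame 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j)
        if (Pi(j, k) > u[t]) a += alpha(t - 1, j);
      a *= emit(t, k);
      alpha(t, k) = a; s += a;
    }
    if (s <= 0.0) stop("beam: empty support (numerical underflow)");
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  IntegerVector path(T);
  NumericVector w(K);
  double un = unif_rand(), acc = 0.0;
  int st = K - 1;
  for (int k = 0; k < K; ++k) { acc += alpha(T - 1, k); if (un <= acc) { st = k; break; } }
  path[T - 1] = st + 1;
  for (int t = T - 2; t >= 0; --t) {
    double tot = 0.0;
    for (int j = 0; j < K; ++j) {
      w[j] = (Pi(j, st) > u[t + 1]) ? alpha(t, j) : 0.0;
      tot += w[j];
    }
    un = unif_rand() * tot; acc = 0.0;
    st = K - 1;
    for (int j = 0; j < K; ++j) { acc += w[j]; if (un <= acc) { st = j; break; } }
    path[t] = st + 1;
  }
  return path;
}

// Transition count matrix from a 1-based path over K states, with s0 as the
// state before frame 1.
// [[Rcpp::export]]
IntegerMatrix cpp_transition_counts(IntegerVector path, int K, int s0) {
  IntegerMatrix N(K, K);
  int prev = s0 - 1;
  for (int t = 0; t < path.size(); ++t) {
    int cur = path[t] - 1;
    N(prev, cur) += 1;
    prev = cur;
  }
  return N;
}
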