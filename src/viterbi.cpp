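#include <Rcpp.h>
using namespace Rcpp;

// Maximum a-posteriori state path for a discrete-emission HMM, in log space.
// obs: 1-based observed symbol indices; ties broken toward the lowest state
// index (strict inequality when updating the running maximum).
// [[Rcpp::export(name = ".viterbi_path")]]
IntegerVector viterbi_path(IntegerVector obs, NumericVector log_prior,
                           NumericMatrix log_trans, NumericMatrix log_emis) {
  const int T = obs.size();
  const int S = log_prior.size();
  if (T == 0) return IntegerVector(0);

  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);

  for (int s = 0; s < S; ++s) {
    delta(s, 0) = log_prior[s] + log_emis(s, obs[0] - 1);
    psi(s, 0) = 0;
  }
  for (int t = 1; t < T; ++t) {
    const int o = obs[t] - 1;
    for (int s = 0; s < S; ++s) {
      double best = delta(0, t - 1) + log_trans(0, s);
      int arg = 0;
      for (int r = 1; r < S; ++r) {
        const double v = delta(r, t - 1) + log_trans(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta(s, t) = best + log_emis(s, o);
      psi(s, t) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(0, T - 1);
  int arg = 0;
  for (int s = 1; s < S; ++s) {
    if (delta(s, T - 1) > best) { best = delta(s, T - 1); arg = s; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(arg, t);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Variant taking a T x S matrix of per-step emission log-likelihoods
// (e.g. log forest class-probabilities) instead of a discrete emission.
// [[Rcpp::export(name = ".viterbi_path_ll")]]
IntegerVector viterbi_path_ll(NumericMatrix loglik, NumericVector log_prior,
                              NumericMatrix log_trans) {
  const int T = loglik.nrow();
  const int S = log_prior.size();
  if (T == 0) return IntegerVector(0);

  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);
  for (int s = 0; s < S; ++s) delta(s, 0) = log_prior[s] + loglik(0, s);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = delta(0, t - 1) + log_trans(0, s);
      int arg = 0;
      for (int r = 1; r < S; ++r) {
        const double v = delta(r, t - 1) + log_trans(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta(s, t) = best + loglik(t, s);
      psi(s, t) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(0, T - 1);
  int arg = 0;
  for (int s = 1; s < S; ++s) {
    if (delta(s, T - 1) > best) { best = delta(s, T - 1); arg = s; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(arg, t);
    path[t - 1] = arg + 1;
  }
  return path;
}
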