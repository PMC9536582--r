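#include <Rcpp.h>
using namespace Rcpp;

// Latent Rescorla-Wagner skill trajectory at the probe grain.
// rate_idx is 1-based into alphas; t0_ii is the 1-based index of the first
// probe of session 2 (0 = no session break). The session offset is added
// before the prediction-error correction of that probe, and the latent state
// is clipped to [0,1] after every update (slider scale).
static void check_rate_idx(const IntegerVector& rate_idx, int n, int k) {
  if (rate_idx.size() != n) stop("rate_idx length mismatch");
  for (int t = 0; t < n; ++t) {
    if (rate_idx[t] < 1 || rate_idx[t] > k) stop("rate_idx out of range");
  }
}

// [[Rcpp::export]]
NumericVector skill_trajectory_cpp(IntegerVector outcome, IntegerVector rate_idx,
                                   NumericVector alphas, double s0,
                                   double offset, int t0_ii) {
  int n = outcome.size();
  check_rate_idx(rate_idx, n, alphas.size());
  NumericVector s(n);
  double prev = s0;
  for (int t = 0; t < n; ++t) {
    double delta = outcome[t] - prev;
    double st = prev + alphas[rate_idx[t] - 1] * delta;
    if (t + 1 == t0_ii) st += offset;
    if (st < 0.0) st = 0.0; else if (st > 1.0) st = 1.0;
    s[t] = st;
    prev = st;
  }
  return s;
}

// Gaussian report likelihood of the trajectory above. `observed` marks probes
// with a skill report; unobserved probes advance the recursion but add no
// likelihood term.
// [[Rcpp::export]]
double skill_loglik_cpp(NumericVector report, LogicalVector observed,
                        IntegerVector outcome, IntegerVector rate_idx,
                        NumericVector alphas, double s0, double offset,
                        int t0_ii, double sdev) {
  int n = outcome.size();
  check_rate_idx(rate_idx, n, alphas.size());
  double prev = s0, ll = 0.0;
  const double log_norm = -0.5 * std::log(2.0 * M_PI) - std::log(sdev);
  for (int t = 0; t < n; ++t) {
    double delta = outcome[t] - prev;
    double st = prev + alphas[rate_idx[t] - 1] * delta;
    if (t + 1 == t0_ii) st += offset;
    if (st < 0.0) st = 0.0; else if (st > 1.0) st = 1.0;
    if (observed[t]) {
      double z = (report[t] - st) / sdev;
      ll += log_norm - 0.5 * z * z;
    }
    prev = st;
  }
  return ll;
}

// Multinomial softmax attribution likelihood. choice: 1..4 over
// (Internal, Maze, Rotations, Luck); NA or 0 = missing probe (skipped).
// X: n x k feature matrix, first column the bias constant 1. Wwin/Wloss:
// 3 x k weight matrices for Internal/Maze/Rotations; the Luck score is the
// negative sum of the other three (sum-to-zero constraint).
// [[Rcpp::export]]
double attr_loglik_cpp(IntegerVector choice, IntegerVector outcome,
                       NumericMatrix X, NumericMatrix Wwin,
                       NumericMatrix Wloss) {
  int n = choice.size(), k = X.ncol();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = choice[t];
    if (c == NA_INTEGER || c < 1) continue;
    NumericMatrix W = (outcome[t] == 1) ? Wwin : Wloss;
    double sc[4];
    double tot = 0.0;
    for (int o = 0; o < 3; ++o) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += W(o, j) * X(t, j);
      sc[o] = acc;
      tot += acc;
    }
    sc[3] = -tot;
    double m = sc[0];
    for (int o = 1; o < 4; ++o) if (sc[o] > m) m = sc[o];
    double z = 0.0;
    for (int o = 0; o < 4; ++o) z += std::exp(sc[o] - m);
    ll += (sc[c - 1] - m) - std::log(z);
  }
  return ll;
}
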