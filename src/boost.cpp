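#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct StumpFit {
  double threshold;
  double left;
  double right;
  double gain;   // sum-of-squares reduction relative to a zero prediction
  int n_left;    // observations on the left leaf (0 => degenerate)
};

// Best single split of residuals r along one presorted feature column.
// xs holds the column's values in ascending order, ord the matching row
// indices.  Candidate thresholds are midpoints of consecutive distinct
// sorted values; leaf values are the mean residual on each side; ties in
// SSE go to the smallest threshold (first encountered in the ascending
// scan).  A column with no distinct pair of values yields the degenerate
// stump (threshold -Inf, both leaves mean(r)).
StumpFit stump_on_sorted(const std::vector<double>& xs,
                         const std::vector<int>& ord,
                         const std::vector<double>& r) {
  const int n = static_cast<int>(ord.size());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += r[i];

  double best_gain = -1.0;
  int best_k = -1;
  double best_sl = 0.0;
  double run = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    run += r[ord[k]];
    if (xs[k] < xs[k + 1]) {
      const int nl = k + 1, nr = n - nl;
      const double sr = total - run;
      const double gain = run * run / nl + sr * sr / nr;
      if (gain > best_gain) {  // strict: ties keep the smaller threshold
        best_gain = gain;
        best_k = k;
        best_sl = run;
      }
    }
  }

  StumpFit out;
  if (best_k < 0) {  // constant feature
    const double m = total / n;
    out.threshold = -std::numeric_limits<double>::infinity();
    out.left = m;
    out.right = m;
    out.gain = n * m * m;
    out.n_left = 0;
    return out;
  }
  const int nl = best_k + 1, nr = n - nl;
  out.threshold = 0.5 * (xs[best_k] + xs[best_k + 1]);
  out.left = best_sl / nl;
  out.right = (total - best_sl) / nr;
  out.gain = best_gain;
  out.n_left = nl;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List fit_stump_cpp(NumericVector x, NumericVector r) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* xp = REAL(x);
  std::stable_sort(ord.begin(), ord.end(),
                   [xp](int a, int b) { return xp[a] < xp[b]; });
  std::vector<double> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = xp[ord[i]];
  std::vector<double> rv(r.begin(), r.end());
  StumpFit s = stump_on_sorted(xs, ord, rv);
  double total_sq = 0.0;
  for (int i = 0; i < n; ++i) total_sq += rv[i] * rv[i];
  double sse = total_sq - s.gain;
  if (sse < 0.0) sse = 0.0;
  return List::create(_["threshold"] = s.threshold, _["left"] = s.left,
                      _["right"] = s.right, _["sse"] = sse);
}

// Gradient boosting of decision stumps for a Gaussian-deviance additive
// model.  policy 0: cyclic — every feature receives one stump per round, in
// column order; policy 1: best — one stump per round, on the feature whose
// stump attains the lowest SSE (ties to the lowest column index).  Stored
// leaf values are already scaled by the learning rate.
// [[Rcpp::export]]
List boost_fit_cpp(NumericMatrix X, NumericVector y, double eta,
                   int n_rounds, int policy) {
  const int n = X.nrow(), p = X.ncol();

  // presort each column once; keep sorted values contiguous
  std::vector<std::vector<int>> ord(p);
  std::vector<std::vector<double>> xs(p);
  for (int j = 0; j < p; ++j) {
    ord[j].resize(n);
    for (int i = 0; i < n; ++i) ord[j][i] = i;
    const double* xp = &X(0, j);
    std::stable_sort(ord[j].begin(), ord[j].end(),
                     [xp](int a, int b) { return xp[a] < xp[b]; });
    xs[j].resize(n);
    for (int i = 0; i < n; ++i) xs[j][i] = xp[ord[j][i]];
  }

  double intercept = 0.0;
  for (int i = 0; i < n; ++i) intercept += y[i];
  intercept /= n;

  std::vector<double> r(n);
  double null_dev = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = y[i] - intercept;
    null_dev += r[i] * r[i];
  }

  const int max_stumps = n_rounds * (policy == 0 ? p : 1);
  NumericMatrix stumps(max_stumps, 4);  // feature (1-based), threshold, left, right
  int n_stumps = 0;
  NumericVector dev_trace(n_rounds);

  // apply one eta-scaled stump on feature j and record it
  auto apply_stump = [&](int j, const StumpFit& s) {
    const double dl = eta * s.left, dr = eta * s.right;
    const double t = s.threshold;
    const double* xp = &X(0, j);
    for (int i = 0; i < n; ++i) r[i] -= (xp[i] <= t) ? dl : dr;
    stumps(n_stumps, 0) = j + 1;
    stumps(n_stumps, 1) = t;
    stumps(n_stumps, 2) = dl;
    stumps(n_stumps, 3) = dr;
    ++n_stumps;
  };

  for (int round = 0; round < n_rounds; ++round) {
    if (policy == 0) {
      for (int j = 0; j < p; ++j)
        apply_stump(j, stump_on_sorted(xs[j], ord[j], r));
    } else {
      // within one round every feature sees the same residuals, so the
      // lowest SSE is the highest gain
      StumpFit best = stump_on_sorted(xs[0], ord[0], r);
      int best_j = 0;
      for (int j = 1; j < p; ++j) {
        StumpFit s = stump_on_sorted(xs[j], ord[j], r);
        if (s.gain > best.gain) {
          best = s;
          best_j = j;
        }
      }
      apply_stump(best_j, best);
    }
    double dev = 0.0;
    for (int i = 0; i < n; ++i) dev += r[i] * r[i];
    dev_trace[round] = dev;
  }

  NumericMatrix kept(n_stumps, 4);
  for (int s = 0; s < n_stumps; ++s)
    for (int c = 0; c < 4; ++c) kept(s, c) = stumps(s, c);

  NumericVector resid(n);
  for (int i = 0; i < n; ++i) resid[i] = r[i];

  return List::create(_["intercept"] = intercept, _["stumps"] = kept,
                      _["deviance_trace"] = dev_trace,
                      _["null_deviance"] = null_dev,
                      _["residuals"] = resid);
}
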