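#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Viterbi decoding of Gaussian-emission HMM paths, one subject per row.
// States are labelled 0..S-1; log_trans(j, k) is log P(j -> k).
// Returns the most probable state path per subject.
// [[Rcpp::export]]
IntegerMatrix viterbi_paths_cpp(NumericMatrix obs, NumericVector means,
                                NumericVector sds, NumericVector log_init,
                                NumericMatrix log_trans) {
  const int n = obs.nrow(), L = obs.ncol(), S = means.size();
  if (L < 1) stop("empty observation vector");
  if (sds.size() != S || log_init.size() != S ||
      log_trans.nrow() != S || log_trans.ncol() != S)
    stop("inconsistent HMM parameter dimensions");

  IntegerMatrix paths(n, L);
  std::vector<double> c1(S), inv2v(S);
  for (int s = 0; s < S; ++s) {
    if (sds[s] <= 0) stop("emission sds must be positive");
    c1[s] = -std::log(sds[s]) - 0.5 * std::log(2.0 * M_PI);
    inv2v[s] = 0.5 / (sds[s] * sds[s]);
  }

  std::vector<double> v(S), vnew(S);
  std::vector<int> bp((size_t)L * S);

  for (int i = 0; i < n; ++i) {
    double x = obs(i, 0);
    if (!std::isfinite(x)) stop("non-finite LRR value");
    for (int s = 0; s < S; ++s) {
      double d = x - means[s];
      v[s] = log_init[s] + c1[s] - inv2v[s] * d * d;
    }
    for (int t = 1; t < L; ++t) {
      x = obs(i, t);
      if (!std::isfinite(x)) stop("non-finite LRR value");
      for (int k = 0; k < S; ++k) {
        int best_j = 0;
        double best = v[0] + log_trans(0, k);
        for (int j = 1; j < S; ++j) {
          double cand = v[j] + log_trans(j, k);
          if (cand > best) { best = cand; best_j = j; }
        }
        bp[(size_t)t * S + k] = best_j;
        double d = x - means[k];
        vnew[k] = best + c1[k] - inv2v[k] * d * d;
      }
      v = vnew;
    }
    int s_star = 0;
    for (int s = 1; s < S; ++s) if (v[s] > v[s_star]) s_star = s;
    paths(i, L - 1) = s_star;
    for (int t = L - 1; t > 0; --t) {
      s_star = bp[(size_t)t * S + s_star];
      paths(i, t - 1) = s_star;
    }
  }
  return paths;
}
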