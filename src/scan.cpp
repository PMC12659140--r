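#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli scan log-likelihood ratio for one cut; zero unless enriched.
static inline double llr1(double c, double n, double p) {
  if (n <= 0.0 || c <= n * p) return 0.0;
  double t = c * std::log(c / (p * n));
  if (n - c > 0.0) t += (n - c) * std::log((n - c) / ((1.0 - p) * n));
  return t;
}

// Monte-Carlo null distribution of the maximum LLR. Units (children, or
// child-code memberships) are stored CSR-style: unit i covers cuts
// cut_idx[row_ptr[i] .. row_ptr[i+1]-1] (0-based). Each replicate relabels
// every unit exposed with probability p -- all of a unit's cut memberships
// move together -- recomputes every cut's LLR against the fixed totals
// n_cut, and records the maximum. Uses R's RNG, so set.seed() upstream
// makes the result reproducible.
// [[Rcpp::export]]
NumericVector cpp_scan_null(IntegerVector row_ptr, IntegerVector cut_idx,
                            NumericVector n_cut, double p, int R) {
  const int n_units = row_ptr.size() - 1;
  const int n_cuts = n_cut.size();
  std::vector<double> c(n_cuts);
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    std::fill(c.begin(), c.end(), 0.0);
    for (int i = 0; i < n_units; ++i) {
      if (unif_rand() < p) {
        for (int j = row_ptr[i]; j < row_ptr[i + 1]; ++j)
          c[cut_idx[j]] += 1.0;
      }
    }
    double m = 0.0;
    for (int k = 0; k < n_cuts; ++k) {
      double v = llr1(c[k], n_cut[k], p);
      if (v > m) m = v;
    }
    out[r] = m;
  }
  return out;
}
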