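#include <Rcpp.h>
using namespace Rcpp;

// One-sided Poisson scan log-likelihood ratio for a candidate window with
// observed oz, expected ez, against totals ot, et. direction: +1 high-rate,
// -1 low-rate. Zero-count terms contribute 0 (x log x -> 0).
static inline double zone_llr(double oz, double ez, double ot, double et,
                              int direction) {
  double oout = ot - oz, eout = et - ez;
  if (ez <= 0.0 || eout <= 0.0) return 0.0;
  double inside = oz / ez, outside = oout / eout;
  if (direction > 0 ? (inside <= outside) : (inside >= outside)) return 0.0;
  double llr = 0.0;
  if (oz > 0.0) llr += oz * std::log(oz / ez);
  if (oout > 0.0) llr += oout * std::log(oout / eout);
  return llr;
}

// Maximum LLR over all circular zones, for each simulated count vector.
// ord: n x ncenter matrix; column c is the ordering of units by distance
// from center c (1-based indices into the count vector). zlen[c] gives the
// number of admissible nested zones for center c (window size cap already
// applied). ecum: cumulative expected counts along each ordering.
// [[Rcpp::export]]
NumericVector scan_max_llr_cpp(IntegerMatrix simO, IntegerMatrix ord,
                               IntegerVector zlen, NumericMatrix ecum,
                               double etot, int direction) {
  int n = simO.nrow(), nsim = simO.ncol(), ncenter = ord.ncol();
  NumericVector out(nsim);
  for (int s = 0; s < nsim; ++s) {
    double ot = 0.0;
    for (int i = 0; i < n; ++i) ot += simO(i, s);
    double best = 0.0;
    for (int c = 0; c < ncenter; ++c) {
      double acc = 0.0;
      int L = zlen[c];
      for (int r = 0; r < L; ++r) {
        acc += simO(ord(r, c) - 1, s);
        double llr = zone_llr(acc, ecum(r, c), ot, etot, direction);
        if (llr > best) best = llr;
      }
    }
    out[s] = best;
  }
  return out;
}
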