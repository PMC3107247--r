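#include <Rcpp.h>
using namespace Rcpp;

// Trough detection with a topographic-prominence criterion.
//
// A candidate event is a maximal run of equal values strictly below both
// neighbouring samples (runs touching either end of the series are not
// candidates); the event index is the run midpoint, rounded down. The
// prominence of a candidate with value v is min(left barrier, right barrier)
// - v, where each barrier is the largest value encountered walking away from
// the run before meeting a sample strictly deeper than v (samples at or past
// the deeper one excluded); if no deeper sample exists on a side, the barrier
// is the maximum over that whole side. A candidate is kept iff its prominence
// is at least threshold_ratio * (global max - global min) of the series.
//
// Returns 1-based sample indices, strictly increasing.
// [[Rcpp::export]]
IntegerVector cpp_find_troughs(NumericVector x, double threshold_ratio) {
  const int n = x.size();
  std::vector<int> out;
  if (n < 3) return IntegerVector(0);

  double lo = x[0], hi = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  const double range = hi - lo;
  if (range <= 0.0) return IntegerVector(0);
  const double min_prom = threshold_ratio * range;

  int i = 1;
  while (i < n - 1) {
    if (x[i] < x[i - 1]) {
      int j = i;
      while (j + 1 < n && x[j + 1] == x[i]) ++j;
      if (j < n - 1 && x[j + 1] > x[i]) {
        const double v = x[i];
        double barL = x[i - 1];
        for (int l = i - 1; l >= 0; --l) {
          if (x[l] < v) break;
          if (x[l] > barL) barL = x[l];
        }
        double barR = x[j + 1];
        for (int r = j + 1; r < n; ++r) {
          if (x[r] < v) break;
          if (x[r] > barR) barR = x[r];
        }
        const double prom = (barL < barR ? barL : barR) - v;
        if (prom >= min_prom) out.push_back((i + j) / 2 + 1);
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
  return wrap(out);
}
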