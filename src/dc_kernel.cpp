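#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Fluctuation measure of one window: sum over maximal monotone segments of
// |value change| / |occasion change|, normalized by s * (m - 1). Plateaus
// (runs of equal consecutive values) are absorbed into the surrounding
// segment; when the direction reverses across a plateau the turning point
// is the last index of the plateau.
// A segment is a maximal run of same-direction nonzero steps; plateaus
// interior to a run are absorbed (they dilute the slope), while plateaus
// across which the direction reverses (and leading/trailing plateaus)
// belong to no segment. This keeps F invariant under time reversal.
static double fluct_one(const double *x, int m, double s) {
  int prev_sign = 0;
  int seg_start = -1, seg_end = -1; // 0-based window indices
  double acc = 0.0;
  for (int i = 0; i + 1 < m; ++i) {
    double d = x[i + 1] - x[i];
    if (d == 0.0) continue;
    int sg = d > 0 ? 1 : -1;
    if (sg != prev_sign) {
      if (prev_sign != 0) {
        acc += std::abs(x[seg_end] - x[seg_start]) /
          (double)(seg_end - seg_start);
      }
      seg_start = i;
      prev_sign = sg;
    }
    seg_end = i + 1;
  }
  if (prev_sign == 0) return 0.0; // constant window
  acc += std::abs(x[seg_end] - x[seg_start]) / (double)(seg_end - seg_start);
  return acc / (s * (m - 1));
}

// Distribution measure of one window: 1 minus the summed shortfall of the
// sorted pairwise gaps below the equidistant full-scale ideal, relative to
// the summed ideal gaps.
static double dist_one(const double *x, int m, double s, double *buf) {
  std::copy(x, x + m, buf);
  std::sort(buf, buf + m);
  double ideal_unit = s / (double)(m - 1);
  double dev_sum = 0.0, ideal_sum = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double ideal = (j - i) * ideal_unit;
      double actual = buf[j] - buf[i];
      double dev = ideal - actual;
      if (dev > 0.0) dev_sum += dev;
      ideal_sum += ideal;
    }
  }
  return 1.0 - dev_sum / ideal_sum;
}

// [[Rcpp::export(name = ".dc_fd_kernel")]]
List dc_fd_kernel(NumericMatrix x, int m, NumericVector norm_min,
                  NumericVector norm_max) {
  int T = x.nrow(), V = x.ncol();
  if (m < 2) stop("window size m must be >= 2");
  if (T < m) stop("series length (%d) is shorter than the window (%d)", T, m);
  NumericMatrix F(T, V), D(T, V);
  std::fill(F.begin(), F.end(), NA_REAL);
  std::fill(D.begin(), D.end(), NA_REAL);
  std::vector<double> win(m), buf(m);
  for (int v = 0; v < V; ++v) {
    double s = norm_max[v] - norm_min[v];
    if (!(s > 0)) stop("scale range must be positive (factor column %d)", v + 1);
    for (int t = m - 1; t < T; ++t) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double val = x(t - m + 1 + k, v);
        if (NumericVector::is_na(val)) { ok = false; break; }
        win[k] = val;
      }
      if (!ok) continue;
      F(t, v) = fluct_one(win.data(), m, s);
      D(t, v) = dist_one(win.data(), m, s, buf.data());
    }
  }
  return List::create(Named("F") = F, Named("D") = D);
}
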