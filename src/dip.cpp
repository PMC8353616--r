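// Hartigan-type dip statistic: the sup-norm distance from the empirical cdf
// to the nearest unimodal cdf (convex below the mode, concave above, with an
// atom permitted only at the mode).  Computed by minimising, over all mode
// placements (each gap between distinct sample values and each value itself),
// the smallest band half-width eps for which a convex function fits under the
// upper band on the left of the mode and a concave function fits over the
// lower band on the right.  Both feasibility problems reduce to hull
// evaluations, so each placement costs O(m) for m distinct values.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// Lower convex hull of points (vx, vy) given in increasing vx (strictly,
// after tie-collapse).  Returns hull vertex indices.
std::vector<int> lower_hull(const std::vector<double>& vx,
                            const std::vector<double>& vy,
                            int from, int to) {
  std::vector<int> h;
  for (int i = from; i <= to; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      // keep turn right (convex): cross((b-a),(i-a)) <= 0 -> pop b
      double cr = (vx[b] - vx[a]) * (vy[i] - vy[a]) -
                  (vy[b] - vy[a]) * (vx[i] - vx[a]);
      if (cr <= 0.0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  return h;
}

std::vector<int> upper_hull(const std::vector<double>& vx,
                            const std::vector<double>& vy,
                            int from, int to) {
  std::vector<int> h;
  for (int i = from; i <= to; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      double cr = (vx[b] - vx[a]) * (vy[i] - vy[a]) -
                  (vy[b] - vy[a]) * (vx[i] - vx[a]);
      if (cr >= 0.0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  return h;
}

// Evaluate piecewise-linear hull at the x of every point in [from, to];
// hull vertices are indices into vx/vy.
void hull_eval(const std::vector<double>& vx, const std::vector<double>& vy,
               const std::vector<int>& h, int from, int to,
               std::vector<double>& out) {
  size_t seg = 0;
  for (int i = from; i <= to; ++i) {
    while (seg + 1 < h.size() && vx[h[seg + 1]] < vx[i]) ++seg;
    int a = h[seg];
    double y;
    if (seg + 1 >= h.size() || vx[i] <= vx[a]) {
      y = vy[a];
    } else {
      int b = h[seg + 1];
      double t = (vx[i] - vx[a]) / (vx[b] - vx[a]);
      y = vy[a] + t * (vy[b] - vy[a]);
    }
    out[i - from] = y;
  }
}

// eps needed for a convex function to satisfy upper constraints
// (vx[t], Cprev[t]) for t in 1..k and lower constraints C[t] - eps for
// t in 1..k_low (k_low = k or k-1 when the mode sits at point k).
double dev_convex(const std::vector<double>& vx, const std::vector<double>& C,
                  const std::vector<double>& Cprev, int k, int k_low) {
  if (k < 1 || k_low < 1) return 0.0;
  std::vector<int> h = lower_hull(vx, Cprev, 1, k);
  std::vector<double> hv(k);
  hull_eval(vx, Cprev, h, 1, k, hv);
  double d = 0.0;
  for (int t = 1; t <= k_low; ++t) d = std::max(d, (C[t] - hv[t - 1]) / 2.0);
  return d;
}

// eps needed for a concave function over points t in k..m with lower
// constraints C[t] - eps and upper constraints Cprev[t] + eps, the first
// point's upper constraint optionally relaxed (mode with an atom there).
double dev_concave(const std::vector<double>& vx, const std::vector<double>& C,
                   const std::vector<double>& Cprev, int k, int m,
                   bool relax_first) {
  if (k > m) return 0.0;
  std::vector<int> h = upper_hull(vx, C, k, m);
  std::vector<double> hv(m - k + 1);
  hull_eval(vx, C, h, k, m, hv);
  double d = 0.0;
  for (int t = k; t <= m; ++t) {
    if (relax_first && t == k) continue;
    d = std::max(d, (hv[t - k] - Cprev[t]) / 2.0);
  }
  return d;
}

double dip_of_sorted(const std::vector<double>& xs) {
  const int n = (int)xs.size();
  if (n < 2) return 0.0;
  // collapse ties -> distinct values with cumulative ecdf steps
  std::vector<double> vx(1, 0.0), C(1, 0.0), Cprev(1, 0.0);  // index 0 unused
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    vx.push_back(xs[i]);
    Cprev.push_back((double)i / n);
    C.push_back((double)j / n);
    i = j;
  }
  const int m = (int)vx.size() - 1;
  if (m == 1) return 0.0;  // point mass is unimodal
  double best = 1.0;
  for (int t = 0; t <= m; ++t) {  // mode in the open gap after value t
    double d = std::max(dev_convex(vx, C, Cprev, t, t),
                        dev_concave(vx, C, Cprev, t + 1, m, false));
    best = std::min(best, d);
  }
  for (int t = 1; t <= m; ++t) {  // mode at value t (atom allowed)
    double d = std::max(dev_convex(vx, C, Cprev, t, t - 1),
                        dev_concave(vx, C, Cprev, t, m, true));
    best = std::min(best, d);
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
double cpp_dip_stat(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_of_sorted(xs);
}

// Null distribution of the dip for samples of size n from a continuous
// uniform distribution (the classical calibration reference).
// [[Rcpp::export]]
NumericVector cpp_dip_null(int n, int B, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericVector out(B);
  std::vector<double> xs(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = unif(rng);
    std::sort(xs.begin(), xs.end());
    out[b] = dip_of_sorted(xs);
  }
  return out;
}
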