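#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact least-squares segmentation of a series into a fixed number of
// segments: layered dynamic program over (point index, segment count)
// with cumulative-sum cost evaluation.  The within-segment SSE interval
// cost does not satisfy the quadrangle inequality on unsorted series,
// so no divide-and-conquer/SMAWK shortcut applies and each layer is a
// dense O(m^2) scan.  The layer kernel is compiled per-function with
// fast-math (all sentinels are finite, so its finite-math assumption
// holds) and cloned for newer vector ISAs with runtime dispatch, which
// keeps the scan vectorized without baking a CPU target into the
// build.

static const double BIG = 1.0e300;

#if defined(__GNUC__) && !defined(__clang__) && defined(__x86_64__)
__attribute__((optimize("O3", "fast-math", "unroll-loops")))
__attribute__((target_clones("default", "avx2", "avx512f")))
#endif
static void dp_layer(int s, int m, const double* c1, const double* c2,
                     const double* pinv, const double* pp, double* cur,
                     int* brow) {
  const int B = 512;
  for (int i = s; i <= m; ++i) {
    const double C1 = c1[i], C2 = c2[i];
    // blocked value pass: branch-free running block minima, with
    // t = i - j walking the reciprocal table forward; only the winning
    // block is rescanned for the argmin index
    const int tmax = i - (s - 1);
    double best = BIG;
    int blo = 1, bhi = tmax;
    for (int tb = 1; tb <= tmax; tb += B) {
      const int te = std::min(tb + B - 1, tmax);
      double bmin = BIG;
      for (int t = tb; t <= te; ++t) {
        const int j = i - t;
        const double d1 = C1 - c1[j];
        const double v = pp[j] + (C2 - c2[j]) - d1 * d1 * pinv[t];
        bmin = v < bmin ? v : bmin;
      }
      // non-strict: on ties the later block (larger t, lower j) wins
      if (bmin <= best) {
        best = bmin;
        blo = tb;
        bhi = te;
      }
    }
    // index pass over one block, largest t (lowest j) first;
    // epsilon-guarded against reassociation between the passes
    const double eps = 1e-9 * std::fabs(best) + 1e-12;
    int bestj = -1;
    for (int t = bhi; t >= blo; --t) {
      const int j = i - t;
      const double d1 = C1 - c1[j];
      const double v = pp[j] + (C2 - c2[j]) - d1 * d1 * pinv[t];
      if (v <= best + eps) {
        bestj = j;
        break;
      }
    }
    cur[i] = best;
    brow[i] = bestj;
  }
}

// [[Rcpp::export(name = ".dp_segment_cpp")]]
List dp_segment_cpp(NumericVector x, int n_seg) {
  const int m = x.size();
  if (m < 1) stop("empty series");
  if (n_seg < 1) stop("n_seg must be >= 1");
  if (n_seg > m) n_seg = m;
  for (int i = 0; i < m; ++i) {
    if (!R_FINITE(x[i])) stop("series contains non-finite values");
  }

  std::vector<double> c1(m + 1, 0.0), c2(m + 1, 0.0), inv(m + 2, 0.0);
  for (int i = 1; i <= m + 1; ++i) inv[i] = 1.0 / i;
  for (int i = 1; i <= m; ++i) {
    c1[i] = c1[i - 1] + x[i - 1];
    c2[i] = c2[i - 1] + x[i - 1] * x[i - 1];
  }

  std::vector<double> prev(m + 1, BIG), cur(m + 1, BIG);
  // backpointers for layers 2..n_seg (layer s at row s-2)
  std::vector<int> back;
  if (n_seg > 1) back.assign((size_t)(n_seg - 1) * (m + 1), -1);
  NumericVector cost_by_s(n_seg);

  for (int i = 1; i <= m; ++i) {
    prev[i] = c2[i] - c1[i] * c1[i] * inv[i];
  }
  cost_by_s[0] = std::max(prev[m], 0.0);

  for (int s = 2; s <= n_seg; ++s) {
    int* brow = back.data() + (size_t)(s - 2) * (m + 1);
    dp_layer(s, m, c1.data(), c2.data(), inv.data(), prev.data(),
             cur.data(), brow);
    cost_by_s[s - 1] = std::max(cur[m], 0.0);
    std::swap(prev, cur);
  }

  // backtrack: ends[s] = right endpoint of segment s (1-based index)
  IntegerVector ends(n_seg);
  int i = m;
  for (int s = n_seg; s >= 2; --s) {
    ends[s - 1] = i;
    i = back[(size_t)(s - 2) * (m + 1) + i];
  }
  ends[0] = i;

  NumericVector means(n_seg);
  int a = 1;
  for (int s = 0; s < n_seg; ++s) {
    const int b = ends[s];
    means[s] = (c1[b] - c1[a - 1]) / (b - a + 1);
    a = b + 1;
  }
  return List::create(_["ends"] = ends, _["means"] = means,
                      _["cost"] = cost_by_s[n_seg - 1],
                      _["cost_by_s"] = cost_by_s);
}
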