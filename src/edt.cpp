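#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared-distance transform (lower envelope of parabolas), after
// Felzenszwalb & Huttenlocher. f: sampled function, d: output, n: length.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform in pixel units. `target` marks the
// zero-distance set; cells with NA propagate NA but still act as obstacles
// only in the sense of carrying no target (they never seed distance 0).
// [[Rcpp::export]]
NumericMatrix edt_cpp(LogicalMatrix target) {
  const int nr = target.nrow(), nc = target.ncol();
  // large finite sentinel: infinity would poison the envelope with Inf-Inf
  const double BIG = 1e30;
  std::vector<double> g(nr * nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      g[i + (size_t)j * nr] =
          (target(i, j) == TRUE) ? 0.0 : BIG;

  // pass 1: along columns (down each column of the grid)
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = g[i + (size_t)j * nr];
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) g[i + (size_t)j * nr] = d[i];
  }
  // pass 2: along rows
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = g[i + (size_t)j * nr];
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}
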