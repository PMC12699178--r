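#include "ubm.h"
using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher separable parabolic lower envelope).
// f: sampled squared-distance function along one axis, spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      if (f[p] == INF) { // first finite parabola
        --k;
        if (k < 0) break;
        continue;
      }
      double xq = w * q, xp = w * p;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // whole line infinite
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = w * q;
    while (z[k + 1] < xq) ++k;
    int p = v[k];
    double dx = xq - w * p;
    d[q] = dx * dx + f[p];
  }
}

// mask: logical, TRUE = foreground. Returns squared physical distance from
// each voxel to the nearest background (FALSE) voxel; 0 on background.
// Domain borders are NOT treated as background (pad in R when needed).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  Dim3 d(dim);
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  for (long long i = 0; i < (long long)mask.size(); ++i)
    out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, g;
  // along z
  f.resize(d.nz); g.resize(d.nz);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = out[d.idx(z, y, x)];
      dt1d(f, g, spacing[0]);
      for (int z = 0; z < d.nz; ++z) out[d.idx(z, y, x)] = g[z];
    }
  // along y
  f.resize(d.ny); g.resize(d.ny);
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = out[d.idx(z, y, x)];
      dt1d(f, g, spacing[1]);
      for (int y = 0; y < d.ny; ++y) out[d.idx(z, y, x)] = g[y];
    }
  // along x
  f.resize(d.nx); g.resize(d.nx);
  for (int y = 0; y < d.ny; ++y)
    for (int z = 0; z < d.nz; ++z) {
      for (int x = 0; x < d.nx; ++x) f[x] = out[d.idx(z, y, x)];
      dt1d(f, g, spacing[2]);
      for (int x = 0; x < d.nx; ++x) out[d.idx(z, y, x)] = g[x];
    }
  return out;
}
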