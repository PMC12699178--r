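#include "ubm.h"
using namespace Rcpp;

// Grayscale min/max filter with an arbitrary structuring element given as a
// m x 3 matrix of integer voxel offsets (dz, dy, dx).  Values outside the
// domain are ignored (SE is clipped at borders), which makes closing/opening
// border-neutral.
// [[Rcpp::export]]
NumericVector cpp_gray_filter(NumericVector values, IntegerVector dim,
                              IntegerMatrix offsets, bool maximum) {
  Dim3 d(dim);
  NumericVector out(values.size());
  int m = offsets.nrow();
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double best = values[d.idx(z, y, x)];
        for (int k = 0; k < m; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
              xx = x + offsets(k, 2);
          if (!d.inside(zz, yy, xx)) continue;
          double v = values[d.idx(zz, yy, xx)];
          if (maximum ? (v > best) : (v < best)) best = v;
        }
        out[d.idx(z, y, x)] = best;
      }
  out.attr("dim") = dim;
  return out;
}

static void gauss1d(std::vector<double>& line, const std::vector<double>& ker) {
  int n = (int)line.size(), r = ((int)ker.size() - 1) / 2;
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, wsum = 0.0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0 || j >= n) continue; // renormalised at borders
      double w = ker[k + r];
      s += w * line[j];
      wsum += w;
    }
    out[i] = s / wsum;
  }
  line.swap(out);
}

// Separable Gaussian blur; sigma given per axis in voxel units
// (pass sigma_phys / spacing from R).  sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector values, IntegerVector dim,
                          NumericVector sigma) {
  Dim3 d(dim);
  NumericVector out = clone(values);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    for (int k = -r; k <= r; ++k) ker[k + r] = std::exp(-0.5 * k * k / (s * s));
    int len = axis == 0 ? d.nz : (axis == 1 ? d.ny : d.nx);
    std::vector<double> line(len);
    if (axis == 0) {
      for (int x = 0; x < d.nx; ++x)
        for (int y = 0; y < d.ny; ++y) {
          for (int z = 0; z < d.nz; ++z) line[z] = out[d.idx(z, y, x)];
          gauss1d(line, ker);
          for (int z = 0; z < d.nz; ++z) out[d.idx(z, y, x)] = line[z];
        }
    } else if (axis == 1) {
      for (int x = 0; x < d.nx; ++x)
        for (int z = 0; z < d.nz; ++z) {
          for (int y = 0; y < d.ny; ++y) line[y] = out[d.idx(z, y, x)];
          gauss1d(line, ker);
          for (int y = 0; y < d.ny; ++y) out[d.idx(z, y, x)] = line[y];
        }
    } else {
      for (int y = 0; y < d.ny; ++y)
        for (int z = 0; z < d.nz; ++z) {
          for (int x = 0; x < d.nx; ++x) line[x] = out[d.idx(z, y, x)];
          gauss1d(line, ker);
          for (int x = 0; x < d.nx; ++x) out[d.idx(z, y, x)] = line[x];
        }
    }
  }
  out.attr("dim") = dim;
  return out;
}
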