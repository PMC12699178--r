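#include "ubm.h"
using namespace Rcpp;

// Connected components of a logical mask, 26-connectivity, labels 1..K in
// raster order of the first voxel encountered (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  Dim3 d(dim);
  std::vector<std::array<int,3> > off;
  neighbours26(off);
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<long long> stack;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long long i = d.idx(z, y, x);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
          long long p = stack.back();
          stack.pop_back();
          int pz = (int)(p % d.nz);
          long long rest = p / d.nz;
          int py = (int)(rest % d.ny), px = (int)(rest / d.ny);
          for (size_t k = 0; k < off.size(); ++k) {
            int zz = pz + off[k][0], yy = py + off[k][1], xx = px + off[k][2];
            if (!d.inside(zz, yy, xx)) continue;
            long long q = d.idx(zz, yy, xx);
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Per-label voxel count, physical centroid, population covariance of voxel
// centre coordinates (z, y, x order) and voxel-index bounding boxes.
// Labels must be positive integers; 0 is background.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, IntegerVector dim,
                     NumericVector spacing, NumericVector origin) {
  Dim3 d(dim);
  int K = 0;
  for (long long i = 0; i < (long long)labels.size(); ++i)
    if (labels[i] > K) K = labels[i];
  NumericVector count(K);
  NumericMatrix sum(K, 3), sq(K, 6); // sq cols: zz, yy, xx, zy, zx, yx
  IntegerMatrix bbox(K, 6);          // zmin, zmax, ymin, ymax, xmin, xmax
  for (int k = 0; k < K; ++k) {
    bbox(k, 0) = bbox(k, 2) = bbox(k, 4) = INT_MAX;
    bbox(k, 1) = bbox(k, 3) = bbox(k, 5) = -1;
  }
  for (int x = 0; x < d.nx; ++x) {
    double px = origin[2] + x * spacing[2];
    for (int y = 0; y < d.ny; ++y) {
      double py = origin[1] + y * spacing[1];
      for (int z = 0; z < d.nz; ++z) {
        int L = labels[d.idx(z, y, x)];
        if (L <= 0) continue;
        double pz = origin[0] + z * spacing[0];
        int k = L - 1;
        count[k] += 1;
        sum(k, 0) += pz; sum(k, 1) += py; sum(k, 2) += px;
        sq(k, 0) += pz * pz; sq(k, 1) += py * py; sq(k, 2) += px * px;
        sq(k, 3) += pz * py; sq(k, 4) += pz * px; sq(k, 5) += py * px;
        if (z < bbox(k, 0)) bbox(k, 0) = z;
        if (z > bbox(k, 1)) bbox(k, 1) = z;
        if (y < bbox(k, 2)) bbox(k, 2) = y;
        if (y > bbox(k, 3)) bbox(k, 3) = y;
        if (x < bbox(k, 4)) bbox(k, 4) = x;
        if (x > bbox(k, 5)) bbox(k, 5) = x;
      }
    }
  }
  NumericMatrix centroid(K, 3), cov(K, 6);
  for (int k = 0; k < K; ++k) {
    double n = count[k];
    if (n < 1) continue;
    for (int j = 0; j < 3; ++j) centroid(k, j) = sum(k, j) / n;
    cov(k, 0) = sq(k, 0) / n - centroid(k, 0) * centroid(k, 0);
    cov(k, 1) = sq(k, 1) / n - centroid(k, 1) * centroid(k, 1);
    cov(k, 2) = sq(k, 2) / n - centroid(k, 2) * centroid(k, 2);
    cov(k, 3) = sq(k, 3) / n - centroid(k, 0) * centroid(k, 1);
    cov(k, 4) = sq(k, 4) / n - centroid(k, 0) * centroid(k, 2);
    cov(k, 5) = sq(k, 5) / n - centroid(k, 1) * centroid(k, 2);
  }
  return List::create(_["count"] = count, _["centroid"] = centroid,
                      _["cov"] = cov, _["bbox"] = bbox);
}

// Voxels whose 6-neighbourhood carries a different positive label
// (inter-cell contact surfaces).
// [[Rcpp::export]]
LogicalVector cpp_touch_boundary(IntegerVector labels, IntegerVector dim) {
  Dim3 d(dim);
  LogicalVector out(labels.size());
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        int L = labels[d.idx(z, y, x)];
        if (L <= 0) continue;
        for (int k = 0; k < 6; ++k) {
          int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
          if (!d.inside(zz, yy, xx)) continue;
          int M = labels[d.idx(zz, yy, xx)];
          if (M > 0 && M != L) { out[d.idx(z, y, x)] = true; break; }
        }
      }
  out.attr("dim") = dim;
  return out;
}
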