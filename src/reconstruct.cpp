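#include "ubm.h"
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask pointwise), 26-connectivity.  Hybrid raster /
// anti-raster algorithm with a FIFO completion queue (Vincent 1993).
// [[Rcpp::export]]
NumericVector cpp_grayrec(NumericVector marker, NumericVector mask,
                          IntegerVector dim) {
  Dim3 d(dim);
  NumericVector J = clone(marker);
  std::vector<std::array<int,3> > all, plus, minus;
  neighbours26(all);
  for (size_t k = 0; k < all.size(); ++k) {
    // raster order: earlier voxel = smaller linear index
    long long lin = (long long)all[k][0] +
      (long long)d.nz * ((long long)all[k][1] + (long long)d.ny * all[k][2]);
    if (lin < 0) minus.push_back(all[k]); else plus.push_back(all[k]);
  }
  // forward sweep
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long long i = d.idx(z, y, x);
        double m = J[i];
        for (size_t k = 0; k < minus.size(); ++k) {
          int zz = z + minus[k][0], yy = y + minus[k][1], xx = x + minus[k][2];
          if (!d.inside(zz, yy, xx)) continue;
          double v = J[d.idx(zz, yy, xx)];
          if (v > m) m = v;
        }
        J[i] = std::min(m, mask[i]);
      }
  // backward sweep + queue seeding
  std::queue<long long> fifo;
  for (int x = d.nx - 1; x >= 0; --x)
    for (int y = d.ny - 1; y >= 0; --y)
      for (int z = d.nz - 1; z >= 0; --z) {
        long long i = d.idx(z, y, x);
        double m = J[i];
        for (size_t k = 0; k < plus.size(); ++k) {
          int zz = z + plus[k][0], yy = y + plus[k][1], xx = x + plus[k][2];
          if (!d.inside(zz, yy, xx)) continue;
          double v = J[d.idx(zz, yy, xx)];
          if (v > m) m = v;
        }
        J[i] = std::min(m, mask[i]);
        for (size_t k = 0; k < plus.size(); ++k) {
          int zz = z + plus[k][0], yy = y + plus[k][1], xx = x + plus[k][2];
          if (!d.inside(zz, yy, xx)) continue;
          long long q = d.idx(zz, yy, xx);
          if (J[q] < J[i] && J[q] < mask[q]) { fifo.push(i); break; }
        }
      }
  while (!fifo.empty()) {
    long long p = fifo.front();
    fifo.pop();
    int pz = (int)(p % d.nz);
    long long rest = p / d.nz;
    int py = (int)(rest % d.ny), px = (int)(rest / d.ny);
    for (size_t k = 0; k < all.size(); ++k) {
      int zz = pz + all[k][0], yy = py + all[k][1], xx = px + all[k][2];
      if (!d.inside(zz, yy, xx)) continue;
      long long q = d.idx(zz, yy, xx);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dim;
  return J;
}
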