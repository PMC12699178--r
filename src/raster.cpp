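#include "ubm.h"
using namespace Rcpp;

// Digitize a set of oriented ellipsoids into a label volume.  A voxel centre
// belongs to cell i when its ellipsoidal norm Q_i <= 1; overlaps resolve to
// the smallest Q (then lowest cell index), so cells stay pairwise disjoint.
// centers: n x 3 physical (z, y, x); semi: n x 3 (a >= b >= c);
// rot: n x 9, column-major 3x3 matrix R whose COLUMNS are the world-frame
// directions of the a, b, c axes (coordinates in (z, y, x) order).
// [[Rcpp::export]]
IntegerVector cpp_raster_ellipsoids(IntegerVector dim, NumericVector spacing,
                                    NumericVector origin, NumericMatrix centers,
                                    NumericMatrix semi, NumericMatrix rot) {
  Dim3 d(dim);
  IntegerVector lab(d.n());
  std::vector<double> bestQ(d.n(), std::numeric_limits<double>::infinity());
  int n = centers.nrow();
  for (int i = 0; i < n; ++i) {
    double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    double a = semi(i, 0), b = semi(i, 1), c = semi(i, 2);
    double rmax = a;
    int z0 = std::max(0, (int)std::floor((cz - rmax - origin[0]) / spacing[0]));
    int z1 = std::min(d.nz - 1,
                      (int)std::ceil((cz + rmax - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::floor((cy - rmax - origin[1]) / spacing[1]));
    int y1 = std::min(d.ny - 1,
                      (int)std::ceil((cy + rmax - origin[1]) / spacing[1]));
    int x0 = std::max(0, (int)std::floor((cx - rmax - origin[2]) / spacing[2]));
    int x1 = std::min(d.nx - 1,
                      (int)std::ceil((cx + rmax - origin[2]) / spacing[2]));
    // R columns (axis directions) in (z,y,x) coords
    double R[9];
    for (int k = 0; k < 9; ++k) R[k] = rot(i, k);
    for (int x = x0; x <= x1; ++x) {
      double px = origin[2] + x * spacing[2] - cx;
      for (int y = y0; y <= y1; ++y) {
        double py = origin[1] + y * spacing[1] - cy;
        for (int z = z0; z <= z1; ++z) {
          double pz = origin[0] + z * spacing[0] - cz;
          // local coords = R^T p  (columns of R are axis vectors)
          double u = R[0] * pz + R[1] * py + R[2] * px;
          double v = R[3] * pz + R[4] * py + R[5] * px;
          double w = R[6] * pz + R[7] * py + R[8] * px;
          double Q = (u / a) * (u / a) + (v / b) * (v / b) + (w / c) * (w / c);
          if (Q <= 1.0) {
            long long idx = d.idx(z, y, x);
            if (Q < bestQ[idx]) {
              bestQ[idx] = Q;
              lab[idx] = i + 1;
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
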