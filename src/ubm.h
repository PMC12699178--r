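#ifndef UBM_H
#define UBM_H

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

// All 3D grids are stored as R arrays with dim = (nz, ny, nx); the first
// index varies fastest, so linear index = z + nz*(y + ny*x).
struct Dim3 {
  int nz, ny, nx;
  Dim3(const Rcpp::IntegerVector& d) : nz(d[0]), ny(d[1]), nx(d[2]) {}
  inline long long idx(int z, int y, int x) const {
    return (long long)z + (long long)nz * ((long long)y + (long long)ny * x);
  }
  inline long long n() const { return (long long)nz * ny * nx; }
  inline bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

// 26-neighbourhood offsets, excluding (0,0,0)
inline void neighbours26(std::vector<std::array<int,3> >& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dz || dy || dx) off.push_back({{dz, dy, dx}});
}

#endif
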