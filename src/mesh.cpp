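#include "ubm.h"
using namespace Rcpp;

// Surface area of the iso-surface of a scalar field by marching tetrahedra:
// each grid cube is split into the six Kuhn tetrahedra sharing the main
// diagonal, iso-crossings are linearly interpolated along tetrahedron edges
// in physical coordinates, and triangle areas are accumulated.
static inline double triArea(const double* A, const double* B,
                             const double* C) {
  double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double v[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dim,
                   NumericVector spacing, double iso) {
  Dim3 d(dim);
  // corner bit layout: bit0 -> +x, bit1 -> +y, bit2 -> +z
  const int orders[6][3] = {{1, 2, 4}, {1, 4, 2}, {2, 1, 4},
                            {2, 4, 1}, {4, 1, 2}, {4, 2, 1}};
  double area = 0.0;
  double cval[8];
  double cpos[8][3];
  for (int x = 0; x + 1 < d.nx; ++x)
    for (int y = 0; y + 1 < d.ny; ++y)
      for (int z = 0; z + 1 < d.nz; ++z) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int dz = (c >> 2) & 1, dy = (c >> 1) & 1, dx = c & 1;
          double v = field[d.idx(z + dz, y + dy, x + dx)];
          cval[c] = v;
          cpos[c][0] = (z + dz) * spacing[0];
          cpos[c][1] = (y + dy) * spacing[1];
          cpos[c][2] = (x + dx) * spacing[2];
          if (v > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int c0 = 0;
          int c1 = orders[t][0];
          int c2 = orders[t][0] | orders[t][1];
          int c3 = 7;
          int tc[4] = {c0, c1, c2, c3};
          int above[4], nAbove = 0;
          for (int k = 0; k < 4; ++k) {
            above[k] = cval[tc[k]] > iso ? 1 : 0;
            nAbove += above[k];
          }
          if (nAbove == 0 || nAbove == 4) continue;
          // interpolated point on edge (i, j)
          double P[4][3];
          int nP = 0;
          int hi[4], lo[4], nh = 0, nl = 0;
          for (int k = 0; k < 4; ++k)
            (above[k] ? hi[nh++] : lo[nl++]) = tc[k];
          if (nAbove == 1 || nAbove == 3) {
            int apex = (nAbove == 1) ? hi[0] : lo[0];
            int* base = (nAbove == 1) ? lo : hi;
            for (int k = 0; k < 3; ++k) {
              double va = cval[apex], vb = cval[base[k]];
              double tt = (iso - va) / (vb - va);
              for (int j = 0; j < 3; ++j)
                P[nP][j] = cpos[apex][j] + tt * (cpos[base[k]][j] - cpos[apex][j]);
              ++nP;
            }
            area += triArea(P[0], P[1], P[2]);
          } else { // 2 above, 2 below: quad
            int pairs[4][2] = {{hi[0], lo[0]}, {hi[0], lo[1]},
                               {hi[1], lo[1]}, {hi[1], lo[0]}};
            for (int k = 0; k < 4; ++k) {
              double va = cval[pairs[k][0]], vb = cval[pairs[k][1]];
              double tt = (iso - va) / (vb - va);
              for (int j = 0; j < 3; ++j)
                P[k][j] = cpos[pairs[k][0]][j] +
                          tt * (cpos[pairs[k][1]][j] - cpos[pairs[k][0]][j]);
            }
            area += triArea(P[0], P[1], P[2]) + triArea(P[0], P[2], P[3]);
          }
        }
      }
  return area;
}
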