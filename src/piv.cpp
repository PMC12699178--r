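#include "ubm.h"
using namespace Rcpp;

// Block-matching PIV: normalized cross-correlation over integer shifts with
// parabolic sub-pixel peak refinement.  Images are (ny x nx) R matrices
// indexed [y, x].  Returns one vector per window centre; windows with
// near-zero variance are flagged invalid.
// [[Rcpp::export]]
List cpp_piv(NumericMatrix ref, NumericMatrix img, int window, int step,
             int maxshift) {
  int ny = ref.nrow(), nx = ref.ncol();
  std::vector<double> cy, cx, uy, ux;
  std::vector<int> ok;
  for (int ty = maxshift; ty + window <= ny - maxshift; ty += step) {
    for (int tx = maxshift; tx + window <= nx - maxshift; tx += step) {
      // reference window stats
      double sa = 0, saa = 0;
      for (int j = 0; j < window; ++j)
        for (int i = 0; i < window; ++i) {
          double a = ref(ty + i, tx + j);
          sa += a; saa += a * a;
        }
      int n = window * window;
      double ma = sa / n, va = saa / n - ma * ma;
      double bestr = -2.0;
      int bdy = 0, bdx = 0;
      int span = 2 * maxshift + 1;
      std::vector<double> cc(span * span, -2.0);
      bool flat = va < 1e-12;
      if (!flat) {
        for (int dy = -maxshift; dy <= maxshift; ++dy)
          for (int dx = -maxshift; dx <= maxshift; ++dx) {
            double sb = 0, sbb = 0, sab = 0;
            for (int j = 0; j < window; ++j)
              for (int i = 0; i < window; ++i) {
                double a = ref(ty + i, tx + j);
                double b = img(ty + dy + i, tx + dx + j);
                sb += b; sbb += b * b; sab += a * b;
              }
            double mb = sb / n, vb = sbb / n - mb * mb;
            double r;
            if (vb < 1e-12) r = -2.0;
            else r = (sab / n - ma * mb) / std::sqrt(va * vb);
            cc[(dy + maxshift) * span + (dx + maxshift)] = r;
            if (r > bestr) { bestr = r; bdy = dy; bdx = dx; }
          }
      }
      double suy = bdy, sux = bdx;
      bool valid = !flat && bestr > -1.5;
      // a perfect correlation peak needs no sub-pixel refinement
      if (valid && bestr < 1.0 - 1e-12 &&
          std::abs(bdy) < maxshift && std::abs(bdx) < maxshift) {
        // parabolic refinement per axis
        double c0 = cc[(bdy + maxshift) * span + (bdx + maxshift)];
        double cm = cc[(bdy - 1 + maxshift) * span + (bdx + maxshift)];
        double cp = cc[(bdy + 1 + maxshift) * span + (bdx + maxshift)];
        double den = cm - 2 * c0 + cp;
        if (den < -1e-12) suy += 0.5 * (cm - cp) / den;
        cm = cc[(bdy + maxshift) * span + (bdx - 1 + maxshift)];
        cp = cc[(bdy + maxshift) * span + (bdx + 1 + maxshift)];
        den = cm - 2 * c0 + cp;
        if (den < -1e-12) sux += 0.5 * (cm - cp) / den;
      }
      cy.push_back(ty + (window - 1) / 2.0);
      cx.push_back(tx + (window - 1) / 2.0);
      uy.push_back(valid ? suy : NA_REAL);
      ux.push_back(valid ? sux : NA_REAL);
      ok.push_back(valid ? 1 : 0);
    }
  }
  return List::create(_["cy"] = cy, _["cx"] = cx, _["uy"] = uy,
                      _["ux"] = ux, _["valid"] = ok);
}
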