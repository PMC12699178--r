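#include "ubm.h"
using namespace Rcpp;

// Marker-controlled watershed (Meyer's flooding) on `values` as relief,
// 26-connectivity.  Voxels where two basins meet become watershed lines
// (label 0 in the output).  Deterministic: ties broken by insertion order.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector values, IntegerVector markers,
                            IntegerVector dim) {
  Dim3 d(dim);
  std::vector<std::array<int,3> > off;
  neighbours26(off);
  const int LINE = -1;
  IntegerVector out = clone(markers);

  typedef std::tuple<double, long long, long long> Item; // value, order, idx
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long long counter = 0;
  std::vector<char> queued(out.size(), 0);

  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long long i = d.idx(z, y, x);
        if (out[i] <= 0) continue;
        for (size_t k = 0; k < off.size(); ++k) {
          int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
          if (!d.inside(zz, yy, xx)) continue;
          long long q = d.idx(zz, yy, xx);
          if (out[q] == 0 && !queued[q]) {
            queued[q] = 1;
            pq.push(Item(values[q], counter++, q));
          }
        }
      }

  while (!pq.empty()) {
    long long p = std::get<2>(pq.top());
    pq.pop();
    if (out[p] != 0) continue;
    int pz = (int)(p % d.nz);
    long long rest = p / d.nz;
    int py = (int)(rest % d.ny), px = (int)(rest / d.ny);
    int lab = 0;
    bool conflict = false;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = pz + off[k][0], yy = py + off[k][1], xx = px + off[k][2];
      if (!d.inside(zz, yy, xx)) continue;
      int L = out[d.idx(zz, yy, xx)];
      if (L > 0) {
        if (lab == 0) lab = L;
        else if (L != lab) { conflict = true; break; }
      }
    }
    if (conflict) {
      out[p] = LINE;
      continue;
    }
    if (lab == 0) { queued[p] = 0; continue; } // no labelled neighbour yet
    out[p] = lab;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = pz + off[k][0], yy = py + off[k][1], xx = px + off[k][2];
      if (!d.inside(zz, yy, xx)) continue;
      long long q = d.idx(zz, yy, xx);
      if (out[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(Item(values[q], counter++, q));
      }
    }
  }
  for (long long i = 0; i < (long long)out.size(); ++i)
    if (out[i] == LINE) out[i] = 0;
  out.attr("dim") = dim;
  return out;
}
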