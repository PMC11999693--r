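#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement on a 3-D statistic volume.
// For each threshold h in {dh, 2dh, ...} up to max(stat), voxels with
// stat >= h are partitioned into connected clusters (6- or 26-connectivity)
// and every member voxel accumulates extent^E * h^H * dh. One-sided:
// non-positive statistics are never enhanced.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim,
                       double H = 2.0, double E = 0.5, double dh = 0.0,
                       int connectivity = 6) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int V = nx * ny * nz;
  NumericVector out(V);
  double mx = 0.0;
  for (int i = 0; i < V; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0) return out;
  if (dh <= 0.0) dh = mx / 100.0;

  std::vector<int> label(V), stack(V), members(V);
  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  int noff = (int)dxs.size();

  int nsteps = (int)std::floor(mx / dh + 1e-9);
  for (int step = 1; step <= nsteps; ++step) {
    double h = dh * step;
    std::fill(label.begin(), label.end(), 0);
    int cur = 0;
    for (int s = 0; s < V; ++s) {
      if (stat[s] < h || label[s]) continue;
      ++cur;
      int top = 0, nmem = 0;
      stack[top++] = s; label[s] = cur;
      while (top > 0) {
        int vox = stack[--top];
        members[nmem++] = vox;
        int x = vox % nx, y = (vox / nx) % ny, z = vox / (nx * ny);
        for (int o = 0; o < noff; ++o) {
          int xx = x + dxs[o], yy = y + dys[o], zz = z + dzs[o];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int nb = xx + nx * (yy + ny * zz);
          if (stat[nb] >= h && !label[nb]) { label[nb] = cur; stack[top++] = nb; }
        }
      }
      double add = std::pow((double)nmem, E) * std::pow(h, H) * dh;
      for (int m = 0; m < nmem; ++m) out[members[m]] += add;
    }
  }
  out.attr("dim") = dim;
  return out;
}
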