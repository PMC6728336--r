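// Threshold-free cluster enhancement on a 3D grid.
//
// For each integration height h = k * dh (k = 1..n_steps, dh = max/n_steps)
// the suprathreshold voxels are partitioned into connected components
// (6- or 26-neighborhood) and every member voxel accumulates
// e(h)^E * h^H * dh, where e(h) is its component's size. The permutation
// test calls this once per sign per permutation, so the labelling is kept
// allocation-light.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector map, IntegerVector dims,
                               double E, double H, int n_steps,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if ((int)map.size() != V) stop("map length does not match dims");

  NumericVector enh(V);
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) if (map[v] > hmax) hmax = map[v];
  if (hmax <= 0.0) return enh;
  const double dh = hmax / n_steps;

  // neighbor offsets in (dx, dy, dz)
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int n_nb = (int)ox.size();

  std::vector<int> label(V), queue(V), comp(V);
  for (int k = 1; k <= n_steps; ++k) {
    const double h = k * dh;
    const double hH_dh = std::pow(h, H) * dh;
    std::fill(label.begin(), label.end(), 0);
    int next_label = 0;
    for (int v0 = 0; v0 < V; ++v0) {
      if (map[v0] < h || label[v0] != 0) continue;
      // BFS flood fill of the component containing v0
      ++next_label;
      int head = 0, tail = 0, csize = 0;
      queue[tail++] = v0;
      label[v0] = next_label;
      while (head < tail) {
        int v = queue[head++];
        comp[csize++] = v;
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        for (int j = 0; j < n_nb; ++j) {
          int xx = x + ox[j], yy = y + oy[j], zz = z + oz[j];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
              zz >= nz) continue;
          int w = xx + nx * (yy + ny * zz);
          if (label[w] == 0 && map[w] >= h) {
            label[w] = next_label;
            queue[tail++] = w;
          }
        }
      }
      const double add = std::pow((double)csize, E) * hH_dh;
      for (int i = 0; i < csize; ++i) enh[comp[i]] += add;
    }
  }
  return enh;
}
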