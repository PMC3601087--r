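#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian convolution of a 3D grid, zero-padded at the edges.
// sigmaVox is in voxel units per axis; axes with sigma <= 0 are skipped.
// Kernel radius 4*sigma (at least 1), normalized to unit sum per axis.
// [[Rcpp::export(name = ".gaussianSmooth3dCpp")]]
NumericVector gaussianSmooth3dCpp(NumericVector arr, IntegerVector dim,
                                  NumericVector sigmaVox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> cur(arr.begin(), arr.end());
  std::vector<double> nxt(cur.size());
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigmaVox[ax];
    if (sg <= 0) continue;
    int rad = std::max(1, (int)std::ceil(4.0 * sg));
    std::vector<double> ker(2 * rad + 1);
    double ksum = 0;
    for (int d = -rad; d <= rad; ++d) {
      ker[d + rad] = std::exp(-0.5 * d * d / (sg * sg));
      ksum += ker[d + rad];
    }
    for (double &kv : ker) kv /= ksum;

    int st = strides[ax], len = sizes[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int idx = x + nx * (y + ny * z);
          int pos = (ax == 0) ? x : (ax == 1) ? y : z;
          double acc = 0;
          int lo = std::max(-rad, -pos), hi = std::min(rad, len - 1 - pos);
          for (int d = lo; d <= hi; ++d)
            acc += ker[d + rad] * cur[idx + d * st];
          nxt[idx] = acc;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// 3D connected components on a binary grid.  Connectivity 6 (faces),
// 18 (faces+edges) or 26 (full neighborhood).  Labels are 1..K in
// first-encounter (column-major scan) order; background stays 0.
// [[Rcpp::export(name = ".labelClustersCpp")]]
List labelClustersCpp(LogicalVector mask, IntegerVector dim,
                      int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  // neighbor deltas as (dx,dy,dz) triplets so bounds checks stay per-axis
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next;
    int sz = 0;
    stack.clear();
    stack.push_back(idx);
    labels[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++sz;
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (size_t t = 0; t < odx.size(); ++t) {
        int x = cx + odx[t], y = cy + ody[t], z = cz + odz[t];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        int nb = x + nx * (y + ny * z);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
    sizes.push_back(sz);
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
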