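// Rasterization of the deformed voxel mesh back into image space: each solid
// voxel's hexahedron is carried through its 8 nodal displacements, split into
// 6 tetrahedra, and tested against 2x supersampled pixel centres of the
// target grid. Overlap priority: cement over bone.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#ifdef __GNUC__
#pragma GCC optimize("O3")
#endif
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// local corner order: v0..v7 with x fastest on the bottom face then top face
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

static inline double det3(const double a[3], const double b[3], const double c[3]) {
  return a[0] * (b[1] * c[2] - b[2] * c[1])
       - a[1] * (b[0] * c[2] - b[2] * c[0])
       + a[2] * (b[0] * c[1] - b[1] * c[0]);
}

// [[Rcpp::export(name = ".rasterize_warped")]]
List rasterize_warped(IntegerMatrix vox, IntegerVector mat,
                      NumericVector ux, NumericVector uy, NumericVector uz,
                      IntegerVector ndims, double h, NumericVector src_origin,
                      IntegerVector tdims, double t, NumericVector tgt_origin) {
  int gnx = ndims[0], gny = ndims[1];
  int mx = tdims[0], my = tdims[1], mz = tdims[2];
  R_xlen_t ntgt = (R_xlen_t)mx * my * mz;
  std::vector<uint8_t> solid_bits(ntgt, 0), cement_bits(ntgt, 0);
  std::vector<int> inverted;
  int nel = vox.nrow();
  const double eps = 1e-9;
  double P[8][3];
  for (int e = 0; e < nel; ++e) {
    int vi = vox(e, 0), vj = vox(e, 1), vk = vox(e, 2);
    bool cem = mat[e] == 2;
    for (int c = 0; c < 8; ++c) {
      int ni = vi + CORNER[c][0], nj = vj + CORNER[c][1], nk = vk + CORNER[c][2];
      R_xlen_t nidx = idx3(ni, nj, nk, gnx, gny);
      // warped position in target sample-grid units: 2 * (p - origin_t) / t
      P[c][0] = 2.0 * (src_origin[0] + ni * h + ux[nidx] - tgt_origin[0]) / t;
      P[c][1] = 2.0 * (src_origin[1] + nj * h + uy[nidx] - tgt_origin[1]) / t;
      P[c][2] = 2.0 * (src_origin[2] + nk * h + uz[nidx] - tgt_origin[2]) / t;
    }
    bool flagged = false;
    for (int tt = 0; tt < 6; ++tt) {
      const double* a = P[TETS[tt][0]];
      const double* b = P[TETS[tt][1]];
      const double* c = P[TETS[tt][2]];
      const double* d = P[TETS[tt][3]];
      double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
      double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
      double ad[3] = {d[0] - a[0], d[1] - a[1], d[2] - a[2]};
      double D0 = det3(ab, ac, ad);
      if (D0 <= 0.0) {
        if (!flagged) { inverted.push_back(e + 1); flagged = true; }
        continue;
      }
      double lo[3], hi[3];
      for (int x = 0; x < 3; ++x) {
        lo[x] = std::min(std::min(a[x], b[x]), std::min(c[x], d[x]));
        hi[x] = std::max(std::max(a[x], b[x]), std::max(c[x], d[x]));
      }
      // sample s sits at (s + 0.5) in sample-grid units
      int s0[3], s1[3];
      int smax[3] = {2 * mx - 1, 2 * my - 1, 2 * mz - 1};
      bool empty = false;
      for (int x = 0; x < 3; ++x) {
        s0[x] = (int)std::ceil(lo[x] - 0.5 - 1e-12);
        s1[x] = (int)std::floor(hi[x] - 0.5 + 1e-12);
        if (s0[x] < 0) s0[x] = 0;
        if (s1[x] > smax[x]) s1[x] = smax[x];
        if (s0[x] > s1[x]) empty = true;
      }
      if (empty) continue;
      for (int sz = s0[2]; sz <= s1[2]; ++sz) {
        double pz = sz + 0.5;
        for (int sy = s0[1]; sy <= s1[1]; ++sy) {
          double py = sy + 0.5;
          for (int sx = s0[0]; sx <= s1[0]; ++sx) {
            double px = sx + 0.5;
            double ap[3] = {px - a[0], py - a[1], pz - a[2]};
            double l1 = det3(ap, ac, ad) / D0;
            if (l1 < -eps || l1 > 1 + eps) continue;
            double l2 = det3(ab, ap, ad) / D0;
            if (l2 < -eps || l1 + l2 > 1 + eps) continue;
            double l3 = det3(ab, ac, ap) / D0;
            if (l3 < -eps || l1 + l2 + l3 > 1 + eps) continue;
            R_xlen_t v = idx3(sx >> 1, sy >> 1, sz >> 1, mx, my);
            uint8_t bit = (uint8_t)(1u << ((sx & 1) + 2 * (sy & 1) + 4 * (sz & 1)));
            solid_bits[v] |= bit;
            if (cem) cement_bits[v] |= bit;
          }
        }
      }
    }
    if (e % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector lab(ntgt);
  for (R_xlen_t v = 0; v < ntgt; ++v) {
    int ns = 0, nc = 0;
    uint8_t sb = solid_bits[v], cb = cement_bits[v];
    for (int b = 0; b < 8; ++b) {
      ns += (sb >> b) & 1;
      nc += (cb >> b) & 1;
    }
    lab[v] = (ns >= 4) ? ((2 * nc >= ns) ? 2 : 1) : 0;
  }
  return List::create(_["labels"] = lab,
                      _["inverted_elements"] = IntegerVector(inverted.begin(), inverted.end()));
}
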