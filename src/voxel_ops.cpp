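// Low-level voxel-grid kernels: connected components, Euclidean distance
// transforms, Voronoi strut-lattice helpers, separable Gaussian blur.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <map>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Union-find connected components, 26-connectivity, on a logical mask.
// Returns integer label array (0 = background), labels 1..ncomp ordered by
// first voxel encountered.

struct DisjointSet {
  std::vector<int> parent;
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  int add() { int id = (int)parent.size(); parent.push_back(id); return id; }
};

// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  DisjointSet ds;
  // backward half-neighbourhood (13 offsets)
  int offs[13][3];
  int m = 0;
  for (int dk = -1; dk <= 0; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
        offs[m][0] = di; offs[m][1] = dj; offs[m][2] = dk; ++m;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = idx3(i, j, k, nx, ny);
        if (!mask[v]) continue;
        int cur = -1;
        for (int t = 0; t < 13; ++t) {
          int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          R_xlen_t w = idx3(ii, jj, kk, nx, ny);
          if (!mask[w]) continue;
          int lw = lab[w] - 1;
          if (cur < 0) cur = ds.find(lw);
          else ds.unite(cur, lw), cur = ds.find(cur);
        }
        if (cur < 0) cur = ds.add();
        lab[v] = cur + 1;
      }
  // relabel compactly in scan order of root first-appearance
  std::vector<int> newlab((int)ds.parent.size(), 0);
  int next = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!lab[v]) continue;
    int r = ds.find(lab[v] - 1);
    if (!newlab[r]) newlab[r] = ++next;
    lab[v] = newlab[r];
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, isotropic spacing, with optional feature transform (index of the
// nearest seed voxel, 1-based). Input: mask of seed voxels (distance 0).

static void dt1d(const double* f, const int* id, int n, double* d, int* di,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] < INF) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) { d[q] = INF; di[q] = -1; }
    return;
  }
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
    di[q] = id[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
List edt3d(LogicalVector seeds, IntegerVector dims, bool feature) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  std::vector<int> fi(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    d[v] = seeds[v] ? 0.0 : std::numeric_limits<double>::infinity();
    fi[v] = seeds[v] ? (int)(v + 1) : -1;
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dl(nmax);
  std::vector<int> idl(nmax), io(nmax), vv(nmax);
  std::vector<double> zz(nmax + 1);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = idx3(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) { f[i] = d[base + i]; io[i] = fi[base + i]; }
      dt1d(f.data(), io.data(), nx, dl.data(), idl.data(), vv, zz);
      for (int i = 0; i < nx; ++i) { d[base + i] = dl[i]; fi[base + i] = idl[i]; }
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) { R_xlen_t v = idx3(i, j, k, nx, ny); f[j] = d[v]; io[j] = fi[v]; }
      dt1d(f.data(), io.data(), ny, dl.data(), idl.data(), vv, zz);
      for (int j = 0; j < ny; ++j) { R_xlen_t v = idx3(i, j, k, nx, ny); d[v] = dl[j]; fi[v] = idl[j]; }
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) { R_xlen_t v = idx3(i, j, k, nx, ny); f[k] = d[v]; io[k] = fi[v]; }
      dt1d(f.data(), io.data(), nz, dl.data(), idl.data(), vv, zz);
      for (int k = 0; k < nz; ++k) { R_xlen_t v = idx3(i, j, k, nx, ny); d[v] = dl[k]; fi[v] = idl[k]; }
    }
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = d[v];
  if (!feature) return List::create(_["dist2"] = out);
  IntegerVector ft(n);
  for (R_xlen_t v = 0; v < n; ++v) ft[v] = fi[v];
  return List::create(_["dist2"] = out, _["feature"] = ft);
}

// ---------------------------------------------------------------------------
// Nearest-seed (Voronoi) labelling of a coarse grid: brute force over seeds.
// centers: voxel centre coordinates are origin + (idx + 0.5) * vox (mm).

// [[Rcpp::export(name = ".nearest_seed_labels")]]
IntegerVector nearest_seed_labels(NumericMatrix seeds, IntegerVector dims,
                                  double vox, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ns = seeds.nrow();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<double> sx(ns), sy(ns), sz(ns);
  for (int s = 0; s < ns; ++s) { sx[s] = seeds(s, 0); sy[s] = seeds(s, 1); sz[s] = seeds(s, 2); }
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + (k + 0.5) * vox;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + (j + 0.5) * vox;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + (i + 0.5) * vox;
        double best = std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int s = 0; s < ns; ++s) {
          double dx = x - sx[s], dy = y - sy[s], dz = z - sz[s];
          double d = dx * dx + dy * dy + dz * dz;
          if (d < best) { best = d; bi = s; }
        }
        lab[idx3(i, j, k, nx, ny)] = bi + 1;
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Voronoi edge extraction on the dual grid: a dual node (corner shared by a
// 2x2x2 block of coarse voxels) lies on a Voronoi edge if >= 3 distinct cell
// labels meet there (>= 4 marks a vertex). Returns positions (corner coords,
// mm), a strut id formed from the three dominant labels, and a vertex flag.

// [[Rcpp::export(name = ".voronoi_edge_points")]]
List voronoi_edge_points(IntegerVector lab, IntegerVector dims, double vox,
                         NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> px, py, pz;
  std::vector<double> ids;
  std::vector<int> vert;
  int labs[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int m = 0;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = 0; dj <= 1; ++dj)
            for (int di = 0; di <= 1; ++di)
              labs[m++] = lab[idx3(i + di, j + dj, k + dk, nx, ny)];
        // count distinct (small fixed set)
        int uniq[8], nu = 0;
        for (int t = 0; t < 8; ++t) {
          bool seen = false;
          for (int u = 0; u < nu; ++u) if (uniq[u] == labs[t]) { seen = true; break; }
          if (!seen) uniq[nu++] = labs[t];
        }
        if (nu < 3) continue;
        // sort first three smallest labels for a stable strut id
        for (int a = 0; a < nu; ++a)
          for (int b = a + 1; b < nu; ++b)
            if (uniq[b] < uniq[a]) std::swap(uniq[a], uniq[b]);
        double id = ((double)uniq[0] * 1048576.0 + (double)uniq[1]) * 1048576.0 + (double)uniq[2];
        px.push_back(origin[0] + (i + 1) * vox);
        py.push_back(origin[1] + (j + 1) * vox);
        pz.push_back(origin[2] + (k + 1) * vox);
        ids.push_back(id);
        vert.push_back(nu >= 4 ? 1 : 0);
      }
  int np = (int)px.size();
  NumericMatrix pts(np, 3);
  NumericVector idv(np);
  IntegerVector vv(np);
  for (int t = 0; t < np; ++t) {
    pts(t, 0) = px[t]; pts(t, 1) = py[t]; pts(t, 2) = pz[t];
    idv[t] = ids[t]; vv[t] = vert[t];
  }
  return List::create(_["points"] = pts, _["strut_id"] = idv, _["vertex"] = vv);
}

// ---------------------------------------------------------------------------
// Strut stamping: for each centreline point with radius r_i, update the fine
// grid field q(v) = min_i dist(v, p_i) / r_i within the stamp radius. Solid
// phase at shrink factor s is then {q <= s}.

// [[Rcpp::export(name = ".stamp_struts")]]
NumericVector stamp_struts(NumericMatrix pts, NumericVector radii,
                           IntegerVector dims, double vox, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector q(n, R_PosInf);
  int np = pts.nrow();
  for (int t = 0; t < np; ++t) {
    double x = pts(t, 0), y = pts(t, 1), z = pts(t, 2), r = radii[t];
    // the voxel containing the centreline point is always part of the strut
    // (keeps chains connected when radii approach the voxel size)
    {
      int ci = (int)std::floor((x - origin[0]) / vox);
      int cj = (int)std::floor((y - origin[1]) / vox);
      int ck = (int)std::floor((z - origin[2]) / vox);
      if (ci >= 0 && cj >= 0 && ck >= 0 && ci < nx && cj < ny && ck < nz) {
        double dx = origin[0] + (ci + 0.5) * vox - x;
        double dy = origin[1] + (cj + 0.5) * vox - y;
        double dz = origin[2] + (ck + 0.5) * vox - z;
        // never thinner than the voxel holding the centreline at full scale
        double qq = std::min(std::sqrt(dx * dx + dy * dy + dz * dz) / r, 1.0);
        R_xlen_t v = idx3(ci, cj, ck, nx, ny);
        if (qq < q[v]) q[v] = qq;
      }
    }
    int i0 = (int)std::floor((x - r - origin[0]) / vox - 0.5);
    int i1 = (int)std::ceil((x + r - origin[0]) / vox - 0.5);
    int j0 = (int)std::floor((y - r - origin[1]) / vox - 0.5);
    int j1 = (int)std::ceil((y + r - origin[1]) / vox - 0.5);
    int k0 = (int)std::floor((z - r - origin[2]) / vox - 0.5);
    int k1 = (int)std::ceil((z + r - origin[2]) / vox - 0.5);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + (k + 0.5) * vox - z;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + (j + 0.5) * vox - y;
        double dyz = dy * dy + dz * dz;
        if (dyz > r * r) continue;
        R_xlen_t base = idx3(i0, j, k, nx, ny);
        for (int i = i0; i <= i1; ++i, ++base) {
          double dx = origin[0] + (i + 0.5) * vox - x;
          double d2 = dx * dx + dyz;
          if (d2 > r * r) continue;
          double qq = std::sqrt(d2) / r;
          if (qq < q[base]) q[base] = qq;
        }
      }
    }
  }
  return q;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with replicate boundary, kernel given.

// [[Rcpp::export(name = ".blur_separable")]]
NumericVector blur_separable(NumericVector a, IntegerVector dims, NumericVector kern) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kr = ((int)kern.size() - 1) / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector src = clone(a), dst(n);
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = idx3(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int ii = std::min(std::max(i + t, 0), nx - 1);
          s += kern[t + kr] * src[base + ii];
        }
        dst[base + i] = s;
      }
    }
  std::swap(src, dst);
  // y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int jj = std::min(std::max(j + t, 0), ny - 1);
          s += kern[t + kr] * src[idx3(i, jj, k, nx, ny)];
        }
        dst[idx3(i, j, k, nx, ny)] = s;
      }
  std::swap(src, dst);
  // z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int kk = std::min(std::max(k + t, 0), nz - 1);
          s += kern[t + kr] * src[idx3(i, j, kk, nx, ny)];
        }
        dst[idx3(i, j, k, nx, ny)] = s;
      }
  return dst;
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a node-grid vector field onto a finer node grid.
// Field components are arrays over the source node grid ((nx+1) x ... nodes
// at origin + idx * h). Target nodes at origin + idx * t.

// [[Rcpp::export(name = ".resample_field_trilinear")]]
List resample_field_trilinear(NumericVector ux, NumericVector uy, NumericVector uz,
                              IntegerVector ndims, double h,
                              IntegerVector tdims, double t) {
  int nx = ndims[0], ny = ndims[1], nz = ndims[2];
  int mx = tdims[0], my = tdims[1], mz = tdims[2];
  R_xlen_t m = (R_xlen_t)mx * my * mz;
  NumericVector vx(m), vy(m), vz(m);
  for (int k = 0; k < mz; ++k) {
    double zf = k * t / h;
    int k0 = std::min((int)std::floor(zf), nz - 2); k0 = std::max(k0, 0);
    double wz = zf - k0;
    wz = std::min(std::max(wz, 0.0), 1.0);
    for (int j = 0; j < my; ++j) {
      double yf = j * t / h;
      int j0 = std::min((int)std::floor(yf), ny - 2); j0 = std::max(j0, 0);
      double wy = std::min(std::max(yf - j0, 0.0), 1.0);
      for (int i = 0; i < mx; ++i) {
        double xf = i * t / h;
        int i0 = std::min((int)std::floor(xf), nx - 2); i0 = std::max(i0, 0);
        double wx = std::min(std::max(xf - i0, 0.0), 1.0);
        double acc[3] = {0, 0, 0};
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = 0; dj <= 1; ++dj)
            for (int di = 0; di <= 1; ++di) {
              double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
              if (w == 0) continue;
              R_xlen_t v = idx3(i0 + di, j0 + dj, k0 + dk, nx, ny);
              acc[0] += w * ux[v]; acc[1] += w * uy[v]; acc[2] += w * uz[v];
            }
        R_xlen_t w3 = idx3(i, j, k, mx, my);
        vx[w3] = acc[0]; vy[w3] = acc[1]; vz[w3] = acc[2];
      }
    }
  }
  return List::create(_["ux"] = vx, _["uy"] = vy, _["uz"] = vz);
}
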