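// Matrix-free element-by-element kernels for the voxel hexahedral elasticity
// solver: global stiffness products, diagonal extraction, and a Jacobi
// preconditioned conjugate gradient loop. Elements share per-material 24x24
// stiffness templates; optional penalty springs couple duplicated interface
// node DOFs (linearized frictionless contact).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __GNUC__
#pragma GCC optimize("O3")
#endif
using namespace Rcpp;

struct HexSystem {
  const int* nodes;      // nel x 8, column-major, 0-based node ids
  int nel;
  const int* tmpl;       // per-element template id, 0-based
  std::vector<const double*> K; // 24x24 templates, column-major
  const int* pen_a;      // penalty DOF pairs (0-based), may be empty
  const int* pen_b;
  const double* pen_k;
  int npen;
  const int* fixed;      // 0/1 per DOF
  R_xlen_t ndof;

  // y := K u, then zero rows at fixed DOFs if mask_fixed
  void matvec(const double* u, double* y, bool mask_fixed) const {
    for (R_xlen_t i = 0; i < ndof; ++i) y[i] = 0.0;
    double ue[24], we[24];
    for (int e = 0; e < nel; ++e) {
      const double* Ke = K[tmpl[e]];
      int dof[24];
      for (int a = 0; a < 8; ++a) {
        int n = nodes[e + (R_xlen_t)a * nel];
        dof[3 * a] = 3 * n; dof[3 * a + 1] = 3 * n + 1; dof[3 * a + 2] = 3 * n + 2;
      }
      for (int a = 0; a < 24; ++a) ue[a] = u[dof[a]];
      for (int a = 0; a < 24; ++a) we[a] = 0.0;
      for (int c = 0; c < 24; ++c) {
        double uc = ue[c];
        if (uc == 0.0) continue;
        const double* col = Ke + 24 * c;
        for (int r = 0; r < 24; ++r) we[r] += col[r] * uc;
      }
      for (int a = 0; a < 24; ++a) y[dof[a]] += we[a];
    }
    for (int p = 0; p < npen; ++p) {
      double dif = u[pen_a[p]] - u[pen_b[p]];
      y[pen_a[p]] += pen_k[p] * dif;
      y[pen_b[p]] -= pen_k[p] * dif;
    }
    if (mask_fixed)
      for (R_xlen_t i = 0; i < ndof; ++i) if (fixed[i]) y[i] = 0.0;
  }
};

static HexSystem make_system(IntegerMatrix elem_nodes, IntegerVector elem_tmpl,
                             List templates, IntegerVector pen_a, IntegerVector pen_b,
                             NumericVector pen_k, IntegerVector fixed) {
  HexSystem S;
  S.nodes = INTEGER(elem_nodes);
  S.nel = elem_nodes.nrow();
  S.tmpl = INTEGER(elem_tmpl);
  for (int t = 0; t < templates.size(); ++t) {
    NumericMatrix Kt = templates[t];
    S.K.push_back(REAL(Kt));
  }
  S.npen = pen_a.size();
  S.pen_a = S.npen ? INTEGER(pen_a) : nullptr;
  S.pen_b = S.npen ? INTEGER(pen_b) : nullptr;
  S.pen_k = S.npen ? REAL(pen_k) : nullptr;
  S.fixed = INTEGER(fixed);
  S.ndof = fixed.size();
  return S;
}

// [[Rcpp::export(name = ".hex_matvec")]]
NumericVector hex_matvec(IntegerMatrix elem_nodes, IntegerVector elem_tmpl,
                         List templates, IntegerVector pen_a, IntegerVector pen_b,
                         NumericVector pen_k, IntegerVector fixed,
                         NumericVector u, bool mask_fixed) {
  HexSystem S = make_system(elem_nodes, elem_tmpl, templates, pen_a, pen_b, pen_k, fixed);
  NumericVector y(S.ndof);
  S.matvec(REAL(u), REAL(y), mask_fixed);
  return y;
}

// [[Rcpp::export(name = ".hex_diag")]]
NumericVector hex_diag(IntegerMatrix elem_nodes, IntegerVector elem_tmpl,
                       List templates, IntegerVector pen_a, IntegerVector pen_b,
                       NumericVector pen_k, R_xlen_t ndof) {
  NumericVector d(ndof, 0.0);
  int nel = elem_nodes.nrow();
  const int* nodes = INTEGER(elem_nodes);
  for (int e = 0; e < nel; ++e) {
    NumericMatrix Ke = templates[elem_tmpl[e]];
    for (int a = 0; a < 8; ++a) {
      int n = nodes[e + (R_xlen_t)a * nel];
      for (int c = 0; c < 3; ++c)
        d[3 * n + c] += Ke(3 * a + c, 3 * a + c);
    }
  }
  for (int p = 0; p < pen_a.size(); ++p) {
    d[pen_a[p]] += pen_k[p];
    d[pen_b[p]] += pen_k[p];
  }
  return d;
}

// [[Rcpp::export(name = ".hex_pcg")]]
List hex_pcg(IntegerMatrix elem_nodes, IntegerVector elem_tmpl, List templates,
             IntegerVector pen_a, IntegerVector pen_b, NumericVector pen_k,
             IntegerVector fixed, NumericVector b, NumericVector x0,
             NumericVector diag_prec, double tol, int maxit) {
  HexSystem S = make_system(elem_nodes, elem_tmpl, templates, pen_a, pen_b, pen_k, fixed);
  R_xlen_t n = S.ndof;
  NumericVector x = clone(x0);
  std::vector<double> r(n), z(n), p(n), Ap(n), minv(n);
  for (R_xlen_t i = 0; i < n; ++i)
    minv[i] = (fixed[i] || diag_prec[i] <= 0.0) ? 0.0 : 1.0 / diag_prec[i];
  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    for (R_xlen_t i = 0; i < n; ++i) x[i] = 0.0;
    return List::create(_["x"] = x, _["iterations"] = 0, _["relres"] = 0.0,
                        _["converged"] = true);
  }
  S.matvec(REAL(x), Ap.data(), true);
  for (R_xlen_t i = 0; i < n; ++i) r[i] = fixed[i] ? 0.0 : b[i] - Ap[i];
  double rz = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) { z[i] = minv[i] * r[i]; rz += r[i] * z[i]; }
  for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i];
  double relres = 0.0;
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    double rn = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) rn += r[i] * r[i];
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) { converged = true; break; }
    S.matvec(p.data(), Ap.data(), true);
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break; // lost positive-definiteness (should not happen)
    double alpha = rz / pAp;
    for (R_xlen_t i = 0; i < n; ++i) { x[i] += alpha * p[i]; r[i] -= alpha * Ap[i]; }
    double rznew = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { z[i] = minv[i] * r[i]; rznew += r[i] * z[i]; }
    double beta = rznew / rz;
    rz = rznew;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = x, _["iterations"] = it, _["relres"] = relres,
                      _["converged"] = converged);
}
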