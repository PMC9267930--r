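#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include "octree.h"

using namespace Rcpp;

// Exact all-pairs Coulomb forces and potentials in Hartree atomic units with
// Plummer softening eps:  F_i = sum_j qi qj (ri-rj) / (|ri-rj|^2 + eps^2)^{3/2},
// phi_i = sum_j qj / sqrt(|ri-rj|^2 + eps^2).  Symmetric (Newton third law)
// accumulation, ascending-j summation order.
// [[Rcpp::export]]
List cpp_brute_forces(NumericMatrix pos, NumericVector q, double eps) {
  int n = pos.nrow();
  if (n < 1) stop("need at least one charged particle");
  NumericMatrix F(n, 3);
  NumericVector phi(n);
  double e2 = eps * eps;
  double npairs = 0;
  for (int i = 0; i < n - 1; ++i) {
    double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2), qi = q[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - pos(j, 0), dy = yi - pos(j, 1), dz = zi - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz + e2;
      if (r2 == 0.0)
        stop("singular-configuration error: coincident charges %d and %d with zero softening",
             i + 1, j + 1);
      double rinv = 1.0 / std::sqrt(r2);
      double r3inv = rinv / r2;
      double f = qi * q[j] * r3inv;
      F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
      F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
      phi[i] += q[j] * rinv;
      phi[j] += qi * rinv;
      npairs += 1;
    }
  }
  return List::create(_["force"] = F, _["potential"] = phi,
                      _["pair_evals"] = npairs);
}

// Per-cell multipole aggregates for an octree built over charged particles:
// total charge Q, |q|-weighted center of charge, dipole moment about that
// center.  Parents are assembled from children by the shift theorem.
struct MomTree {
  std::vector<std::vector<double>> Q, A, cx, cy, cz, px, py, pz;
};

static void compute_moments_core(const Octree &T, const double *q, MomTree &M) {
  int d = T.depth;
  M.Q.assign(d + 1, {}); M.A.assign(d + 1, {});
  M.cx.assign(d + 1, {}); M.cy.assign(d + 1, {}); M.cz.assign(d + 1, {});
  M.px.assign(d + 1, {}); M.py.assign(d + 1, {}); M.pz.assign(d + 1, {});
  for (int k = 0; k <= d; ++k) {
    size_t m = T.lv_pre[k].size();
    M.Q[k].assign(m, 0); M.A[k].assign(m, 0);
    M.cx[k].assign(m, 0); M.cy[k].assign(m, 0); M.cz[k].assign(m, 0);
    M.px[k].assign(m, 0); M.py[k].assign(m, 0); M.pz[k].assign(m, 0);
  }
  // leaves: direct sums
  for (size_t j = 0; j < T.lv_pre[d].size(); ++j) {
    int s = T.lv_start[d][j], e = T.lv_start[d][j + 1];
    double Q = 0, A = 0, cx = 0, cy = 0, cz = 0;
    for (int t = s; t < e; ++t) {
      int i = T.perm[t];
      double aq = std::fabs(q[i]);
      Q += q[i]; A += aq;
      cx += aq * T.X[i]; cy += aq * T.Y[i]; cz += aq * T.Z[i];
    }
    if (A > 0) { cx /= A; cy /= A; cz /= A; }
    double px = 0, py = 0, pz = 0;
    for (int t = s; t < e; ++t) {
      int i = T.perm[t];
      px += q[i] * (T.X[i] - cx);
      py += q[i] * (T.Y[i] - cy);
      pz += q[i] * (T.Z[i] - cz);
    }
    M.Q[d][j] = Q; M.A[d][j] = A;
    M.cx[d][j] = cx; M.cy[d][j] = cy; M.cz[d][j] = cz;
    M.px[d][j] = px; M.py[d][j] = py; M.pz[d][j] = pz;
  }
  // internal nodes bottom-up
  for (int k = d - 1; k >= 0; --k) {
    const std::vector<uint64_t> &P = T.lv_pre[k + 1];
    for (size_t j = 0; j < T.lv_pre[k].size(); ++j) {
      uint64_t pre = T.lv_pre[k][j];
      size_t c0 = std::lower_bound(P.begin(), P.end(), pre << 3) - P.begin();
      double Q = 0, A = 0, cx = 0, cy = 0, cz = 0;
      size_t c1 = c0;
      while (c1 < P.size() && P[c1] < ((pre + 1) << 3)) {
        Q += M.Q[k + 1][c1]; A += M.A[k + 1][c1];
        cx += M.A[k + 1][c1] * M.cx[k + 1][c1];
        cy += M.A[k + 1][c1] * M.cy[k + 1][c1];
        cz += M.A[k + 1][c1] * M.cz[k + 1][c1];
        ++c1;
      }
      if (A > 0) { cx /= A; cy /= A; cz /= A; }
      double px = 0, py = 0, pz = 0;
      for (size_t t = c0; t < c1; ++t) {
        px += M.px[k + 1][t] + M.Q[k + 1][t] * (M.cx[k + 1][t] - cx);
        py += M.py[k + 1][t] + M.Q[k + 1][t] * (M.cy[k + 1][t] - cy);
        pz += M.pz[k + 1][t] + M.Q[k + 1][t] * (M.cz[k + 1][t] - cz);
      }
      M.Q[k][j] = Q; M.A[k][j] = A;
      M.cx[k][j] = cx; M.cy[k][j] = cy; M.cz[k][j] = cz;
      M.px[k][j] = px; M.py[k][j] = py; M.pz[k][j] = pz;
    }
  }
}

struct WalkCtx {
  const Octree *T;
  const MomTree *M;
  const double *q;
  double theta2;     // theta^2 (0 forces full opening)
  bool use_theta;
  int order;         // 0 monopole, 1 monopole+dipole
  double e2;         // softening^2
  long long pp, nmul;
};

static void walk_rec(WalkCtx &W, int k, int j, double tx, double ty, double tz,
                     double qt, int slot, double &fx, double &fy, double &fz,
                     double &ph) {
  const Octree &T = *W.T;
  const MomTree &M = *W.M;
  int s = T.lv_start[k][j], e = T.lv_start[k][j + 1];
  double side = T.side / (double)((uint64_t)1 << k);
  double dx = tx - M.cx[k][j], dy = ty - M.cy[k][j], dz = tz - M.cz[k][j];
  double d2 = dx * dx + dy * dy + dz * dz;
  bool contains = (slot >= s && slot < e);
  if (W.use_theta && !contains && side * side < W.theta2 * d2) {
    // accepted far cell: monopole (+ dipole) about the center of charge
    W.nmul++;
    double R2 = d2 + W.e2;
    if (R2 == 0.0) return;                 // empty of effect only if Q=p=0
    double Rinv = 1.0 / std::sqrt(R2);
    double R3inv = Rinv / R2;
    double Q = M.Q[k][j];
    ph += Q * Rinv;
    fx += qt * Q * dx * R3inv;
    fy += qt * Q * dy * R3inv;
    fz += qt * Q * dz * R3inv;
    if (W.order >= 1) {
      double px = M.px[k][j], py = M.py[k][j], pz = M.pz[k][j];
      double pr = px * dx + py * dy + pz * dz;
      ph += pr * R3inv;
      double c = 3.0 * pr / R2;
      fx += qt * (c * dx - px) * R3inv;
      fy += qt * (c * dy - py) * R3inv;
      fz += qt * (c * dz - pz) * R3inv;
    }
    return;
  }
  // open: small slot ranges are summed directly (ascending slots, the same
  // accumulation order a full descent would produce)
  if (k == T.depth || e - s <= 8) {
    for (int t = s; t < e; ++t) {
      int i = T.perm[t];
      if (t == slot) continue;             // self
      double ddx = tx - T.X[i], ddy = ty - T.Y[i], ddz = tz - T.Z[i];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz + W.e2;
      if (r2 == 0.0)
        stop("singular-configuration error: coincident charges with zero softening");
      double rinv = 1.0 / std::sqrt(r2);
      double r3inv = rinv / r2;
      W.pp++;
      ph += W.q[i] * rinv;
      double f = qt * W.q[i] * r3inv;
      fx += f * ddx; fy += f * ddy; fz += f * ddz;
    }
    return;
  }
  uint64_t pre = T.lv_pre[k][j];
  const std::vector<uint64_t> &P = T.lv_pre[k + 1];
  size_t c0 = std::lower_bound(P.begin(), P.end(), pre << 3) - P.begin();
  for (size_t t = c0; t < P.size() && P[t] < ((pre + 1) << 3); ++t)
    walk_rec(W, k + 1, (int)t, tx, ty, tz, qt, slot, fx, fy, fz, ph);
}

// Barnes-Hut forces/potentials.  MAC: a cell of geometric side s at distance
// d from the target (measured to the cell's center of charge) is accepted
// unopened when s/d < theta; a cell whose slot range contains the target is
// always opened.  theta = 0 degenerates to the exact all-pairs sum.
// [[Rcpp::export]]
List cpp_tree_forces(NumericMatrix pos, NumericVector q, double eps,
                     double theta, int order, int depth) {
  int n = pos.nrow();
  if (n < 1) stop("need at least one charged particle");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double o[3], side;
  bounding_cube(x.data(), y.data(), z.data(), n, 1e-6, o, side);
  Octree T;
  oct_build_core(T, x.data(), y.data(), z.data(), n, depth, o, side);
  MomTree M;
  std::vector<double> qq(q.begin(), q.end());
  compute_moments_core(T, qq.data(), M);
  WalkCtx W{&T, &M, qq.data(), theta * theta, theta > 0, order, eps * eps, 0, 0};
  NumericMatrix F(n, 3);
  NumericVector phi(n);
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0, fz = 0, ph = 0;
    walk_rec(W, 0, 0, x[i], y[i], z[i], qq[i], T.slot_of[i], fx, fy, fz, ph);
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
    phi[i] = ph;
  }
  // symmetric-pair-equivalent count: each direct interaction is walked from
  // both ends, so halve it before adding the multipole evaluations
  double count = 0.5 * (double)W.pp + (double)W.nmul;
  return List::create(_["force"] = F, _["potential"] = phi,
                      _["pair_evals"] = count,
                      _["direct_evals"] = (double)W.pp,
                      _["multipole_evals"] = (double)W.nmul);
}

// Moments table for inspection/tests: one row per occupied box.
// [[Rcpp::export]]
List cpp_moments(NumericMatrix pos, NumericVector q, int depth) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double o[3], side;
  bounding_cube(x.data(), y.data(), z.data(), n, 1e-6, o, side);
  Octree T;
  oct_build_core(T, x.data(), y.data(), z.data(), n, depth, o, side);
  MomTree M;
  std::vector<double> qq(q.begin(), q.end());
  compute_moments_core(T, qq.data(), M);
  std::vector<int> lev, from, to;
  std::vector<double> id, Q, cx, cy, cz, px, py, pz, sd;
  for (int k = 0; k <= depth; ++k)
    for (size_t j = 0; j < T.lv_pre[k].size(); ++j) {
      lev.push_back(k);
      id.push_back((double)T.lv_pre[k][j]);
      from.push_back(T.lv_start[k][j] + 1);
      to.push_back(T.lv_start[k][j + 1]);
      Q.push_back(M.Q[k][j]);
      cx.push_back(M.cx[k][j]); cy.push_back(M.cy[k][j]); cz.push_back(M.cz[k][j]);
      px.push_back(M.px[k][j]); py.push_back(M.py[k][j]); pz.push_back(M.pz[k][j]);
      sd.push_back(T.side / (double)((uint64_t)1 << k));
    }
  return List::create(_["depth"] = wrap(lev), _["id"] = wrap(id),
                      _["slot_from"] = wrap(from), _["slot_to"] = wrap(to),
                      _["Q"] = wrap(Q),
                      _["cx"] = wrap(cx), _["cy"] = wrap(cy), _["cz"] = wrap(cz),
                      _["px"] = wrap(px), _["py"] = wrap(py), _["pz"] = wrap(pz),
                      _["side"] = wrap(sd),
                      _["perm"] = wrap([&T] {
                        std::vector<int> p(T.perm.size());
                        for (size_t i = 0; i < p.size(); ++i) p[i] = T.perm[i] + 1;
                        return p;
                      }()));
}
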