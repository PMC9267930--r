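#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <climits>
#include "octree.h"

using namespace Rcpp;

__attribute__((noinline))
double pair_dist2(double ax, double ay, double az,
                  double bx, double by, double bz) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  return dx * dx + dy * dy + dz * dz;
}

uint64_t box_id_of(double x, double y, double z,
                   const double o[3], double side, int depth) {
  double lo[3] = {o[0], o[1], o[2]};
  double hi[3] = {o[0] + side, o[1] + side, o[2] + side};
  double c[3] = {x, y, z};
  uint64_t id = 0;
  for (int k = 0; k < depth; ++k) {
    uint64_t oct = 0;
    for (int a = 0; a < 3; ++a) {
      double mid = 0.5 * (lo[a] + hi[a]);
      if (c[a] >= mid) {        // lower-inclusive half-open convention
        oct |= (uint64_t)1 << (2 - a);   // bit order: x, y, z
        lo[a] = mid;
      } else {
        hi[a] = mid;
      }
    }
    id = (id << 3) | oct;
  }
  return id;
}

void bounding_cube(const double *x, const double *y, const double *z, int n,
                   double rel, double o[3], double &side) {
  double lo[3] = {x[0], y[0], z[0]}, hi[3] = {x[0], y[0], z[0]};
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo[0]) lo[0] = x[i];
    if (x[i] > hi[0]) hi[0] = x[i];
    if (y[i] < lo[1]) lo[1] = y[i];
    if (y[i] > hi[1]) hi[1] = y[i];
    if (z[i] < lo[2]) lo[2] = z[i];
    if (z[i] > hi[2]) hi[2] = z[i];
  }
  double s = 0;
  for (int a = 0; a < 3; ++a) s = std::max(s, hi[a] - lo[a]);
  if (s <= 0) s = 1.0;          // all particles coincident
  double pad = 0.5 * s * rel;
  side = s * (1.0 + rel);
  for (int a = 0; a < 3; ++a) {
    double center = 0.5 * (lo[a] + hi[a]);
    o[a] = center - 0.5 * side;
    (void)pad;
  }
}

void oct_build_core(Octree &T, const double *x, const double *y,
                    const double *z, int n, int depth,
                    const double o[3], double side) {
  if (n < 1) stop("empty-tree error: need at least one position");
  if (depth < 1) stop("max_depth must be >= 1");
  T.depth = depth;
  T.o[0] = o[0]; T.o[1] = o[1]; T.o[2] = o[2];
  T.side = side;
  T.n = n;
  T.X.assign(x, x + n); T.Y.assign(y, y + n); T.Z.assign(z, z + n);
  std::vector<uint64_t> raw(n);
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) {
      double c = (a == 0 ? x[i] : (a == 1 ? y[i] : z[i]));
      if (c < o[a] || c > o[a] + side)
        stop("out-of-box error: position %d outside the root box", i + 1);
    }
    raw[i] = box_id_of(x[i], y[i], z[i], o, side, depth);
  }
  T.perm.resize(n);
  for (int i = 0; i < n; ++i) T.perm[i] = i;
  // sort by (id, original index): deterministic stable tie-break
  std::sort(T.perm.begin(), T.perm.end(), [&raw](int a, int b) {
    if (raw[a] != raw[b]) return raw[a] < raw[b];
    return a < b;
  });
  T.ids.resize(n);
  T.slot_of.assign(n, -1);
  for (int s = 0; s < n; ++s) {
    T.ids[s] = raw[T.perm[s]];
    T.slot_of[T.perm[s]] = s;
  }
  // per-level offset tables of occupied boxes
  T.lv_pre.assign(depth + 1, {});
  T.lv_start.assign(depth + 1, {});
  for (int k = 0; k <= depth; ++k) {
    int shift = 3 * (depth - k);
    uint64_t prev = 0;
    bool first = true;
    for (int s = 0; s < n; ++s) {
      uint64_t pre = T.ids[s] >> shift;
      if (first || pre != prev) {
        T.lv_pre[k].push_back(pre);
        T.lv_start[k].push_back(s);
        prev = pre;
        first = false;
      }
    }
    T.lv_start[k].push_back(n);
  }
  T.ndist = 0;
  T.nbox = 0;
}

// squared distance from point to axis-aligned box
static double box_point_d2(const double p[3], const double lo[3],
                           const double hi[3]) {
  double d2 = 0;
  for (int a = 0; a < 3; ++a) {
    if (p[a] < lo[a]) { double d = lo[a] - p[a]; d2 += d * d; }
    else if (p[a] > hi[a]) { double d = p[a] - hi[a]; d2 += d * d; }
  }
  return d2;
}

static void child_bounds(const double lo[3], const double hi[3], uint64_t oct,
                         double clo[3], double chi[3]) {
  for (int a = 0; a < 3; ++a) {
    double mid = 0.5 * (lo[a] + hi[a]);
    if ((oct >> (2 - a)) & 1) { clo[a] = mid; chi[a] = hi[a]; }
    else { clo[a] = lo[a]; chi[a] = mid; }
  }
}

static void neigh_rec(const Octree &T, int k, int j,
                      const double lo[3], const double hi[3],
                      const double p[3], double r2, std::vector<int> &out) {
  T.nbox++;
  if (box_point_d2(p, lo, hi) > r2) return;
  int s = T.lv_start[k][j], e = T.lv_start[k][j + 1];
  // small ranges are scanned directly: slots ascend left-to-right across the
  // children, so the visit order (hence the result) is unchanged
  if (k == T.depth || e - s <= 8) {
    for (int t = s; t < e; ++t) {
      int i = T.perm[t];
      T.ndist++;
      if (pair_dist2(p[0], p[1], p[2], T.X[i], T.Y[i], T.Z[i]) <= r2)
        out.push_back(i);
    }
    return;
  }
  uint64_t pre = T.lv_pre[k][j];
  const std::vector<uint64_t> &P = T.lv_pre[k + 1];
  size_t c0 = std::lower_bound(P.begin(), P.end(), pre << 3) - P.begin();
  for (size_t t = c0; t < P.size() && P[t] < ((pre + 1) << 3); ++t) {
    double clo[3], chi[3];
    child_bounds(lo, hi, P[t] & 7, clo, chi);
    neigh_rec(T, k + 1, (int)t, clo, chi, p, r2, out);
  }
}

void oct_neighbors(const Octree &T, const double p[3], double r,
                   std::vector<int> &out) {
  out.clear();
  if (r < 0) return;
  double lo[3] = {T.o[0], T.o[1], T.o[2]};
  double hi[3] = {T.o[0] + T.side, T.o[1] + T.side, T.o[2] + T.side};
  neigh_rec(T, 0, 0, lo, hi, p, r * r, out);
  std::sort(out.begin(), out.end());
}

static void near_rec(const Octree &T, int k, int j,
                     const double lo[3], const double hi[3],
                     const double p[3], int skip,
                     double &bd2, int &bidx) {
  T.nbox++;
  // descend on equality too: an equally distant particle with a smaller
  // original index may still improve the tie-break
  if (box_point_d2(p, lo, hi) > bd2) return;
  int s = T.lv_start[k][j], e = T.lv_start[k][j + 1];
  if (k == T.depth || e - s <= 8) {
    for (int t = s; t < e; ++t) {
      int i = T.perm[t];
      if (i == skip) continue;
      T.ndist++;
      double d2 = pair_dist2(p[0], p[1], p[2], T.X[i], T.Y[i], T.Z[i]);
      if (d2 < bd2 || (d2 == bd2 && i < bidx)) { bd2 = d2; bidx = i; }
    }
    return;
  }
  uint64_t pre = T.lv_pre[k][j];
  const std::vector<uint64_t> &P = T.lv_pre[k + 1];
  size_t c0 = std::lower_bound(P.begin(), P.end(), pre << 3) - P.begin();
  for (size_t t = c0; t < P.size() && P[t] < ((pre + 1) << 3); ++t) {
    double clo[3], chi[3];
    child_bounds(lo, hi, P[t] & 7, clo, chi);
    near_rec(T, k + 1, (int)t, clo, chi, p, skip, bd2, bidx);
  }
}

int oct_nearest(const Octree &T, const double p[3], double r,
                double &best_d2, int skip) {
  if (r < 0) return -1;
  double bd2 = r * r;
  int bidx = INT_MAX;
  double lo[3] = {T.o[0], T.o[1], T.o[2]};
  double hi[3] = {T.o[0] + T.side, T.o[1] + T.side, T.o[2] + T.side};
  near_rec(T, 0, 0, lo, hi, p, skip, bd2, bidx);
  if (bidx == INT_MAX) return -1;
  best_d2 = bd2;
  return bidx;
}

// ------------------------------------------------------------------ R API

// [[Rcpp::export]]
NumericVector cpp_box_id(NumericMatrix pos, int depth,
                         NumericVector origin, double side) {
  int n = pos.nrow();
  NumericVector out(n);
  double o[3] = {origin[0], origin[1], origin[2]};
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a)
      if (pos(i, a) < o[a] || pos(i, a) > o[a] + side)
        stop("out-of-box error: position %d outside the root box", i + 1);
    out[i] = (double)box_id_of(pos(i, 0), pos(i, 1), pos(i, 2), o, side, depth);
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_oct_build(NumericMatrix pos, int depth,
                   NumericVector origin, double side) {
  Octree *T = new Octree();
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double o[3] = {origin[0], origin[1], origin[2]};
  try {
    oct_build_core(*T, x.data(), y.data(), z.data(), n, depth, o, side);
  } catch (...) {
    delete T;
    throw;
  }
  XPtr<Octree> ptr(T, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_oct_info(SEXP tp) {
  XPtr<Octree> T(tp);
  int n = T->n;
  NumericVector ids(n);
  IntegerVector perm(n);
  for (int s = 0; s < n; ++s) { ids[s] = (double)T->ids[s]; perm[s] = T->perm[s] + 1; }
  return List::create(_["ids"] = ids, _["perm"] = perm,
                      _["depth"] = T->depth, _["n"] = n,
                      _["origin"] = NumericVector::create(T->o[0], T->o[1], T->o[2]),
                      _["side"] = T->side);
}

// [[Rcpp::export]]
List cpp_oct_index_dump(SEXP tp) {
  XPtr<Octree> T(tp);
  std::vector<int> lev;
  std::vector<double> pre;
  std::vector<int> from, to;
  for (int k = 0; k <= T->depth; ++k)
    for (size_t j = 0; j < T->lv_pre[k].size(); ++j) {
      lev.push_back(k);
      pre.push_back((double)T->lv_pre[k][j]);
      from.push_back(T->lv_start[k][j] + 1);
      to.push_back(T->lv_start[k][j + 1]);
    }
  return List::create(_["depth"] = wrap(lev), _["id"] = wrap(pre),
                      _["slot_from"] = wrap(from), _["slot_to"] = wrap(to));
}

// [[Rcpp::export]]
IntegerVector cpp_oct_neighbors(SEXP tp, NumericVector point, double r) {
  XPtr<Octree> T(tp);
  double p[3] = {point[0], point[1], point[2]};
  std::vector<int> out;
  oct_neighbors(*T, p, r, out);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_oct_nearest(SEXP tp, NumericVector point, double r) {
  XPtr<Octree> T(tp);
  double p[3] = {point[0], point[1], point[2]};
  double d2 = 0;
  int i = oct_nearest(*T, p, r, d2, -1);
  if (i < 0) return List::create(_["index"] = NA_INTEGER, _["distance"] = NA_REAL);
  return List::create(_["index"] = i + 1, _["distance"] = std::sqrt(d2));
}

// [[Rcpp::export]]
NumericVector cpp_oct_counters(SEXP tp) {
  XPtr<Octree> T(tp);
  return NumericVector::create(_["dist_evals"] = (double)T->ndist,
                               _["box_tests"] = (double)T->nbox);
}

// [[Rcpp::export]]
void cpp_oct_reset_counters(SEXP tp) {
  XPtr<Octree> T(tp);
  T->ndist = 0;
  T->nbox = 0;
}

// [[Rcpp::export]]
NumericVector cpp_bounding_cube(NumericMatrix pos, double rel) {
  int n = pos.nrow();
  if (n < 1) stop("empty-tree error: need at least one position");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double o[3], side;
  bounding_cube(x.data(), y.data(), z.data(), n, rel, o, side);
  return NumericVector::create(o[0], o[1], o[2], side);
}
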