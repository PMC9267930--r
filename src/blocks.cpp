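#include <Rcpp.h>
#include <cmath>
#include <climits>
#include <cstdint>
#include "octree.h"

using namespace Rcpp;

static const double HARTREE_EV = 27.211386245988;
static const double PI_ = 3.14159265358979323846;

// ---- keyed counter RNG (splitmix64): both SI implementations draw the same
// emission direction for the same (seed, step, electron), independently of
// any global RNG stream.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t v) { return (double)(v >> 11) * 0x1.0p-53; }

static void keyed_direction(uint64_t seed, int step, int electron,
                            double dir[3]) {
  uint64_t x = seed ^ ((uint64_t)(uint32_t)step << 32) ^ (uint64_t)(uint32_t)electron;
  x = x * 0x2545F4914F6CDD1DULL + 0x9E3779B97F4A7C15ULL;
  double u1 = u01(splitmix64(x));
  double u2 = u01(splitmix64(x));
  double ct = 2.0 * u1 - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * PI_ * u2;
  dir[0] = st * std::cos(ph);
  dir[1] = st * std::sin(ph);
  dir[2] = ct;
}

// Lotz-form impact-ionization cross section [bohr^2]; E, B in eV.
static inline double sigma_lotz(double E, double B, double N, double a) {
  if (E <= B || B <= 0 || N <= 0) return 0.0;
  return a * N * std::log(E / B) / (E * B);
}

// ------------------------------------------------------------------ SI block
//
// Electrons are processed in ascending index order against the pre-block atom
// snapshot.  Per electron: a target-independent search radius from the
// lab-frame kinetic energy and full-capacity orbital occupancies bounds the
// nearest-neighbor query; the nearest atom within it (tie-break: smallest
// atom index) is then evaluated with the pairwise relative-frame energy.
// brute scans every atom per electron (exactly Ne*Na distance evaluations);
// tree queries the oct-tree.  Both share pair_dist2 and the same update rule,
// so event lists and post-states are bit-wise identical.
// [[Rcpp::export]]
List cpp_si_block(NumericMatrix apos, NumericMatrix avel,
                  IntegerMatrix occ, NumericMatrix bind, IntegerMatrix cap,
                  IntegerVector charge,
                  NumericMatrix epos, NumericMatrix evel,
                  NumericVector glob_B, NumericVector glob_N,
                  double a_const, bool use_tree, int depth,
                  int step, double seed_key) {
  int na = apos.nrow(), ne = epos.nrow(), K = occ.ncol();
  IntegerMatrix occ2 = clone(occ);
  IntegerVector ch2 = clone(charge);
  NumericMatrix ev2 = clone(evel);
  std::vector<int> ev_e, ev_a, ev_orb;
  std::vector<double> nex, ney, nez, nvx, nvy, nvz;
  long long ndist = 0, nbox = 0;
  uint64_t seed = (uint64_t)seed_key;

  std::vector<double> ax(na), ay(na), az(na);
  for (int i = 0; i < na; ++i) { ax[i] = apos(i, 0); ay[i] = apos(i, 1); az[i] = apos(i, 2); }
  Octree T;
  if (use_tree && na > 0) {
    double o[3], side;
    bounding_cube(ax.data(), ay.data(), az.data(), na, 1e-6, o, side);
    oct_build_core(T, ax.data(), ay.data(), az.data(), na, depth, o, side);
  }

  int ng = glob_B.size();
  for (int e = 0; e < ne; ++e) {
    double ex = epos(e, 0), ey = epos(e, 1), ez = epos(e, 2);
    double vx = ev2(e, 0), vy = ev2(e, 1), vz = ev2(e, 2);
    // search radius: upper bound over the orbital table at full capacity
    double Elab = 0.5 * (vx * vx + vy * vy + vz * vz) * HARTREE_EV;
    double smax = 0;
    for (int g = 0; g < ng; ++g) {
      double s = sigma_lotz(Elab, glob_B[g], glob_N[g], a_const);
      if (s > smax) smax = s;
    }
    double rmax = (smax > 0) ? std::sqrt(smax / PI_) : 0.0;

    int best = -1;
    double bd2 = 0;
    if (use_tree) {
      if (na > 0 && rmax > 0) {
        double p[3] = {ex, ey, ez};
        best = oct_nearest(T, p, rmax, bd2, -1);
      }
    } else {
      // brute force: scan every atom (counter = Ne*Na by construction)
      double b2 = rmax * rmax;
      int bidx = INT_MAX;
      for (int a = 0; a < na; ++a) {
        ndist++;
        double d2 = pair_dist2(ex, ey, ez, ax[a], ay[a], az[a]);
        if (d2 < b2 || (d2 == b2 && a < bidx)) { b2 = d2; bidx = a; }
      }
      if (bidx != INT_MAX && rmax > 0) { best = bidx; bd2 = b2; }
    }
    if (best < 0) continue;

    // pairwise evaluation against the pre-block snapshot
    int a = best;
    double wx = vx - avel(a, 0), wy = vy - avel(a, 1), wz = vz - avel(a, 2);
    double vrel2 = wx * wx + wy * wy + wz * wz;
    double Erel = 0.5 * vrel2 * HARTREE_EV;
    double sbest = 0;
    int korb = -1;
    for (int k = 0; k < K; ++k) {
      if (cap(a, k) <= 0 || occ(a, k) <= 0) continue;
      double s = sigma_lotz(Erel, bind(a, k), (double)occ(a, k), a_const);
      if (s > sbest) { sbest = s; korb = k; }
    }
    if (korb < 0 || sbest <= 0) continue;
    if (bd2 > sbest / PI_) continue;        // d <= r_cut(E_rel)

    // apply (drop if a same-step event already emptied the orbital)
    if (occ2(a, korb) < 1) continue;
    occ2(a, korb) -= 1;
    ch2[a] += 1;
    double B = bind(a, korb);
    double avail = Erel - B;                // eV, >= 0 since Erel > B
    double Esec = std::min(0.1 * avail, 10.0);
    double Eprim = avail - Esec;
    double wnorm = std::sqrt(vrel2);
    double ux = wx / wnorm, uy = wy / wnorm, uz = wz / wnorm;
    double vprim = std::sqrt(2.0 * Eprim / HARTREE_EV);
    ev2(e, 0) = avel(a, 0) + ux * vprim;
    ev2(e, 1) = avel(a, 1) + uy * vprim;
    ev2(e, 2) = avel(a, 2) + uz * vprim;
    double dir[3];
    keyed_direction(seed, step, e, dir);
    double vsec = std::sqrt(2.0 * Esec / HARTREE_EV);
    nex.push_back(apos(a, 0) + 0.5 * dir[0]);
    ney.push_back(apos(a, 1) + 0.5 * dir[1]);
    nez.push_back(apos(a, 2) + 0.5 * dir[2]);
    nvx.push_back(avel(a, 0) + dir[0] * vsec);
    nvy.push_back(avel(a, 1) + dir[1] * vsec);
    nvz.push_back(avel(a, 2) + dir[2] * vsec);
    ev_e.push_back(e + 1);
    ev_a.push_back(a + 1);
    ev_orb.push_back(korb + 1);
  }

  if (use_tree) { ndist = T.ndist; nbox = T.nbox; }
  int m = (int)ev_e.size();
  IntegerMatrix events(m, 4);
  NumericMatrix npos(m, 3), nvel(m, 3);
  for (int i = 0; i < m; ++i) {
    events(i, 0) = step; events(i, 1) = ev_e[i];
    events(i, 2) = ev_a[i]; events(i, 3) = ev_orb[i];
    npos(i, 0) = nex[i]; npos(i, 1) = ney[i]; npos(i, 2) = nez[i];
    nvel(i, 0) = nvx[i]; nvel(i, 1) = nvy[i]; nvel(i, 2) = nvz[i];
  }
  return List::create(_["events"] = events, _["occ"] = occ2,
                      _["charge"] = ch2, _["evel"] = ev2,
                      _["new_epos"] = npos, _["new_evel"] = nvel,
                      _["dist_evals"] = (double)ndist,
                      _["box_tests"] = (double)nbox);
}

// ------------------------------------------------------------------ RE block
//
// Electrons in ascending order against the pre-block ion snapshot (atoms with
// charge >= 1).  Capture iff the nearest ion within r_rec forms a classically
// bound pair (0.5 * m_red * v_rel^2 - q_ion / r < 0) and has not already
// captured this step.  brute scans all ions per electron; tree queries an
// oct-tree over the ions only.  Bit-wise identical by the same construction
// as the SI block.
// [[Rcpp::export]]
List cpp_re_block(NumericMatrix apos, NumericMatrix avel, NumericVector amass,
                  IntegerMatrix occ, IntegerMatrix cap, IntegerVector charge,
                  NumericMatrix epos, NumericMatrix evel,
                  double r_rec, bool use_tree, int depth, int step) {
  int na = apos.nrow(), ne = epos.nrow(), K = occ.ncol();
  std::vector<int> ion;                    // ion subset, ascending atom index
  for (int a = 0; a < na; ++a) if (charge[a] >= 1) ion.push_back(a);
  int ni = (int)ion.size();
  IntegerMatrix occ2 = clone(occ);
  IntegerVector ch2 = clone(charge);
  LogicalVector removed(ne);
  std::vector<int> ev_e, ev_a;
  double energy = 0;                        // discarded electron KE [hartree]
  long long ndist = 0, nbox = 0;

  std::vector<double> ix(ni), iy(ni), iz(ni);
  for (int t = 0; t < ni; ++t) {
    ix[t] = apos(ion[t], 0); iy[t] = apos(ion[t], 1); iz[t] = apos(ion[t], 2);
  }
  Octree T;
  if (use_tree && ni > 0) {
    double o[3], side;
    bounding_cube(ix.data(), iy.data(), iz.data(), ni, 1e-6, o, side);
    oct_build_core(T, ix.data(), iy.data(), iz.data(), ni, depth, o, side);
  }

  std::vector<char> captured(ni, 0);       // at most one capture per ion
  for (int e = 0; e < ne; ++e) {
    if (ni == 0) break;
    double ex = epos(e, 0), ey = epos(e, 1), ez = epos(e, 2);
    int bt = -1;                            // subset index of nearest ion
    double bd2 = 0;
    if (use_tree) {
      double p[3] = {ex, ey, ez};
      bt = oct_nearest(T, p, r_rec, bd2, -1);
    } else {
      double b2 = r_rec * r_rec;
      int bidx = INT_MAX;
      for (int t = 0; t < ni; ++t) {
        ndist++;
        double d2 = pair_dist2(ex, ey, ez, ix[t], iy[t], iz[t]);
        if (d2 < b2 || (d2 == b2 && t < bidx)) { b2 = d2; bidx = t; }
      }
      if (bidx != INT_MAX) { bt = bidx; bd2 = b2; }
    }
    if (bt < 0 || captured[bt]) continue;
    int a = ion[bt];
    double wx = evel(e, 0) - avel(a, 0), wy = evel(e, 1) - avel(a, 1),
           wz = evel(e, 2) - avel(a, 2);
    double vrel2 = wx * wx + wy * wy + wz * wz;
    double mred = amass[a] / (1.0 + amass[a]);
    bool bound;
    if (bd2 <= 0) bound = true;
    else bound = (0.5 * mred * vrel2 - (double)charge[a] / std::sqrt(bd2)) < 0.0;
    if (!bound) continue;
    // capture: fill the outermost open orbital (lowest binding, i.e. the
    // highest orbital column with a vacancy)
    int korb = -1;
    for (int k = K - 1; k >= 0; --k)
      if (cap(a, k) > 0 && occ2(a, k) < cap(a, k)) { korb = k; break; }
    if (korb < 0)
      stop("bookkeeping error: capture onto a closed-shell configuration (atom %d)", a + 1);
    occ2(a, korb) += 1;
    ch2[a] -= 1;
    removed[e] = true;
    captured[bt] = 1;
    double v2 = evel(e, 0) * evel(e, 0) + evel(e, 1) * evel(e, 1) +
                evel(e, 2) * evel(e, 2);
    energy += 0.5 * v2;
    ev_e.push_back(e + 1);
    ev_a.push_back(a + 1);
  }

  if (use_tree) { ndist = T.ndist; nbox = T.nbox; }
  int m = (int)ev_e.size();
  IntegerMatrix events(m, 3);
  for (int i = 0; i < m; ++i) {
    events(i, 0) = step; events(i, 1) = ev_e[i]; events(i, 2) = ev_a[i];
  }
  return List::create(_["events"] = events, _["occ"] = occ2,
                      _["charge"] = ch2, _["removed"] = removed,
                      _["energy_discarded"] = energy,
                      _["n_ions"] = ni,
                      _["dist_evals"] = (double)ndist,
                      _["box_tests"] = (double)nbox);
}
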