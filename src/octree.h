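#ifndef RADDYN_OCTREE_H
#define RADDYN_OCTREE_H

#include <vector>
#include <cstdint>

// Linear (array-backed) oct-tree over particle positions.  Each particle gets
// a 3*depth-bit identifier: per level, 3 bits (x-high, y-high, z-high) chosen
// by the >=-midpoint convention, most significant level first.  Particles are
// stored as a permutation sorted by (id, original index); every box at every
// depth owns one contiguous slot range, recoverable from per-level offset
// tables of occupied-box prefixes.
struct Octree {
  int depth;
  double o[3];              // root box minimum corner
  double side;              // root box edge length (cube)
  int n;
  std::vector<double> X, Y, Z;            // positions in original index order
  std::vector<uint64_t> ids;              // sorted ascending
  std::vector<int> perm;                  // sorted slot -> original index
  std::vector<int> slot_of;               // original index -> sorted slot
  // per level k (0..depth): occupied-box prefixes (sorted) and slot offsets;
  // lv_start[k] has one extra trailing entry equal to n.
  std::vector<std::vector<uint64_t>> lv_pre;
  std::vector<std::vector<int>> lv_start;
  // query-work counters (point-particle distance evals; box-ball tests)
  mutable long long ndist, nbox;

  Octree() : depth(0), side(0), n(0), ndist(0), nbox(0) { o[0] = o[1] = o[2] = 0; }
};

// Shared squared-distance kernel.  Deliberately not inlined so that the
// brute-force scans and the tree searches round identically, which is what
// makes the cross-implementation bit-wise equivalence of the ionization
// blocks achievable.
double pair_dist2(double ax, double ay, double az,
                  double bx, double by, double bz);

uint64_t box_id_of(double x, double y, double z,
                   const double o[3], double side, int depth);

// Build over n positions; throws (Rcpp::stop) if any position lies outside
// the root box or n == 0.
void oct_build_core(Octree &T, const double *x, const double *y,
                    const double *z, int n, int depth,
                    const double o[3], double side);

// Tight bounding cube of positions, expanded by `rel` relative on each side.
void bounding_cube(const double *x, const double *y, const double *z, int n,
                   double rel, double o[3], double &side);

// All particles with distance <= r from p (original indices, ascending).
void oct_neighbors(const Octree &T, const double p[3], double r,
                   std::vector<int> &out);

// Closest particle with distance <= r from p; ties broken by smallest
// original index; `skip` (original index, or -1) is excluded.  Returns -1 if
// none.  best_d2 receives the squared distance.
int oct_nearest(const Octree &T, const double p[3], double r,
                double &best_d2, int skip);

#endif
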