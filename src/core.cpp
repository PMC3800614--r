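// Compiled kernels for FCC-lattice conformations: adjacency, self-avoidance,
// contact enumeration via an occupancy index, pull-move mechanics, and the
// exhaustive small-chain enumeration used as a test/optimality oracle.
#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <cstring>
using namespace Rcpp;

// The 12 FCC basis vectors, frozen in their canonical printed order.
// All "first successful move" scans use this order.
static const int BV[12][3] = {
  { 1,  1,  0}, {-1, -1,  0}, {-1,  1,  0}, { 1, -1,  0},
  { 0,  1,  1}, { 0,  1, -1}, { 1,  0,  1}, { 1,  0, -1},
  { 0, -1,  1}, {-1,  0,  1}, { 0, -1, -1}, {-1,  0, -1}
};

static inline bool adj3(int ax, int ay, int az, int bx, int by, int bz) {
  // FCC neighbours are exactly the displacements of squared norm 2 with
  // integer components (two +-1 components, one 0).
  const int dx = bx - ax, dy = by - ay, dz = bz - az;
  return dx * dx + dy * dy + dz * dz == 2;
}

static inline long long packpt(int x, int y, int z) {
  // Coordinates of chains anchored near the origin stay well inside 2^20.
  return (((long long)(x + 1048576)) << 42) |
         (((long long)(y + 1048576)) << 21) |
          ((long long)(z + 1048576));
}

// [[Rcpp::export]]
IntegerMatrix fcc_basis_cpp() {
  IntegerMatrix out(12, 3);
  for (int k = 0; k < 12; ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = BV[k][c];
  return out;
}

// [[Rcpp::export]]
bool is_saw_cpp(IntegerMatrix coords) {
  const int n = coords.nrow();
  if (coords.ncol() != 3) stop("coords must be an n x 3 matrix");
  std::unordered_set<long long> seen;
  seen.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    if (!seen.insert(packpt(coords(i, 0), coords(i, 1), coords(i, 2))).second)
      return false;
    if (i > 0 && !adj3(coords(i - 1, 0), coords(i - 1, 1), coords(i - 1, 2),
                       coords(i, 0), coords(i, 1), coords(i, 2)))
      return false;
  }
  return true;
}

// Non-consecutive lattice contacts (i, j), j > i + 1, 1-based, found by
// probing the 12 neighbour points of every residue in an occupancy map.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(IntegerMatrix coords) {
  const int n = coords.nrow();
  std::unordered_map<long long, int> occ;
  occ.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    occ[packpt(coords(i, 0), coords(i, 1), coords(i, 2))] = i;
  std::vector<std::pair<int, int> > pairs;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 12; ++k) {
      auto it = occ.find(packpt(coords(i, 0) + BV[k][0],
                                coords(i, 1) + BV[k][1],
                                coords(i, 2) + BV[k][2]));
      if (it != occ.end() && it->second > i + 1)
        pairs.push_back(std::make_pair(i + 1, it->second + 1));
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// Sum of emat[aa_i, aa_j] over non-consecutive contacts; aa is 1-based into
// the rows/cols of emat.
// [[Rcpp::export]]
double contact_energy_cpp(IntegerMatrix coords, IntegerVector aa,
                          NumericMatrix emat) {
  const int n = coords.nrow();
  if (aa.size() != n) stop("aa length must match coords");
  std::unordered_map<long long, int> occ;
  occ.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    occ[packpt(coords(i, 0), coords(i, 1), coords(i, 2))] = i;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 12; ++k) {
      auto it = occ.find(packpt(coords(i, 0) + BV[k][0],
                                coords(i, 1) + BV[k][1],
                                coords(i, 2) + BV[k][2]));
      if (it != occ.end() && it->second > i + 1)
        e += emat(aa[i] - 1, aa[it->second] - 1);
    }
  }
  return e;
}

// Free lattice points adjacent to both chain neighbours of residue i
// (1-based, interior), scanned in frozen basis order around residue i-1.
// [[Rcpp::export]]
IntegerMatrix diagonal_candidates_cpp(IntegerMatrix coords, int i) {
  const int n = coords.nrow();
  if (i < 2 || i > n - 1) stop("diagonal move needs an interior residue");
  std::unordered_set<long long> occ;
  occ.reserve(2 * n);
  for (int r = 0; r < n; ++r)
    occ.insert(packpt(coords(r, 0), coords(r, 1), coords(r, 2)));
  const int a = i - 2, c = i;  // 0-based chain neighbours of residue i
  std::vector<std::array<int, 3> > cand;
  for (int k = 0; k < 12; ++k) {
    const int x = coords(a, 0) + BV[k][0];
    const int y = coords(a, 1) + BV[k][1];
    const int z = coords(a, 2) + BV[k][2];
    if (!adj3(x, y, z, coords(c, 0), coords(c, 1), coords(c, 2))) continue;
    if (occ.count(packpt(x, y, z))) continue;
    cand.push_back({x, y, z});
  }
  IntegerMatrix out(cand.size(), 3);
  for (size_t r = 0; r < cand.size(); ++r)
    for (int cc = 0; cc < 3; ++cc) out(r, cc) = cand[r][cc];
  return out;
}

// ---------------------------------------------------------------------------
// Pull moves.
//
// dir = +1: the bond towards the successor is (re-)established at the target
//           and predecessors are dragged along vacated positions;
// dir = -1: symmetric, successors are dragged.
// End residues admit both a simple relocation (target adjacent to the
// penultimate residue) and a dragging pull (target adjacent to the end
// residue itself). By construction every feasible pull yields a
// self-avoiding walk: dragged residues reuse only positions vacated by the
// chain itself and the target is required to be free.
// ---------------------------------------------------------------------------

template <class OCC>
static int apply_pull_core(const int* X, const int* Y, const int* Z, int n,
                           int i /*0-based*/, int tx, int ty, int tz, int dir,
                           const OCC& occupied,
                           int* OX, int* OY, int* OZ, int* mOut) {
  if (occupied(tx, ty, tz)) return 0;
  if (dir == 1) {
    if (i == 0) {
      if (!adj3(tx, ty, tz, X[1], Y[1], Z[1])) return 0;
    } else if (i < n - 1) {
      if (!adj3(tx, ty, tz, X[i + 1], Y[i + 1], Z[i + 1])) return 0;
      if (!adj3(tx, ty, tz, X[i], Y[i], Z[i])) return 0;
    } else {
      if (!adj3(tx, ty, tz, X[n - 1], Y[n - 1], Z[n - 1])) return 0;
    }
    std::memcpy(OX, X, n * sizeof(int));
    std::memcpy(OY, Y, n * sizeof(int));
    std::memcpy(OZ, Z, n * sizeof(int));
    OX[i] = tx; OY[i] = ty; OZ[i] = tz;
    int m = i;
    for (int j = i - 1; j >= 0; --j) {
      if (adj3(X[j], Y[j], Z[j], OX[j + 1], OY[j + 1], OZ[j + 1])) break;
      OX[j] = X[j + 1]; OY[j] = Y[j + 1]; OZ[j] = Z[j + 1];
      m = j;
    }
    *mOut = m;
    return 1;
  }
  if (dir == -1) {
    if (i == n - 1) {
      if (!adj3(tx, ty, tz, X[n - 2], Y[n - 2], Z[n - 2])) return 0;
    } else if (i > 0) {
      if (!adj3(tx, ty, tz, X[i - 1], Y[i - 1], Z[i - 1])) return 0;
      if (!adj3(tx, ty, tz, X[i], Y[i], Z[i])) return 0;
    } else {
      if (!adj3(tx, ty, tz, X[0], Y[0], Z[0])) return 0;
    }
    std::memcpy(OX, X, n * sizeof(int));
    std::memcpy(OY, Y, n * sizeof(int));
    std::memcpy(OZ, Z, n * sizeof(int));
    OX[i] = tx; OY[i] = ty; OZ[i] = tz;
    int m = i;
    for (int j = i + 1; j < n; ++j) {
      if (adj3(X[j], Y[j], Z[j], OX[j - 1], OY[j - 1], OZ[j - 1])) break;
      OX[j] = X[j - 1]; OY[j] = Y[j - 1]; OZ[j] = Z[j - 1];
      m = j;
    }
    *mOut = m;
    return 1;
  }
  return 0;
}

struct LinOcc {
  const int *X, *Y, *Z;
  int n;
  bool operator()(int x, int y, int z) const {
    for (int i = 0; i < n; ++i)
      if (X[i] == x && Y[i] == y && Z[i] == z) return true;
    return false;
  }
};

struct HashOcc {
  const std::unordered_set<long long>* s;
  bool operator()(int x, int y, int z) const {
    return s->count(packpt(x, y, z)) > 0;
  }
};

// dir: 0 = auto (+1 preferred), +1, -1.
// [[Rcpp::export]]
List pull_move_cpp(IntegerMatrix coords, int i, IntegerVector target, int dir) {
  const int n = coords.nrow();
  if (n < 2) stop("pull move needs at least 2 residues");
  if (i < 1 || i > n) stop("residue index out of range");
  if (target.size() != 3) stop("target must be length 3");
  std::vector<int> X(n), Y(n), Z(n), OX(n), OY(n), OZ(n);
  std::unordered_set<long long> occ;
  occ.reserve(2 * n);
  for (int r = 0; r < n; ++r) {
    X[r] = coords(r, 0); Y[r] = coords(r, 1); Z[r] = coords(r, 2);
    occ.insert(packpt(X[r], Y[r], Z[r]));
  }
  HashOcc ho{&occ};
  int m = -1, used = 0;
  for (int d : {1, -1}) {
    if (dir != 0 && dir != d) continue;
    if (apply_pull_core(X.data(), Y.data(), Z.data(), n, i - 1,
                        target[0], target[1], target[2], d, ho,
                        OX.data(), OY.data(), OZ.data(), &m)) {
      used = d;
      break;
    }
  }
  if (used == 0)
    return List::create(_["feasible"] = false);
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    out(r, 0) = OX[r]; out(r, 1) = OY[r]; out(r, 2) = OZ[r];
  }
  // moved segment (1-based, inclusive) between the pulled residue and the
  // last dragged residue
  const int lo = std::min(i, m + 1), hi = std::max(i, m + 1);
  return List::create(_["feasible"] = true, _["coords"] = out,
                      _["dir"] = used, _["from"] = lo, _["to"] = hi);
}

// All feasible (target, dir) pairs for a pull at residue i, in frozen order:
// dir +1 targets first, each scanned in basis order around the relevant
// centre point. Columns: x, y, z, dir.
// [[Rcpp::export]]
IntegerMatrix pull_targets_cpp(IntegerMatrix coords, int i) {
  const int n = coords.nrow();
  if (n < 2) stop("pull move needs at least 2 residues");
  if (i < 1 || i > n) stop("residue index out of range");
  std::unordered_set<long long> occ;
  occ.reserve(2 * n);
  for (int r = 0; r < n; ++r)
    occ.insert(packpt(coords(r, 0), coords(r, 1), coords(r, 2)));
  const int i0 = i - 1;
  std::vector<std::array<int, 4> > cand;
  for (int d : {1, -1}) {
    // centre around which candidate targets are scanned
    int cx, cy, cz;
    if (d == 1) {
      const int c = (i0 == 0) ? 1 : ((i0 == n - 1) ? n - 1 : i0);
      cx = coords(c, 0); cy = coords(c, 1); cz = coords(c, 2);
    } else {
      const int c = (i0 == n - 1) ? n - 2 : ((i0 == 0) ? 0 : i0);
      cx = coords(c, 0); cy = coords(c, 1); cz = coords(c, 2);
    }
    for (int k = 0; k < 12; ++k) {
      const int x = cx + BV[k][0], y = cy + BV[k][1], z = cz + BV[k][2];
      if (occ.count(packpt(x, y, z))) continue;
      if (d == 1 && i0 > 0 && i0 < n - 1 &&
          !adj3(x, y, z, coords(i0 + 1, 0), coords(i0 + 1, 1), coords(i0 + 1, 2)))
        continue;
      if (d == -1 && i0 > 0 && i0 < n - 1 &&
          !adj3(x, y, z, coords(i0 - 1, 0), coords(i0 - 1, 1), coords(i0 - 1, 2)))
        continue;
      cand.push_back({x, y, z, d});
    }
  }
  IntegerMatrix out(cand.size(), 4);
  for (size_t r = 0; r < cand.size(); ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = cand[r][c];
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration of self-avoiding walks. The first step is frozen to
// basis vector v1 for n >= 2: the FCC point group acts transitively on the
// 12 basis vectors, so energies and optima are unaffected by the quotient.
// ---------------------------------------------------------------------------

struct SawEnum {
  int n, L, dim;
  std::vector<short> grid;  // residue index + 1, 0 = free
  std::vector<int> X, Y, Z;
  double count;

  explicit SawEnum(int n_) : n(n_), L(n_), dim(2 * n_ + 1),
      grid((size_t)dim * dim * dim, 0), X(n_), Y(n_), Z(n_), count(0.0) {}

  inline size_t gi(int x, int y, int z) const {
    return ((size_t)(x + L) * dim + (y + L)) * dim + (z + L);
  }

  template <class LEAF>
  void grow(int k, LEAF& leaf) {
    if (k == n) {
      count += 1.0;
      leaf(*this);
      return;
    }
    if (k == 1) {  // frozen first step
      X[1] = X[0] + 1; Y[1] = Y[0] + 1; Z[1] = Z[0];
      grid[gi(X[1], Y[1], Z[1])] = 2;
      grow(2, leaf);
      grid[gi(X[1], Y[1], Z[1])] = 0;
      return;
    }
    for (int v = 0; v < 12; ++v) {
      const int x = X[k - 1] + BV[v][0];
      const int y = Y[k - 1] + BV[v][1];
      const int z = Z[k - 1] + BV[v][2];
      const size_t g = gi(x, y, z);
      if (grid[g]) continue;
      X[k] = x; Y[k] = y; Z[k] = z;
      grid[g] = (short)(k + 1);
      grow(k + 1, leaf);
      grid[g] = 0;
    }
  }

  template <class LEAF>
  void run(LEAF& leaf) {
    X[0] = Y[0] = Z[0] = 0;
    grid[gi(0, 0, 0)] = 1;
    if (n == 1) { count = 1.0; leaf(*this); return; }
    grow(1, leaf);
  }
};

// [[Rcpp::export]]
double count_saws_cpp(int n) {
  if (n < 1 || n > 10) stop("n must be in 1..10");
  SawEnum e(n);
  auto leaf = [](SawEnum&) {};
  e.run(leaf);
  return e.count;
}

// [[Rcpp::export]]
List enumerate_saws_cpp(int n) {
  if (n < 1 || n > 10) stop("n must be in 1..10");
  std::vector<IntegerMatrix> walks;
  SawEnum e(n);
  auto leaf = [&](SawEnum& s) {
    IntegerMatrix m(s.n, 3);
    for (int r = 0; r < s.n; ++r) {
      m(r, 0) = s.X[r]; m(r, 1) = s.Y[r]; m(r, 2) = s.Z[r];
    }
    walks.push_back(m);
  };
  e.run(leaf);
  List out(walks.size());
  for (size_t r = 0; r < walks.size(); ++r) out[r] = walks[r];
  return out;
}

// Exact global minimum contact energy over all SAWs of the sequence length,
// with the contact energy maintained incrementally during growth.
// [[Rcpp::export]]
List global_minimum_cpp(IntegerVector aa, NumericMatrix emat) {
  const int n = aa.size();
  if (n < 1 || n > 10) stop("sequence length must be in 1..10");
  SawEnum e(n);
  std::vector<double> epart(n + 1, 0.0);  // energy after placing residue k
  double best = R_PosInf;
  IntegerMatrix bestCoords(n, 3);
  bool have = false;

  // wrap grow() manually to thread the incremental energy
  std::function<void(int)> grow = [&](int k) {
    if (k == n) {
      e.count += 1.0;
      if (!have || epart[n] < best) {
        best = epart[n];
        have = true;
        for (int r = 0; r < n; ++r) {
          bestCoords(r, 0) = e.X[r];
          bestCoords(r, 1) = e.Y[r];
          bestCoords(r, 2) = e.Z[r];
        }
      }
      return;
    }
    const int vlo = (k == 1) ? 0 : 0, vhi = (k == 1) ? 1 : 12;
    for (int v = vlo; v < vhi; ++v) {
      const int x = e.X[k - 1] + BV[v][0];
      const int y = e.Y[k - 1] + BV[v][1];
      const int z = e.Z[k - 1] + BV[v][2];
      const size_t g = e.gi(x, y, z);
      if (e.grid[g]) continue;
      double de = 0.0;
      for (int w = 0; w < 12; ++w) {
        const short o = e.grid[e.gi(x + BV[w][0], y + BV[w][1], z + BV[w][2])];
        if (o && o - 1 < k - 1) de += emat(aa[o - 1] - 1, aa[k] - 1);
      }
      e.X[k] = x; e.Y[k] = y; e.Z[k] = z;
      e.grid[g] = (short)(k + 1);
      epart[k + 1] = epart[k] + de;
      grow(k + 1);
      e.grid[g] = 0;
    }
  };

  e.X[0] = e.Y[0] = e.Z[0] = 0;
  e.grid[e.gi(0, 0, 0)] = 1;
  epart[1] = 0.0;
  if (n == 1) {
    e.count = 1.0;
    best = 0.0;
    bestCoords(0, 0) = bestCoords(0, 1) = bestCoords(0, 2) = 0;
  } else {
    grow(1);
  }
  return List::create(_["count"] = e.count, _["min_energy"] = best,
                      _["coords"] = bestCoords);
}

// ---------------------------------------------------------------------------
// Exhaustive pull-move reversibility scan: for every first-step-canonical
// SAW of length n, every feasible pull (site x target x direction) is
// applied, and the inverse move space is searched for a pull restoring the
// original walk. Returns counts: walks, feasible pulls, pulls with a found
// inverse.
// ---------------------------------------------------------------------------

static bool same_coords(const int* AX, const int* AY, const int* AZ,
                        const int* BX, const int* BY, const int* BZ, int n) {
  for (int r = 0; r < n; ++r)
    if (AX[r] != BX[r] || AY[r] != BY[r] || AZ[r] != BZ[r]) return false;
  return true;
}

// [[Rcpp::export]]
NumericVector pull_reversibility_scan_cpp(int n) {
  if (n < 2 || n > 8) stop("n must be in 2..8");
  double walks = 0.0, pulls = 0.0, reversed = 0.0;
  std::vector<int> c1x(n), c1y(n), c1z(n), c2x(n), c2y(n), c2z(n);

  SawEnum e(n);
  auto leaf = [&](SawEnum& s) {
    walks += 1.0;
    const int* X = s.X.data();
    const int* Y = s.Y.data();
    const int* Z = s.Z.data();
    struct GridOcc {
      const SawEnum* s;
      bool operator()(int x, int y, int z) const {
        if (x < -s->L || x > s->L || y < -s->L || y > s->L ||
            z < -s->L || z > s->L) return false;
        return s->grid[s->gi(x, y, z)] != 0;
      }
    } gocc{&s};
    LinOcc occ1{c1x.data(), c1y.data(), c1z.data(), n};

    for (int i0 = 0; i0 < n; ++i0) {
      for (int d : {1, -1}) {
        // candidate targets in the same frozen order as pull_targets_cpp
        int c;
        if (d == 1) c = (i0 == 0) ? 1 : ((i0 == n - 1) ? n - 1 : i0);
        else        c = (i0 == n - 1) ? n - 2 : ((i0 == 0) ? 0 : i0);
        for (int k = 0; k < 12; ++k) {
          const int tx = X[c] + BV[k][0];
          const int ty = Y[c] + BV[k][1];
          const int tz = Z[c] + BV[k][2];
          int m;
          if (!apply_pull_core(X, Y, Z, n, i0, tx, ty, tz, d, gocc,
                               c1x.data(), c1y.data(), c1z.data(), &m))
            continue;
          pulls += 1.0;
          // predicted inverse: pull the far end of the moved segment back
          // to its old position with the opposite direction
          bool ok = false;
          int m2;
          if (apply_pull_core(c1x.data(), c1y.data(), c1z.data(), n, m,
                              X[m], Y[m], Z[m], -d, occ1,
                              c2x.data(), c2y.data(), c2z.data(), &m2) &&
              same_coords(c2x.data(), c2y.data(), c2z.data(), X, Y, Z, n))
            ok = true;
          if (!ok) {
            // full search of the inverse move space
            for (int j0 = 0; j0 < n && !ok; ++j0) {
              for (int d2 : {1, -1}) {
                if (ok) break;
                int c2;
                if (d2 == 1) c2 = (j0 == 0) ? 1 : ((j0 == n - 1) ? n - 1 : j0);
                else         c2 = (j0 == n - 1) ? n - 2 : ((j0 == 0) ? 0 : j0);
                for (int k2 = 0; k2 < 12; ++k2) {
                  if (!apply_pull_core(c1x.data(), c1y.data(), c1z.data(), n,
                                       j0, c1x[c2] + BV[k2][0],
                                       c1y[c2] + BV[k2][1],
                                       c1z[c2] + BV[k2][2], d2, occ1,
                                       c2x.data(), c2y.data(), c2z.data(), &m2))
                    continue;
                  if (same_coords(c2x.data(), c2y.data(), c2z.data(),
                                  X, Y, Z, n)) { ok = true; break; }
                }
              }
            }
          }
          if (ok) reversed += 1.0;
        }
      }
    }
  };
  e.run(leaf);
  return NumericVector::create(_["walks"] = walks, _["pulls"] = pulls,
                               _["reversed"] = reversed);
}
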