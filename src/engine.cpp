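// Bond-fluctuation Monte Carlo engine.
//
// Geometry: each node occupies the 8 vertices of a unit cube anchored at its
// lattice coordinate; excluded volume = no two cubes share a vertex, i.e. all
// anchor pairs differ by >= 2 in Chebyshev (max-norm) distance.  Bonds between
// consecutive nodes have squared length in {4,5,6,9,10}.
//
// Energetics: U(eps, r) = |eps| (sigma/r)^12 + eps (sigma/r)^6, sigma = 1,
// truncated at r_c = sqrt(8).  Residue-residue couplings eps_ij from a 20x20
// contact matrix (bonded neighbours excluded); residue-solvent couplings
// fs * eps_i summed over *empty* lattice sites within r_c of the anchor.
// Writing [site empty] = 1 - [site occupied] turns the solvent sum into a
// per-type constant minus short-ranged anchor-anchor "blocking" terms B_t(d)
// (the part of node k's cube footprint that intrudes into node j's shell),
// which makes the Metropolis energy difference a pure neighbour-table scan.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- PCG32 RNG
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform integer in [0, n)
  uint32_t bounded(uint32_t n) { return (uint32_t)(((uint64_t)next() * n) >> 32); }
  double unif() { return next() * 2.3283064365386963e-10; } // [0,1)
};

// ------------------------------------------------------------- basic tables
static const int BOND2[5] = {4, 5, 6, 9, 10};

static inline bool bond_ok(int dx, int dy, int dz) {
  int r2 = dx * dx + dy * dy + dz * dz;
  return r2 == 4 || r2 == 5 || r2 == 6 || r2 == 9 || r2 == 10;
}

static inline double pot(double eps, int r2) {
  if (r2 <= 0 || r2 > 8) return 0.0;
  double x = 1.0 / (double)r2;      // (sigma^2 / r^2)
  double x3 = x * x * x;
  return std::fabs(eps) * x3 * x3 + eps * x3;
}

// admissible bond vectors (|d|^2 in {4,5,6,9,10}), 108 of them
static std::vector<std::array<int,3>> bond_vector_set() {
  std::vector<std::array<int,3>> v;
  for (int x = -3; x <= 3; ++x)
    for (int y = -3; y <= 3; ++y)
      for (int z = -3; z <= 3; ++z)
        if (bond_ok(x, y, z)) v.push_back({x, y, z});
  return v;
}

// [[Rcpp::export]]
IntegerMatrix cpp_bond_vectors() {
  auto v = bond_vector_set();
  IntegerMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i)
    for (int c = 0; c < 3; ++c) m(i, c) = v[i][c];
  return m;
}

// interaction shell: offsets with 0 < |o|^2 <= 8 (92 of them)
// [[Rcpp::export]]
IntegerMatrix cpp_shell_offsets() {
  std::vector<std::array<int,3>> v;
  for (int x = -2; x <= 2; ++x)
    for (int y = -2; y <= 2; ++y)
      for (int z = -2; z <= 2; ++z) {
        int r2 = x * x + y * y + z * z;
        if (r2 > 0 && r2 <= 8) v.push_back({x, y, z});
      }
  IntegerMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i)
    for (int c = 0; c < 3; ++c) m(i, c) = v[i][c];
  return m;
}

// ------------------------------------------------------------------- system
struct System {
  int L, N;
  std::vector<int> tx, ty, tz;      // wrapped anchors
  std::vector<int> ux, uy, uz;      // unwrapped anchors
  std::vector<int> type;            // residue type 0..19 per node
  std::vector<int> grid;            // L^3, 0 = empty, node index + 1

  int wrap(int a) const { int r = a % L; return r < 0 ? r + L : r; }
  size_t gidx(int x, int y, int z) const {
    return ((size_t)z * L + y) * L + x;
  }
  int at(int x, int y, int z) const {
    return grid[gidx(wrap(x), wrap(y), wrap(z))];
  }
  void place(int k) { grid[gidx(tx[k], ty[k], tz[k])] = k + 1; }
  void clearpos(int k) { grid[gidx(tx[k], ty[k], tz[k])] = 0; }
};

// interaction model with precomputed neighbour tables
struct Model {
  double fs, T;
  std::vector<double> epsPair;      // 20x20
  std::vector<double> epsSolv;     // 20
  // combined neighbour offsets (pair + solvent-blocking support)
  std::vector<int> ox, oy, oz, or2; // or2 = |o|^2 if <= 8 else 0
  std::vector<double> Bplus;        // [t * M + m] = B_t(o_m)
  std::vector<double> Bminus;       // [t * M + m] = B_t(-o_m)
  std::vector<double> pairU;        // [(ti*20+tj)*9 + r2]
  std::vector<double> Cc;           // per-type solvent constant C_t - D_t
  int M;

  double Bt(double eps, int dx, int dy, int dz) const {
    double s = 0.0;
    for (int a = 0; a <= 1; ++a)
      for (int b = 0; b <= 1; ++b)
        for (int c = 0; c <= 1; ++c) {
          int x = dx + a, y = dy + b, z = dz + c;
          int r2 = x * x + y * y + z * z;
          if (r2 > 0 && r2 <= 8) s += pot(eps, r2);
        }
    return s;
  }

  void build(const NumericMatrix& ep, const NumericVector& es,
             double fs_, double T_) {
    fs = fs_; T = T_;
    epsPair.assign(400, 0.0);
    for (int i = 0; i < 20; ++i)
      for (int j = 0; j < 20; ++j) epsPair[i * 20 + j] = ep(i, j);
    epsSolv.assign(es.begin(), es.end());

    // pair potential lookup, slots indexed by r2 - 4 (r2 = 7 never occurs)
    pairU.assign(400 * 9, 0.0);
    for (int i = 0; i < 20; ++i)
      for (int j = 0; j < 20; ++j)
        for (int r2 = 4; r2 <= 8; ++r2)
          pairU[(i * 20 + j) * 9 + (r2 - 4)] = pot(epsPair[i * 20 + j], r2);

    // per-type solvent constant: full shell minus own-footprint blocking
    Cc.assign(20, 0.0);
    for (int t = 0; t < 20; ++t) {
      double e = fs * epsSolv[t], C = 0.0, D = 0.0;
      for (int x = -2; x <= 2; ++x)
        for (int y = -2; y <= 2; ++y)
          for (int z = -2; z <= 2; ++z) {
            int r2 = x * x + y * y + z * z;
            if (r2 > 0 && r2 <= 8) C += pot(e, r2);
          }
      for (int a = 0; a <= 1; ++a)
        for (int b = 0; b <= 1; ++b)
          for (int c = 0; c <= 1; ++c) {
            int r2 = a + b + c;
            if (r2 > 0) D += pot(e, r2);
          }
      Cc[t] = C - D;
    }

    // combined offset list
    ox.clear(); oy.clear(); oz.clear(); or2.clear();
    bool solvent_on = (fs != 0.0);
    for (int x = -3; x <= 3; ++x)
      for (int y = -3; y <= 3; ++y)
        for (int z = -3; z <= 3; ++z) {
          if (!x && !y && !z) continue;
          int r2 = x * x + y * y + z * z;
          bool pair_ok = (r2 >= 4 && r2 <= 8 && r2 != 7);
          bool bsup = false;
          if (solvent_on)
            for (int s = 0; s < 2 && !bsup; ++s) {
              int sx = s ? -x : x, sy = s ? -y : y, sz = s ? -z : z;
              for (int a = 0; a <= 1 && !bsup; ++a)
                for (int b = 0; b <= 1 && !bsup; ++b)
                  for (int c = 0; c <= 1 && !bsup; ++c) {
                    int q2 = (sx + a) * (sx + a) + (sy + b) * (sy + b) +
                             (sz + c) * (sz + c);
                    if (q2 > 0 && q2 <= 8) bsup = true;
                  }
            }
          if (pair_ok || bsup) {
            ox.push_back(x); oy.push_back(y); oz.push_back(z);
            or2.push_back(pair_ok ? r2 : 0);
          }
        }
    M = (int)ox.size();
    Bplus.assign(20 * M, 0.0);
    Bminus.assign(20 * M, 0.0);
    for (int t = 0; t < 20; ++t) {
      double e = fs * epsSolv[t];
      for (int m = 0; m < M; ++m) {
        Bplus[t * M + m]  = Bt(e,  ox[m],  oy[m],  oz[m]);
        Bminus[t * M + m] = Bt(e, -ox[m], -oy[m], -oz[m]);
      }
    }
  }
};

// node-level energy E_n: pair terms (non-bonded) + solvent shell of node n
static double node_energy(const System& S, const Model& Mo, int n,
                          double* pair_part = nullptr) {
  int tn = S.type[n];
  double ep = 0.0, bsum = 0.0;
  for (int m = 0; m < Mo.M; ++m) {
    int v = S.at(S.tx[n] + Mo.ox[m], S.ty[n] + Mo.oy[m], S.tz[n] + Mo.oz[m]);
    if (!v) continue;
    int j = v - 1;
    if (j == n) continue;
    if (Mo.or2[m] && j != n - 1 && j != n + 1)
      ep += Mo.pairU[(S.type[j] * 20 + tn) * 9 + (Mo.or2[m] - 4)];
    bsum += Mo.Bplus[tn * Mo.M + m];
  }
  if (pair_part) *pair_part = ep;
  return ep + Mo.Cc[tn] - bsum;
}

// full-system energy: pairs counted once + all solvent shells
static double total_energy(const System& S, const Model& Mo) {
  double e = 0.0;
  for (int n = 0; n < S.N; ++n) {
    double pp = 0.0;
    double en = node_energy(S, Mo, n, &pp);
    e += en - 0.5 * pp;
  }
  return e;
}

// incremental energy difference for moving node k to wrapped position b
// (assumes geometric legality already established; grid still holds k at a)
static double delta_energy_move(const System& S, const Model& Mo, int k,
                                int bx, int by, int bz) {
  int tk = S.type[k];
  double dE = 0.0;
  const int px[2] = {S.tx[k], bx}, py[2] = {S.ty[k], by}, pz[2] = {S.tz[k], bz};
  const double sgn[2] = {-1.0, 1.0};
  for (int s = 0; s < 2; ++s) {
    double acc = 0.0;
    for (int m = 0; m < Mo.M; ++m) {
      int v = S.at(px[s] + Mo.ox[m], py[s] + Mo.oy[m], pz[s] + Mo.oz[m]);
      if (!v) continue;
      int j = v - 1;
      if (j == k) continue;
      double term = -Mo.Bminus[S.type[j] * Mo.M + m] - Mo.Bplus[tk * Mo.M + m];
      if (Mo.or2[m] && j != k - 1 && j != k + 1)
        term += Mo.pairU[(S.type[j] * 20 + tk) * 9 + (Mo.or2[m] - 4)];
      acc += term;
    }
    dE += sgn[s] * acc;
  }
  return dE;
}

// excluded volume for a unit move along axis/dir: the 9 anchor sites in the
// advancing plane two ahead of the new position must be free
static bool ev_ok_move(const System& S, int k, int dx, int dy, int dz,
                       int bx, int by, int bz) {
  if (dx != 0) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        if (S.at(bx + dx, by + a, bz + b)) return false;
  } else if (dy != 0) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        if (S.at(bx + a, by + dy, bz + b)) return false;
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        if (S.at(bx + a, by + b, bz + dz)) return false;
  }
  (void)k;
  return true;
}

// general excluded-volume check of position (x,y,z) for node k
static bool ev_ok_general(const System& S, int k, int x, int y, int z) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int v = S.at(x + a, y + b, z + c);
        if (v && v != k + 1) return false;
      }
  return true;
}

static bool bonds_ok_at(const System& S, int k, int ux_, int uy_, int uz_,
                        bool use_unwrapped) {
  // bond vectors from unwrapped coordinates (exact, no image ambiguity)
  for (int d = -1; d <= 1; d += 2) {
    int j = k + d;
    if (j < 0 || j >= S.N) continue;
    int dx, dy, dz;
    if (use_unwrapped) {
      dx = S.ux[j] - ux_; dy = S.uy[j] - uy_; dz = S.uz[j] - uz_;
    } else {
      dx = S.tx[j] - ux_; dy = S.ty[j] - uy_; dz = S.tz[j] - uz_;
      int L = S.L;
      dx %= L; if (dx > L / 2) dx -= L; if (dx < -L / 2) dx += L;
      dy %= L; if (dy > L / 2) dy -= L; if (dy < -L / 2) dy += L;
      dz %= L; if (dz > L / 2) dz -= L; if (dz < -L / 2) dz += L;
    }
    if (!bond_ok(dx, dy, dz)) return false;
  }
  return true;
}

// full-state audit: bonds, excluded volume, grid consistency
static bool audit_geometry(const System& S) {
  int cnt = 0;
  for (size_t i = 0; i < S.grid.size(); ++i) if (S.grid[i]) ++cnt;
  if (cnt != S.N) return false;
  for (int k = 0; k < S.N; ++k) {
    if (S.grid[S.gidx(S.tx[k], S.ty[k], S.tz[k])] != k + 1) return false;
    if (S.wrap(S.ux[k]) != S.tx[k] || S.wrap(S.uy[k]) != S.ty[k] ||
        S.wrap(S.uz[k]) != S.tz[k]) return false;
    if (!bonds_ok_at(S, k, S.ux[k], S.uy[k], S.uz[k], true)) return false;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int v = S.at(S.tx[k] + a, S.ty[k] + b, S.tz[k] + c);
          if (v && v != k + 1) return false;
        }
  }
  return true;
}

static System make_system(int L, const IntegerVector& type,
                          const IntegerMatrix& wrapped,
                          const IntegerMatrix& unwrapped) {
  System S;
  S.L = L; S.N = type.size();
  S.type.assign(type.begin(), type.end());
  S.tx.resize(S.N); S.ty.resize(S.N); S.tz.resize(S.N);
  S.ux.resize(S.N); S.uy.resize(S.N); S.uz.resize(S.N);
  S.grid.assign((size_t)L * L * L, 0);
  for (int k = 0; k < S.N; ++k) {
    S.tx[k] = S.wrap(wrapped(k, 0)); S.ty[k] = S.wrap(wrapped(k, 1));
    S.tz[k] = S.wrap(wrapped(k, 2));
    S.ux[k] = unwrapped(k, 0); S.uy[k] = unwrapped(k, 1);
    S.uz[k] = unwrapped(k, 2);
    if (S.grid[S.gidx(S.tx[k], S.ty[k], S.tz[k])])
      stop("invalid state: two nodes share an anchor site");
    S.place(k);
  }
  return S;
}

// --------------------------------------------------------- chain initializer
// random self-avoiding growth with admissible bond vectors; restarts on dead
// ends.  Returns wrapped + unwrapped anchors.
// [[Rcpp::export]]
List cpp_init_chain(int L, int N, int seed, int max_restarts = 10000,
                    int tries_per_node = 200) {
  if (L < 8) stop("lattice edge L must be at least 8");
  Pcg32 rng((uint64_t)seed, 0x853c49e6748fea9bULL);
  auto bonds = bond_vector_set();
  System S;
  S.L = L; S.N = N;
  S.tx.resize(N); S.ty.resize(N); S.tz.resize(N);
  S.ux.resize(N); S.uy.resize(N); S.uz.resize(N);
  S.type.assign(N, 0);
  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    S.grid.assign((size_t)L * L * L, 0);
    S.ux[0] = rng.bounded(L); S.uy[0] = rng.bounded(L);
    S.uz[0] = rng.bounded(L);
    S.tx[0] = S.wrap(S.ux[0]); S.ty[0] = S.wrap(S.uy[0]);
    S.tz[0] = S.wrap(S.uz[0]);
    S.place(0);
    bool ok = true;
    for (int k = 1; k < N && ok; ++k) {
      bool placed = false;
      for (int t = 0; t < tries_per_node; ++t) {
        auto& b = bonds[rng.bounded((uint32_t)bonds.size())];
        int ux_ = S.ux[k - 1] + b[0], uy_ = S.uy[k - 1] + b[1],
            uz_ = S.uz[k - 1] + b[2];
        int x = S.wrap(ux_), y = S.wrap(uy_), z = S.wrap(uz_);
        if (!ev_ok_general(S, -2, x, y, z)) continue;
        S.ux[k] = ux_; S.uy[k] = uy_; S.uz[k] = uz_;
        S.tx[k] = x; S.ty[k] = y; S.tz[k] = z;
        S.place(k);
        placed = true;
        break;
      }
      if (!placed) ok = false;
    }
    if (ok) {
      IntegerMatrix w(N, 3), u(N, 3);
      for (int k = 0; k < N; ++k) {
        w(k, 0) = S.tx[k]; w(k, 1) = S.ty[k]; w(k, 2) = S.tz[k];
        u(k, 0) = S.ux[k]; u(k, 1) = S.uy[k]; u(k, 2) = S.uz[k];
      }
      return List::create(_["wrapped"] = w, _["unwrapped"] = u,
                          _["restarts"] = attempt);
    }
  }
  stop("chain growth failed after %d restarts: lattice too small or "
       "pathological seed", max_restarts);
}

// --------------------------------------------------- exported energy helpers
// [[Rcpp::export]]
double cpp_total_energy(int L, IntegerVector type, IntegerMatrix wrapped,
                        NumericMatrix epsPair, NumericVector epsSolv,
                        double fs) {
  System S = make_system(L, type, wrapped, wrapped);
  Model Mo; Mo.build(epsPair, epsSolv, fs, 1.0);
  return total_energy(S, Mo);
}

// [[Rcpp::export]]
NumericVector cpp_node_energies(int L, IntegerVector type,
                                IntegerMatrix wrapped, NumericMatrix epsPair,
                                NumericVector epsSolv, double fs) {
  System S = make_system(L, type, wrapped, wrapped);
  Model Mo; Mo.build(epsPair, epsSolv, fs, 1.0);
  NumericVector out(S.N);
  for (int n = 0; n < S.N; ++n) out[n] = node_energy(S, Mo, n);
  return out;
}

// [[Rcpp::export]]
double cpp_delta_energy(int L, IntegerVector type, IntegerMatrix wrapped,
                        int node, IntegerVector candidate,
                        NumericMatrix epsPair, NumericVector epsSolv,
                        double fs) {
  System S = make_system(L, type, wrapped, wrapped);
  Model Mo; Mo.build(epsPair, epsSolv, fs, 1.0);
  int bx = S.wrap(candidate[0]), by = S.wrap(candidate[1]),
      bz = S.wrap(candidate[2]);
  if (bx == S.tx[node] && by == S.ty[node] && bz == S.tz[node]) return 0.0;
  return delta_energy_move(S, Mo, node, bx, by, bz);
}

// legality of an arbitrary candidate anchor for one node (bond window on both
// adjacent bonds + excluded volume); candidate in wrapped coordinates
// [[Rcpp::export]]
bool cpp_move_legal(int L, IntegerMatrix wrapped, int node,
                    IntegerVector candidate) {
  IntegerVector type(wrapped.nrow());
  System S = make_system(L, type, wrapped, wrapped);
  int x = S.wrap(candidate[0]), y = S.wrap(candidate[1]),
      z = S.wrap(candidate[2]);
  if (!ev_ok_general(S, node, x, y, z)) return false;
  return bonds_ok_at(S, node, x, y, z, false);
}

// [[Rcpp::export]]
int cpp_offset_list_size(NumericMatrix epsPair, NumericVector epsSolv,
                         double fs) {
  Model Mo; Mo.build(epsPair, epsSolv, fs, 1.0);
  return Mo.M;
}

// ------------------------------------------------------------------ MC run
// One trajectory: `steps` Monte Carlo steps (1 MCS = N attempted single-node
// moves), recording observables every dump_interval and auditing the
// incremental energy + geometry every audit_interval.
// [[Rcpp::export]]
List cpp_run(int L, IntegerVector type, IntegerMatrix wrapped,
             IntegerMatrix unwrapped, NumericMatrix epsPair,
             NumericVector epsSolv, double fs, double T, int steps,
             int dump_interval, int audit_interval, int seed,
             bool store_frames = true, bool store_node_energies = false) {
  System S = make_system(L, type, wrapped, unwrapped);
  Model Mo; Mo.build(epsPair, epsSolv, fs, T);
  Pcg32 rng((uint64_t)seed, 0xda3e39cb94b95bdbULL);
  const int N = S.N;
  const double invT = 1.0 / T;

  std::vector<long long> attempts(N, 0), accepts(N, 0);
  double E_run = total_energy(S, Mo);
  double max_drift = 0.0;
  bool geometry_ok = true;

  int nframes = steps / dump_interval;
  NumericVector f_t(nframes), f_rg(nframes), f_E(nframes);
  NumericMatrix f_com(nframes, 3);
  NumericMatrix f_att(nframes, N), f_acc(nframes, N);
  NumericMatrix f_en = store_node_energies ? NumericMatrix(nframes, N)
                                           : NumericMatrix(0, 0);
  List frames(store_frames ? nframes : 0);
  int fi = 0;

  static const int DX[6] = {1, -1, 0, 0, 0, 0};
  static const int DY[6] = {0, 0, 1, -1, 0, 0};
  static const int DZ[6] = {0, 0, 0, 0, 1, -1};

  for (int step = 1; step <= steps; ++step) {
    for (int a = 0; a < N; ++a) {
      int k = (int)rng.bounded((uint32_t)N);
      int d = (int)rng.bounded(6u);
      ++attempts[k];
      int dx = DX[d], dy = DY[d], dz = DZ[d];
      int ux_ = S.ux[k] + dx, uy_ = S.uy[k] + dy, uz_ = S.uz[k] + dz;
      if (!bonds_ok_at(S, k, ux_, uy_, uz_, true)) continue;
      int bx = S.wrap(S.tx[k] + dx), by = S.wrap(S.ty[k] + dy),
          bz = S.wrap(S.tz[k] + dz);
      if (!ev_ok_move(S, k, dx, dy, dz, bx, by, bz)) continue;
      double dE = delta_energy_move(S, Mo, k, bx, by, bz);
      if (dE > 0.0 && rng.unif() >= std::exp(-dE * invT)) continue;
      S.clearpos(k);
      S.tx[k] = bx; S.ty[k] = by; S.tz[k] = bz;
      S.ux[k] = ux_; S.uy[k] = uy_; S.uz[k] = uz_;
      S.place(k);
      E_run += dE;
      ++accepts[k];
    }

    if (audit_interval > 0 && step % audit_interval == 0) {
      double E_full = total_energy(S, Mo);
      double drift = std::fabs(E_full - E_run);
      if (drift > max_drift) max_drift = drift;
      E_run = E_full;
      if (!audit_geometry(S)) geometry_ok = false;
    }

    if (step % dump_interval == 0 && fi < nframes) {
      double mx = 0, my = 0, mz = 0;
      for (int k = 0; k < N; ++k) { mx += S.ux[k]; my += S.uy[k]; mz += S.uz[k]; }
      mx /= N; my /= N; mz /= N;
      double rg2 = 0;
      for (int k = 0; k < N; ++k) {
        double ddx = S.ux[k] - mx, ddy = S.uy[k] - my, ddz = S.uz[k] - mz;
        rg2 += ddx * ddx + ddy * ddy + ddz * ddz;
      }
      f_t[fi] = step;
      f_rg[fi] = std::sqrt(rg2 / N);
      f_E[fi] = E_run;
      f_com(fi, 0) = mx; f_com(fi, 1) = my; f_com(fi, 2) = mz;
      for (int k = 0; k < N; ++k) {
        f_att(fi, k) = (double)attempts[k];
        f_acc(fi, k) = (double)accepts[k];
      }
      if (store_node_energies)
        for (int n = 0; n < N; ++n) f_en(fi, n) = node_energy(S, Mo, n);
      if (store_frames) {
        IntegerMatrix fr(N, 3);
        for (int k = 0; k < N; ++k) {
          fr(k, 0) = S.ux[k]; fr(k, 1) = S.uy[k]; fr(k, 2) = S.uz[k];
        }
        frames[fi] = fr;
      }
      ++fi;
    }
  }

  IntegerMatrix w(N, 3), u(N, 3);
  for (int k = 0; k < N; ++k) {
    w(k, 0) = S.tx[k]; w(k, 1) = S.ty[k]; w(k, 2) = S.tz[k];
    u(k, 0) = S.ux[k]; u(k, 1) = S.uy[k]; u(k, 2) = S.uz[k];
  }
  return List::create(
      _["t"] = f_t, _["rg"] = f_rg, _["energy"] = f_E, _["com"] = f_com,
      _["attempts"] = f_att, _["accepts"] = f_acc,
      _["node_energies"] = f_en, _["frames"] = frames,
      _["wrapped"] = w, _["unwrapped"] = u,
      _["energy_drift"] = max_drift, _["geometry_ok"] = geometry_ok,
      _["final_energy"] = E_run);
}
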