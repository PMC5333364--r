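// Multicanonical Monte Carlo core: Lennard-Jones gas and FENE bead-spring
// polymer solution in a periodic box.  All energies in reduced units
// (epsilon = k_B = m = 1).  The R layer owns weight iteration and analysis;
// this file owns the inner loops.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF_E = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded via splitmix64; self-contained so that runs are
// reproducible from a single integer seed independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int randint(int n) {  // uniform on 0..n-1
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// --------------------------------------------------------------- spec -----
struct Spec {
  bool polymer;
  int nc;       // constituents (particles or chains)
  int mper;     // monomers per chain (1 for gas)
  int nm;       // nc * mper
  double L;
  double eps, sig2, rc, rc2, shift;
  double K, Rf, r0;
};

static Spec parse_spec(const List& s) {
  Spec sp;
  std::string kind = as<std::string>(s["kind"]);
  sp.polymer = (kind == "polymer_solution");
  sp.nc = as<int>(s["n_constituents"]);
  sp.mper = as<int>(s["monomers_per_chain"]);
  sp.nm = sp.nc * sp.mper;
  sp.L = as<double>(s["box_length"]);
  sp.eps = as<double>(s["lj_epsilon"]);
  double sig = as<double>(s["lj_sigma"]);
  sp.sig2 = sig * sig;
  sp.rc = as<double>(s["lj_cutoff"]);
  sp.rc2 = sp.rc * sp.rc;
  sp.shift = as<double>(s["lj_shift"]);
  sp.K = as<double>(s["fene_K"]);
  sp.Rf = as<double>(s["fene_R"]);
  sp.r0 = as<double>(s["fene_r0"]);
  return sp;
}

static inline double mi(double d, double L) {
  return d - L * std::nearbyint(d / L);
}
static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  return x >= L ? x - L : x;  // guard the x/L rounding edge
}

// ---------------------------------------------------------- cell list -----
struct CellList {
  bool active = false;
  int nx = 0;
  double L = 0, cw = 0;
  std::vector<int> head, nxt, prv, cellof;

  inline int cidx(double x, double y, double z) const {
    int a = (int)(x / cw), b = (int)(y / cw), c = (int)(z / cw);
    if (a >= nx) a = nx - 1; if (b >= nx) b = nx - 1; if (c >= nx) c = nx - 1;
    if (a < 0) a = 0; if (b < 0) b = 0; if (c < 0) c = 0;
    return (a * nx + b) * nx + c;
  }
  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, double L_, double rmin) {
    L = L_;
    nx = (int)std::floor(L / rmin);
    int n = (int)px.size();
    if (nx < 3) { active = false; return; }
    active = true;
    cw = L / nx;
    head.assign((size_t)nx * nx * nx, -1);
    nxt.assign(n, -1);
    prv.assign(n, -1);
    cellof.assign(n, -1);
    for (int i = 0; i < n; ++i) insert(i, px[i], py[i], pz[i]);
  }
  void insert(int i, double x, double y, double z) {
    int c = cidx(x, y, z);
    cellof[i] = c;
    nxt[i] = head[c];
    prv[i] = -1;
    if (head[c] >= 0) prv[head[c]] = i;
    head[c] = i;
  }
  void remove(int i) {
    int c = cellof[i];
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
    cellof[i] = -1;
  }
  void move(int i, double x, double y, double z) {
    int c = cidx(x, y, z);
    if (c == cellof[i]) return;
    remove(i);
    insert(i, x, y, z);
  }
};

// ------------------------------------------------------------- engine -----
struct Engine {
  Spec sp;
  std::vector<double> px, py, pz;
  CellList cl;
  double Ep = 0;
  std::vector<int> stamp;  // scratch marker for moved sets
  int stamp_id = 0;

  // weights (multicanonical) or canonical beta
  bool canonical = false;
  double beta_can = 0;
  std::vector<double> wc, lw;  // bin centers, ln W
  double de = 0, elo = 0, ehi = 0;

  void init_positions(const NumericMatrix& pos) {
    int n = pos.nrow();
    px.resize(n); py.resize(n); pz.resize(n);
    for (int i = 0; i < n; ++i) {
      px[i] = wrap(pos(i, 0), sp.L);
      py[i] = wrap(pos(i, 1), sp.L);
      pz[i] = wrap(pos(i, 2), sp.L);
    }
    stamp.assign(n, 0);
    stamp_id = 0;
    cl.build(px, py, pz, sp.L, sp.rc);
  }

  inline bool bonded(int i, int j) const {
    if (!sp.polymer) return false;
    if (i / sp.mper != j / sp.mper) return false;
    int d = i - j;
    return d == 1 || d == -1;
  }
  inline double pair_lj(double r2) const {
    if (r2 >= sp.rc2) return 0.0;
    double sr2 = sp.sig2 / r2, sr6 = sr2 * sr2 * sr2;
    return 4.0 * sp.eps * (sr6 * sr6 - sr6) + sp.shift;
  }
  inline double fene(double r) const {
    double d = r - sp.r0;
    double a = 1.0 - d * d / (sp.Rf * sp.Rf);
    if (a <= 0.0) return INF_E;
    return -0.5 * sp.K * sp.Rf * sp.Rf * std::log(a);
  }
  inline double dist2(double xi, double yi, double zi, int j) const {
    double dx = mi(xi - px[j], sp.L);
    double dy = mi(yi - py[j], sp.L);
    double dz = mi(zi - pz[j], sp.L);
    return dx * dx + dy * dy + dz * dz;
  }

  // LJ energy of a point at (x,y,z) carrying identity i against all
  // unstamped, non-bonded partners.
  double lj_around(int i, double x, double y, double z) const {
    double e = 0;
    if (cl.active) {
      int a = (int)(x / cl.cw), b = (int)(y / cl.cw), c = (int)(z / cl.cw);
      if (a >= cl.nx) a = cl.nx - 1; if (b >= cl.nx) b = cl.nx - 1;
      if (c >= cl.nx) c = cl.nx - 1;
      for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
          for (int dc = -1; dc <= 1; ++dc) {
            int aa = (a + da + cl.nx) % cl.nx;
            int bb = (b + db + cl.nx) % cl.nx;
            int cc = (c + dc + cl.nx) % cl.nx;
            for (int j = cl.head[(aa * cl.nx + bb) * cl.nx + cc]; j >= 0;
                 j = cl.nxt[j]) {
              if (j == i || stamp[j] == stamp_id || bonded(i, j)) continue;
              double r2 = dist2(x, y, z, j);
              if (r2 < sp.rc2) e += pair_lj(r2);
            }
          }
    } else {
      int n = (int)px.size();
      for (int j = 0; j < n; ++j) {
        if (j == i || stamp[j] == stamp_id || bonded(i, j)) continue;
        double r2 = dist2(x, y, z, j);
        if (r2 < sp.rc2) e += pair_lj(r2);
      }
    }
    return e;
  }

  // Energy contribution of a set of monomers at given coordinates:
  // set<->rest LJ, intra-set LJ, and every FENE bond touching the set.
  // `idx` are monomer indices, `cx/cy/cz` their coordinates.  The caller
  // must have stamped exactly the members of `idx`.
  double set_energy(const std::vector<int>& idx, const std::vector<double>& cx,
                    const std::vector<double>& cy,
                    const std::vector<double>& cz) const {
    int m = (int)idx.size();
    double e = 0;
    for (int k = 0; k < m; ++k)
      e += lj_around(idx[k], cx[k], cy[k], cz[k]);
    // intra-set LJ (minimum image on proposed coordinates)
    for (int k = 0; k < m; ++k)
      for (int l = k + 1; l < m; ++l) {
        if (bonded(idx[k], idx[l])) continue;
        double dx = mi(cx[k] - cx[l], sp.L);
        double dy = mi(cy[k] - cy[l], sp.L);
        double dz = mi(cz[k] - cz[l], sp.L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < sp.rc2) e += pair_lj(r2);
      }
    if (sp.polymer) {
      for (int k = 0; k < m; ++k) {
        int i = idx[k];
        int ci = i / sp.mper, mi_ = i % sp.mper;
        for (int d = -1; d <= 1; d += 2) {
          int mj = mi_ + d;
          if (mj < 0 || mj >= sp.mper) continue;
          int j = ci * sp.mper + mj;
          if (stamp[j] == stamp_id) {
            if (j < i) continue;  // counted once from the lower index
            // locate j inside the set
            double xj = 0, yj = 0, zj = 0;
            for (int l = 0; l < m; ++l)
              if (idx[l] == j) { xj = cx[l]; yj = cy[l]; zj = cz[l]; break; }
            double dx = mi(cx[k] - xj, sp.L), dy = mi(cy[k] - yj, sp.L),
                   dz = mi(cz[k] - zj, sp.L);
            e += fene(std::sqrt(dx * dx + dy * dy + dz * dz));
          } else {
            double dx = mi(cx[k] - px[j], sp.L), dy = mi(cy[k] - py[j], sp.L),
                   dz = mi(cz[k] - pz[j], sp.L);
            e += fene(std::sqrt(dx * dx + dy * dy + dz * dz));
          }
        }
      }
    }
    return e;
  }

  double total_energy(bool brute) const {
    int n = (int)px.size();
    double e = 0;
    if (!brute && cl.active) {
      for (int i = 0; i < n; ++i) {
        // half-count via ordered pairs in neighbor cells
        int a = cl.cellof[i] / (cl.nx * cl.nx);
        int b = (cl.cellof[i] / cl.nx) % cl.nx;
        int c = cl.cellof[i] % cl.nx;
        for (int da = -1; da <= 1; ++da)
          for (int db = -1; db <= 1; ++db)
            for (int dc = -1; dc <= 1; ++dc) {
              int aa = (a + da + cl.nx) % cl.nx;
              int bb = (b + db + cl.nx) % cl.nx;
              int cc = (c + dc + cl.nx) % cl.nx;
              for (int j = cl.head[(aa * cl.nx + bb) * cl.nx + cc]; j >= 0;
                   j = cl.nxt[j]) {
                if (j <= i || bonded(i, j)) continue;
                double r2 = dist2(px[i], py[i], pz[i], j);
                if (r2 < sp.rc2) e += pair_lj(r2);
              }
            }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (bonded(i, j)) continue;
          double r2 = dist2(px[i], py[i], pz[i], j);
          if (r2 < sp.rc2) e += pair_lj(r2);
        }
    }
    if (sp.polymer) {
      for (int c = 0; c < sp.nc; ++c)
        for (int m = 0; m + 1 < sp.mper; ++m) {
          int i = c * sp.mper + m, j = i + 1;
          double r2 = dist2(px[i], py[i], pz[i], j);
          e += fene(std::sqrt(r2));
        }
    }
    return e;
  }

  inline double lnW(double E) const {
    if (canonical) return -beta_can * E;
    int k = (int)wc.size();
    double t = (E - wc[0]) / de;
    if (t <= 0) return lw[0];
    if (t >= k - 1) return lw[k - 1];
    int i = (int)t;
    double f = t - i;
    return lw[i] * (1 - f) + lw[i + 1] * f;
  }

  // ---- moves: each returns dE (may be +inf) and fills the proposal ----
  std::vector<int> midx;
  std::vector<double> mx, my, mz;

  void stamp_set() {
    ++stamp_id;
    for (size_t k = 0; k < midx.size(); ++k) stamp[midx[k]] = stamp_id;
  }

  // generic: dE for moving set midx from current coords to (mx,my,mz)
  double proposal_delta() {
    // wrap proposals first: cell lookup and minimum image assume [0,L)
    for (size_t k = 0; k < midx.size(); ++k) {
      mx[k] = wrap(mx[k], sp.L);
      my[k] = wrap(my[k], sp.L);
      mz[k] = wrap(mz[k], sp.L);
    }
    stamp_set();
    std::vector<double> ox(midx.size()), oy(midx.size()), oz(midx.size());
    for (size_t k = 0; k < midx.size(); ++k) {
      ox[k] = px[midx[k]]; oy[k] = py[midx[k]]; oz[k] = pz[midx[k]];
    }
    double enew = set_energy(midx, mx, my, mz);
    if (!std::isfinite(enew)) return INF_E;
    double eold = set_energy(midx, ox, oy, oz);
    return enew - eold;
  }

  void apply_proposal() {
    for (size_t k = 0; k < midx.size(); ++k) {
      int i = midx[k];
      px[i] = wrap(mx[k], sp.L);
      py[i] = wrap(my[k], sp.L);
      pz[i] = wrap(mz[k], sp.L);
      if (cl.active) cl.move(i, px[i], py[i], pz[i]);
    }
  }

  void propose_displace(int i, double d, Xoshiro& rng) {
    midx.assign(1, i);
    mx.assign(1, px[i] + d * (rng.unif() - 0.5));
    my.assign(1, py[i] + d * (rng.unif() - 0.5));
    mz.assign(1, pz[i] + d * (rng.unif() - 0.5));
  }
  void propose_teleport(int i, Xoshiro& rng) {
    midx.assign(1, i);
    mx.assign(1, sp.L * rng.unif());
    my.assign(1, sp.L * rng.unif());
    mz.assign(1, sp.L * rng.unif());
  }
  void propose_chain_shift(int c, Xoshiro& rng) {
    int m = sp.mper;
    midx.resize(m); mx.resize(m); my.resize(m); mz.resize(m);
    double sx = sp.L * rng.unif(), sy = sp.L * rng.unif(),
           sz = sp.L * rng.unif();
    for (int k = 0; k < m; ++k) {
      int i = c * m + k;
      midx[k] = i;
      mx[k] = px[i] + sx; my[k] = py[i] + sy; mz[k] = pz[i] + sz;
    }
  }

  // rotate the shorter arm of chain c about a random axis through the pivot
  // monomer adjacent to bond b; chain unwrapped bond-by-bond from the pivot.
  void propose_bond_rotation(int c, int b, Xoshiro& rng) {
    int m = sp.mper;
    bool tail = (m - 1 - (b + 1)) <= b ? true : false;  // move smaller side
    int pivot, from, to, step;
    if (tail) { pivot = b; from = b + 1; to = m - 1; step = 1; }
    else      { pivot = b + 1; from = b; to = 0; step = -1; }
    int nmove = std::abs(to - from) + 1;
    midx.resize(nmove); mx.resize(nmove); my.resize(nmove); mz.resize(nmove);
    // unwrap from pivot
    double ux = px[c * m + pivot], uy = py[c * m + pivot],
           uz = pz[c * m + pivot];
    // random axis (marsaglia) and angle
    double v1, v2, s;
    do {
      v1 = 2 * rng.unif() - 1; v2 = 2 * rng.unif() - 1;
      s = v1 * v1 + v2 * v2;
    } while (s >= 1 || s == 0);
    double rt = 2 * std::sqrt(1 - s);
    double ax = v1 * rt, ay = v2 * rt, az = 1 - 2 * s;
    double th = (2 * rng.unif() - 1) * M_PI;
    double ct = std::cos(th), st = std::sin(th);
    int prev = pivot;
    double pxu = ux, pyu = uy, pzu = uz;
    int k = 0;
    for (int mm = from; mm != to + step; mm += step, ++k) {
      int i = c * m + mm, ip = c * m + prev;
      double dx = mi(px[i] - px[ip], sp.L), dy = mi(py[i] - py[ip], sp.L),
             dz = mi(pz[i] - pz[ip], sp.L);
      double x = pxu + dx, y = pyu + dy, z = pzu + dz;
      // Rodrigues rotation of (x,y,z) - pivot about (ax,ay,az)
      double rx = x - ux, ry = y - uy, rz = z - uz;
      double dot = rx * ax + ry * ay + rz * az;
      double crx = ay * rz - az * ry, cry = az * rx - ax * rz,
             crz = ax * ry - ay * rx;
      double nxr = rx * ct + crx * st + ax * dot * (1 - ct);
      double nyr = ry * ct + cry * st + ay * dot * (1 - ct);
      double nzr = rz * ct + crz * st + az * dot * (1 - ct);
      midx[k] = i;
      mx[k] = ux + nxr; my[k] = uy + nyr; mz[k] = uz + nzr;
      prev = mm;
      pxu = x; pyu = y; pzu = z;
    }
  }

  // double bridging: swap chain tails after bond b between chains c1, c2.
  // Coordinates do not move; only the bond topology (and hence the bonded
  // exclusions) changes.  Returns dE; applies by swapping tail coordinates.
  int db_c1 = 0, db_c2 = 0, db_b = 0;
  double bridge_delta(int c1, int c2, int b) {
    int m = sp.mper;
    int a1 = c1 * m + b, a2 = a1 + 1, b1 = c2 * m + b, b2 = b1 + 1;
    double ro1 = std::sqrt(dist2(px[a1], py[a1], pz[a1], a2));
    double ro2 = std::sqrt(dist2(px[b1], py[b1], pz[b1], b2));
    double rn1 = std::sqrt(dist2(px[a1], py[a1], pz[a1], b2));
    double rn2 = std::sqrt(dist2(px[b1], py[b1], pz[b1], a2));
    double fn1 = fene(rn1), fn2 = fene(rn2);
    if (!std::isfinite(fn1) || !std::isfinite(fn2)) return INF_E;
    double dE = fn1 + fn2 - fene(ro1) - fene(ro2);
    // old bonded pairs become LJ pairs, new bonded pairs lose their LJ term
    dE += pair_lj(ro1 * ro1) + pair_lj(ro2 * ro2);
    dE -= pair_lj(rn1 * rn1) + pair_lj(rn2 * rn2);
    db_c1 = c1; db_c2 = c2; db_b = b;
    return dE;
  }
  void bridge_apply() {
    int m = sp.mper;
    for (int mm = db_b + 1; mm < m; ++mm) {
      int i = db_c1 * m + mm, j = db_c2 * m + mm;
      std::swap(px[i], px[j]);
      std::swap(py[i], py[j]);
      std::swap(pz[i], pz[j]);
      if (cl.active) {
        cl.move(i, px[i], py[i], pz[i]);
        cl.move(j, px[j], py[j], pz[j]);
      }
    }
  }

  // ----------------------------------------------------- clusters -----
  // Union-find over constituents; adjacency within r_cl (minimum image).
  std::vector<int> uf;
  int uf_find(int i) {
    while (uf[i] != i) { uf[i] = uf[uf[i]]; i = uf[i]; }
    return i;
  }
  void uf_union(int a, int b) {
    a = uf_find(a); b = uf_find(b);
    if (a != b) uf[a] = b;
  }
  // labels constituents; returns largest cluster size
  int clusters(double rcl, std::vector<int>* labels_out) {
    int n = (int)px.size();
    double r2 = rcl * rcl;
    uf.resize(sp.nc);
    for (int i = 0; i < sp.nc; ++i) uf[i] = i;
    bool cells = cl.active && rcl <= cl.cw + 1e-12;
    if (cells) {
      for (int i = 0; i < n; ++i) {
        int a = cl.cellof[i] / (cl.nx * cl.nx);
        int b = (cl.cellof[i] / cl.nx) % cl.nx;
        int c = cl.cellof[i] % cl.nx;
        for (int da = -1; da <= 1; ++da)
          for (int db = -1; db <= 1; ++db)
            for (int dc = -1; dc <= 1; ++dc) {
              int aa = (a + da + cl.nx) % cl.nx;
              int bb = (b + db + cl.nx) % cl.nx;
              int cc = (c + dc + cl.nx) % cl.nx;
              for (int j = cl.head[(aa * cl.nx + bb) * cl.nx + cc]; j >= 0;
                   j = cl.nxt[j]) {
                if (j <= i) continue;
                int ci = i / sp.mper, cj = j / sp.mper;
                if (ci == cj) continue;
                if (dist2(px[i], py[i], pz[i], j) <= r2) uf_union(ci, cj);
              }
            }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          int ci = i / sp.mper, cj = j / sp.mper;
          if (ci == cj) continue;
          if (dist2(px[i], py[i], pz[i], j) <= r2) uf_union(ci, cj);
        }
    }
    std::vector<int> size(sp.nc, 0);
    int nd = 1;
    for (int c = 0; c < sp.nc; ++c) {
      int r = uf_find(c);
      if (++size[r] > nd) nd = size[r];
    }
    if (labels_out) {
      labels_out->resize(sp.nc);
      for (int c = 0; c < sp.nc; ++c) (*labels_out)[c] = uf_find(c);
    }
    return nd;
  }
};

// ------------------------------------------------------------ exports -----

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, List spec, bool brute = false) {
  Engine en;
  en.sp = parse_spec(spec);
  en.init_positions(pos);
  return en.total_energy(brute);
}

// [[Rcpp::export]]
double cpp_move_delta(NumericMatrix pos, List spec, int idx,
                      NumericVector newpos) {
  Engine en;
  en.sp = parse_spec(spec);
  en.init_positions(pos);
  en.midx.assign(1, idx - 1);
  en.mx.assign(1, newpos[0]);
  en.my.assign(1, newpos[1]);
  en.mz.assign(1, newpos[2]);
  return en.proposal_delta();
}

// [[Rcpp::export]]
IntegerVector cpp_find_clusters(NumericMatrix pos, List spec, double rcl) {
  Engine en;
  en.sp = parse_spec(spec);
  en.init_positions(pos);
  std::vector<int> lab;
  en.clusters(rcl, &lab);
  // relabel roots to 1..k in order of first appearance
  std::vector<int> map(en.sp.nc, -1);
  int next = 0;
  IntegerVector out(en.sp.nc);
  for (int c = 0; c < en.sp.nc; ++c) {
    if (map[lab[c]] < 0) map[lab[c]] = next++;
    out[c] = map[lab[c]] + 1;
  }
  return out;
}

// Multicanonical (or canonical, if beta is finite) run.
// move_mix order: [short displacement, long displacement, monomer shift,
//                  bond rotation, double bridging, chain displacement]
// One sweep = nm elementary attempts; (E_p, N_D) recorded once per sweep.
// [[Rcpp::export]]
List cpp_run_muca(NumericMatrix pos, List spec, NumericVector w_centers,
                  NumericVector w_lnw, double elo, double ehi, double beta,
                  int n_sweeps, NumericVector move_mix, double d_short,
                  double r_cl, int seed, bool keep_series,
                  int resync_every = 2000, bool measure_nd = true) {
  Engine en;
  en.sp = parse_spec(spec);
  en.init_positions(pos);
  en.canonical = R_finite(beta);
  en.beta_can = beta;
  en.wc.assign(w_centers.begin(), w_centers.end());
  en.lw.assign(w_lnw.begin(), w_lnw.end());
  en.elo = elo; en.ehi = ehi;
  en.de = en.wc.size() > 1 ? en.wc[1] - en.wc[0] : 1.0;
  en.Ep = en.total_energy(false);

  Xoshiro rng((uint64_t)seed * 2654435761ULL + 1442695040888963407ULL);

  int nbin = (int)en.wc.size();
  double edge0 = en.wc[0] - 0.5 * en.de;
  std::vector<double> hist(nbin, 0.0);
  int ndmax = en.sp.nc;
  std::vector<double> hist2d;
  if (measure_nd) hist2d.assign((size_t)nbin * ndmax, 0.0);

  std::vector<double> ser_e;
  std::vector<int> ser_nd;
  if (keep_series) {
    ser_e.reserve(n_sweeps);
    ser_nd.reserve(n_sweeps);
  }

  const int NMOVE = 6;
  std::vector<double> cum(NMOVE);
  double acc_sum = 0;
  for (int k = 0; k < NMOVE; ++k) {
    acc_sum += move_mix[k];
    cum[k] = acc_sum;
  }
  std::vector<long> att(NMOVE, 0), acc(NMOVE, 0);
  double max_drift = 0;
  int nm = en.sp.nm;

  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int a = 0; a < nm; ++a) {
      double u = rng.unif() * acc_sum;
      int mv = 0;
      while (mv < NMOVE - 1 && u > cum[mv]) ++mv;
      ++att[mv];
      double dE;
      bool bridge = false;
      if (mv == 4) {  // double bridging
        if (en.sp.nc < 2) { dE = INF_E; }
        else {
          int c1 = rng.randint(en.sp.nc);
          int c2 = rng.randint(en.sp.nc - 1);
          if (c2 >= c1) ++c2;
          int b = rng.randint(en.sp.mper - 1);
          dE = en.bridge_delta(c1, c2, b);
          bridge = true;
        }
      } else {
        switch (mv) {
          case 0: en.propose_displace(rng.randint(nm), d_short, rng); break;
          case 1: en.propose_teleport(rng.randint(nm), rng); break;
          case 2: en.propose_displace(rng.randint(nm), d_short, rng); break;
          case 3: {
            int c = rng.randint(en.sp.nc);
            int b = rng.randint(en.sp.mper - 1);
            en.propose_bond_rotation(c, b, rng);
            break;
          }
          default: en.propose_chain_shift(rng.randint(en.sp.nc), rng); break;
        }
        dE = en.proposal_delta();
      }
      if (!std::isfinite(dE)) continue;  // FENE violation etc: reject
      double Enew = en.Ep + dE;
      bool ok;
      if (Enew < en.elo || Enew > en.ehi) {
        // outside the window: only allow moves toward it (recovers a start
        // that was accidentally out of range; inside-window starts never
        // trigger the second branch)
        ok = (en.Ep < en.elo && Enew > en.Ep) ||
             (en.Ep > en.ehi && Enew < en.Ep);
      } else {
        double dlw = en.lnW(Enew) - en.lnW(en.Ep);
        ok = dlw >= 0 || rng.unif() < std::exp(dlw);
      }
      if (ok) {
        if (bridge) en.bridge_apply(); else en.apply_proposal();
        en.Ep = Enew;
        ++acc[mv];
      }
    }
    if (resync_every > 0 && (sw + 1) % resync_every == 0) {
      double ef = en.total_energy(false);
      double dr = std::fabs(ef - en.Ep);
      if (dr > max_drift) max_drift = dr;
      en.Ep = ef;
    }
    // measurement
    int bi = (int)std::floor((en.Ep - edge0) / en.de);
    if (bi < 0) bi = 0;
    if (bi >= nbin) bi = nbin - 1;
    hist[bi] += 1.0;
    int nd = 0;
    if (measure_nd) {
      nd = en.clusters(r_cl, nullptr);
      hist2d[(size_t)bi * ndmax + (nd - 1)] += 1.0;
    }
    if (keep_series) {
      ser_e.push_back(en.Ep);
      ser_nd.push_back(nd);
    }
  }

  // final resync so returned E_p is exact
  double efinal = en.total_energy(false);
  double dr = std::fabs(efinal - en.Ep);
  if (dr > max_drift && resync_every > 0) max_drift = dr;

  int n = (int)en.px.size();
  NumericMatrix pout(n, 3);
  for (int i = 0; i < n; ++i) {
    pout(i, 0) = en.px[i]; pout(i, 1) = en.py[i]; pout(i, 2) = en.pz[i];
  }
  NumericMatrix h2(measure_nd ? nbin : 0, measure_nd ? ndmax : 0);
  if (measure_nd)
    for (int b = 0; b < nbin; ++b)
      for (int d = 0; d < ndmax; ++d) h2(b, d) = hist2d[(size_t)b * ndmax + d];

  List out = List::create(
      _["positions"] = pout, _["e_p"] = efinal,
      _["hist"] = NumericVector(hist.begin(), hist.end()),
      _["hist2d"] = h2,
      _["series_e"] = NumericVector(ser_e.begin(), ser_e.end()),
      _["series_nd"] = IntegerVector(ser_nd.begin(), ser_nd.end()),
      _["attempts"] = NumericVector(att.begin(), att.end()),
      _["accepts"] = NumericVector(acc.begin(), acc.end()),
      _["drift"] = max_drift, _["e_unresynced"] = en.Ep);
  return out;
}
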