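// Core molecular-dynamics kernels for bead-spring lipid membranes.
//
// Beads carry a role: 1 = head, 2 = tail, 3 = cargo. Lipids are chains of
// beads joined by FENE bonds and straightened by cosine angle potentials.
// Non-bonded interactions are WCA repulsion everywhere plus a cos^2-tapered
// attraction of depth eps_p and range omega between tail beads (implicit
// hydrophobic effect). A single large cargo bead may adhere to head beads
// with depth eps_mc via the same tapered well, acting on the shifted
// distance r - (r_cargo - b/2) so the well sits at the cargo surface.
//
// Integration: Gronbech-Jensen/Farago discretisation of Langevin dynamics
// (exact free-particle diffusion, reduces to velocity Verlet at gamma = 0),
// with a Berendsen-style barostat rescaling Lx, Ly toward zero lateral
// pressure. Randomness comes from a counter-based hash RNG keyed on
// (seed, absolute step, bead, draw), so trajectories are bitwise
// reproducible and checkpoint-restartable.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int ROLE_HEAD = 1, ROLE_TAIL = 2, ROLE_CARGO = 3;
static const double RC_FACT = 1.1224620483093730; // 2^(1/6)

struct FF {
  double eps_p, omega, b_head, b_tail, eps_rep;
  double fene_k, fene_rmax;
  double eps_mc, r_cargo;
  int excl_bonds; // non-bonded exclusion depth along the chain (1 or 3)
};

static FF ff_from_list(const List& l) {
  FF f;
  f.eps_p    = as<double>(l["eps_p"]);
  f.omega    = as<double>(l["omega"]);
  f.b_head   = as<double>(l["b_head"]);
  f.b_tail   = as<double>(l["b_tail"]);
  f.eps_rep  = as<double>(l["eps_rep"]);
  f.fene_k   = as<double>(l["fene_k"]);
  f.fene_rmax= as<double>(l["fene_rmax"]);
  f.eps_mc   = as<double>(l["eps_mc"]);
  f.r_cargo  = as<double>(l["r_cargo"]);
  f.excl_bonds = l.containsElementNamed("excl_bonds") ?
    as<int>(l["excl_bonds"]) : 1;
  return f;
}

// WCA repulsion, shifted to zero at 2^(1/6) b. Adds to *e and *fr (= -dE/dr).
static inline void wca_ef(double r, double b, double eps, double* e, double* fr) {
  double rc = RC_FACT * b;
  if (r >= rc) return;
  double sr2 = (b * b) / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  *e  += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
  *fr += 4.0 * eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r;
}

// cos^2-tapered attraction: -eps for r < rc, -eps cos^2(pi (r-rc)/(2 w)) out
// to rc + w. C1 at both joins.
static inline void taper_ef(double r, double rc, double w, double eps,
                            double* e, double* fr) {
  if (eps <= 0.0 || r >= rc + w) return;
  if (r < rc) { *e += -eps; return; }
  double a = M_PI / (2.0 * w);
  double c = cos(a * (r - rc)), s = sin(a * (r - rc));
  *e  += -eps * c * c;
  *fr += -2.0 * eps * a * c * s;
}

// Non-bonded lipid-lipid pair: heads are purely repulsive, tail-tail also
// attracts. b follows the Cooke convention: 0.95 sigma for any pair
// involving a head, 1 sigma for tail-tail.
static inline void pair_ef_lipid(double r, int ri, int rj, const FF& ff,
                                 double* e, double* fr) {
  *e = 0.0; *fr = 0.0;
  bool tt = (ri == ROLE_TAIL && rj == ROLE_TAIL);
  double b = tt ? ff.b_tail : ff.b_head;
  wca_ef(r, b, ff.eps_rep, e, fr);
  if (tt) taper_ef(r, RC_FACT * ff.b_tail, ff.omega, ff.eps_p, e, fr);
}

// Cargo-bead pair in the shifted distance x = r - (r_cargo - b/2); heads
// additionally feel the eps_mc adhesion well at the cargo surface.
static inline void pair_ef_cargo(double r, int role_other, const FF& ff,
                                 double* e, double* fr) {
  *e = 0.0; *fr = 0.0;
  double b = (role_other == ROLE_HEAD) ? ff.b_head : ff.b_tail;
  double delta = ff.r_cargo - 0.5 * b;
  double x = r - delta;
  if (x <= 1e-9) stop("bead overlapping cargo core (r = %f)", r);
  double e0 = 0.0, f0 = 0.0;
  wca_ef(x, b, ff.eps_rep, &e0, &f0);
  if (role_other == ROLE_HEAD)
    taper_ef(x, RC_FACT * b, ff.omega, ff.eps_mc, &e0, &f0);
  *e = e0; *fr = f0; // d/dr == d/dx
}

// FENE bond plus WCA core so bonded beads neither detach nor collapse.
static inline void bond_ef(double r, double b, const FF& ff,
                           double* e, double* fr) {
  if (r >= ff.fene_rmax)
    stop("FENE bond broken: r = %f >= rmax = %f (integration blow-up?)",
         r, ff.fene_rmax);
  double q = r / ff.fene_rmax;
  *e = -0.5 * ff.fene_k * ff.fene_rmax * ff.fene_rmax * log(1.0 - q * q);
  *fr = -ff.fene_k * r / (1.0 - q * q);
  wca_ef(r, b, ff.eps_rep, e, fr);
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_ef(NumericVector r, int role_i, int role_j, List ff_) {
  FF ff = ff_from_list(ff_);
  NumericMatrix out(r.size(), 2);
  for (int k = 0; k < r.size(); ++k) {
    if (r[k] <= 0) stop("overlapping beads: pair distance must be > 0");
    double e, f;
    if (role_i == ROLE_CARGO || role_j == ROLE_CARGO) {
      int other = (role_i == ROLE_CARGO) ? role_j : role_i;
      pair_ef_cargo(r[k], other, ff, &e, &f);
    } else {
      pair_ef_lipid(r[k], role_i, role_j, ff, &e, &f);
    }
    out(k, 0) = e; out(k, 1) = f;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bond_ef(NumericVector r, List ff_, double b) {
  FF ff = ff_from_list(ff_);
  NumericMatrix out(r.size(), 2);
  for (int k = 0; k < r.size(); ++k) {
    if (r[k] <= 0) stop("bond length must be > 0");
    double e, f;
    bond_ef(r[k], b, ff, &e, &f);
    out(k, 0) = e; out(k, 1) = f;
  }
  return out;
}

// Angle potential k (1 + cos theta): zero and flat at theta = pi.
// [[Rcpp::export]]
NumericMatrix cpp_angle_ef(NumericVector theta, double k) {
  NumericMatrix out(theta.size(), 2);
  for (int i = 0; i < theta.size(); ++i) {
    out(i, 0) = k * (1.0 + cos(theta[i]));
    out(i, 1) = k * sin(theta[i]); // -dE/dtheta
  }
  return out;
}

// ---------------------------------------------------------------------------
// System container used by the force/integration kernels

// Tabulated tail-tail taper (r in [rc, rc + omega]): energy and f/r on a
// uniform grid in r^2, analytic values at the nodes, linear interpolation.
// The taper is smooth and shallow so 4096 nodes keep interpolation error
// below 1e-7 eps; the steep WCA core is always evaluated analytically.
struct TaperTab {
  double r2min, r2max, inv_dr2;
  int n;
  std::vector<double> tab; // interleaved (energy, force/r) pairs
  void init(const FF& ff) {
    n = 4096;
    double rc = RC_FACT * ff.b_tail;
    r2min = rc * rc;
    double rmax = rc + ff.omega;
    r2max = rmax * rmax;
    inv_dr2 = (n - 1) / (r2max - r2min);
    tab.resize(2 * n);
    for (int i = 0; i < n; ++i) {
      double r2 = r2min + i / inv_dr2;
      double r = sqrt(r2);
      double ee = 0, ff_ = 0;
      taper_ef(r, rc, ff.omega, ff.eps_p, &ee, &ff_);
      tab[2 * i] = ee;
      tab[2 * i + 1] = ff_ / r;
    }
  }
  // returns energy; stores force/r in *c
  inline double lookup(double r2, double* c) const {
    double u = (r2 - r2min) * inv_dr2;
    int i = (int)u;
    if (i < 0) i = 0;
    if (i >= n - 1) { *c = 0.0; return 0.0; }
    double w = u - i;
    const double* t = &tab[2 * i];
    *c = t[1] * (1 - w) + t[3] * w;
    return t[0] * (1 - w) + t[2] * w;
  }
};

struct Sys {
  int n;
  std::vector<double> x, v, f, w;     // 3n: positions, velocities, forces,
                                      // wrapped positions
  std::vector<double> mass;
  std::vector<int> role;
  std::vector<int> bonds;             // 2m, 0-based
  std::vector<int> angles;            // 3k, 0-based
  std::vector<double> angle_k;
  std::vector<int> cargo;             // indices of cargo beads
  std::vector<std::vector<int> > excl;// bonded partners per bead
  double L[3];
  // neighbour lists (flat pair lists, split by interaction range:
  // tail-tail pairs carry the long attraction cutoff, head-involving
  // pairs only the short WCA core)
  double cutoff, rlist, cutoff_h, rlist_h;
  std::vector<int> pt_i, pt_j, ph_i, ph_j;
  std::vector<double> xref;           // positions at last list build
  double baro_disp;
  long n_rebuilds;
  // accumulators for the current force evaluation
  double pe, W[3];
  TaperTab tab;
};

static void sys_wrap(Sys& S) {
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) {
      double Ld = S.L[d];
      S.w[3 * i + d] = S.x[3 * i + d] - Ld * floor(S.x[3 * i + d] / Ld);
    }
}

static inline double mind(double dx, double L) {
  double hL = 0.5 * L;
  if (dx > hL) dx -= L;
  else if (dx < -hL) dx += L;
  return dx;
}

static bool pair_excluded(const Sys& S, int i, int j) {
  const std::vector<int>& e = S.excl[i];
  for (size_t k = 0; k < e.size(); ++k) if (e[k] == j) return true;
  return false;
}

// Quick exclusion test: builders number beads consecutively within a
// molecule, so bonded pairs always have |i - j| small; only then scan the
// per-bead exclusion list.
static inline bool maybe_excluded(const Sys& S, int i, int j) {
  if (j - i > 8 && i - j > 8) return false;
  return pair_excluded(S, i, j);
}

// Rebuild the neighbour pair list, excluding bonded pairs and cargo.
// Counting-sort beads into cells of size >= rlist, then scan each cell
// against itself and its 13 forward neighbours.
static void build_nlist(Sys& S) {
  sys_wrap(S);
  double rl2 = S.rlist * S.rlist;
  double rlh2 = S.rlist_h * S.rlist_h;
  S.pt_i.clear(); S.pt_j.clear();
  S.ph_i.clear(); S.ph_j.clear();
  int nc[3];
  bool cells = true;
  // cap the grid so dilute systems in huge boxes do not allocate
  // millions of empty cells (larger cells are always valid)
  int cap = (int)ceil(cbrt(8.0 * S.n + 64.0));
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)floor(S.L[d] / S.rlist);
    if (nc[d] > cap) nc[d] = cap;
    if (nc[d] < 3) cells = false;
    if (nc[d] < 1) nc[d] = 1;
  }
  const double* __restrict w = S.w.data();
  const double L0 = S.L[0], L1 = S.L[1], L2 = S.L[2];
  const double h0 = 0.5 * L0, h1 = 0.5 * L1, h2 = 0.5 * L2;

  if (!cells) {
    for (int i = 0; i < S.n; ++i) {
      if (S.role[i] == ROLE_CARGO) continue;
      for (int j = i + 1; j < S.n; ++j) {
        if (S.role[j] == ROLE_CARGO) continue;
        double d0 = mind(w[3 * i] - w[3 * j], L0);
        double d1 = mind(w[3 * i + 1] - w[3 * j + 1], L1);
        double d2 = mind(w[3 * i + 2] - w[3 * j + 2], L2);
        double r2 = d0 * d0 + d1 * d1 + d2 * d2;
        bool tt = (S.role[i] == ROLE_TAIL && S.role[j] == ROLE_TAIL);
        if (r2 < (tt ? rl2 : rlh2) && !maybe_excluded(S, i, j)) {
          if (tt) { S.pt_i.push_back(i); S.pt_j.push_back(j); }
          else    { S.ph_i.push_back(i); S.ph_j.push_back(j); }
        }
      }
    }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> cellof(S.n, -1), cnt(ncell + 1, 0);
    for (int i = 0; i < S.n; ++i) {
      if (S.role[i] == ROLE_CARGO) continue;
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)(S.w[3 * i + d] / S.L[d] * nc[d]);
        if (c[d] >= nc[d]) c[d] = nc[d] - 1;
        if (c[d] < 0) c[d] = 0;
      }
      int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      cellof[i] = ci;
      cnt[ci + 1]++;
    }
    for (int c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
    std::vector<int> sorted(cnt[ncell]);
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    for (int i = 0; i < S.n; ++i)
      if (cellof[i] >= 0) sorted[fill[cellof[i]]++] = i;

    static const int off13[13][3] = {
      {1,0,0},
      {-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
      {-1,1,1},{0,1,1},{1,1,1}};

    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int ca = (cz * nc[1] + cy) * nc[0] + cx;
          int a0 = cnt[ca], a1 = cnt[ca + 1];
          if (a0 == a1) continue;
          // within the cell
          for (int a = a0; a < a1; ++a) {
            int i = sorted[a];
            double wi0 = w[3*i], wi1 = w[3*i+1], wi2 = w[3*i+2];
            bool it = (S.role[i] == ROLE_TAIL);
            for (int b = a + 1; b < a1; ++b) {
              int j = sorted[b];
              double d0 = wi0 - w[3*j];
              double d1 = wi1 - w[3*j+1];
              double d2 = wi2 - w[3*j+2];
              double r2 = d0*d0 + d1*d1 + d2*d2;
              bool tt = it && (S.role[j] == ROLE_TAIL);
              if (r2 < (tt ? rl2 : rlh2) && !maybe_excluded(S, i, j)) {
                if (tt) { S.pt_i.push_back(i); S.pt_j.push_back(j); }
                else    { S.ph_i.push_back(i); S.ph_j.push_back(j); }
              }
            }
          }
          // forward neighbour cells
          for (int k = 0; k < 13; ++k) {
            int ex = (cx + off13[k][0] + nc[0]) % nc[0];
            int ey = (cy + off13[k][1] + nc[1]) % nc[1];
            int ez = (cz + off13[k][2] + nc[2]) % nc[2];
            int cb = (ez * nc[1] + ey) * nc[0] + ex;
            int b0 = cnt[cb], b1 = cnt[cb + 1];
            for (int a = a0; a < a1; ++a) {
              int i = sorted[a];
              double wi0 = w[3*i], wi1 = w[3*i+1], wi2 = w[3*i+2];
              bool it = (S.role[i] == ROLE_TAIL);
              for (int b = b0; b < b1; ++b) {
                int j = sorted[b];
                double d0 = wi0 - w[3*j];
                if (d0 > h0) d0 -= L0; else if (d0 < -h0) d0 += L0;
                double d1 = wi1 - w[3*j+1];
                if (d1 > h1) d1 -= L1; else if (d1 < -h1) d1 += L1;
                double d2 = wi2 - w[3*j+2];
                if (d2 > h2) d2 -= L2; else if (d2 < -h2) d2 += L2;
                double r2 = d0*d0 + d1*d1 + d2*d2;
                bool tt = it && (S.role[j] == ROLE_TAIL);
                if (r2 < (tt ? rl2 : rlh2) && !maybe_excluded(S, i, j)) {
                  if (tt) { S.pt_i.push_back(i); S.pt_j.push_back(j); }
                  else    { S.ph_i.push_back(i); S.ph_j.push_back(j); }
                }
              }
            }
          }
        }
  }
  S.xref = S.x;
  S.baro_disp = 0.0;
  S.n_rebuilds++;
}

static bool nlist_stale(const Sys& S) {
  double lim = 0.5 * (S.rlist - S.cutoff) - S.baro_disp;
  if (lim <= 0) return true;
  double lim2 = lim * lim;
  for (int i = 0; i < S.n; ++i) {
    double dx = S.x[3 * i] - S.xref[3 * i];
    double dy = S.x[3 * i + 1] - S.xref[3 * i + 1];
    double dz = S.x[3 * i + 2] - S.xref[3 * i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// Full force/energy/virial evaluation. Assumes wrapped coords current.
static void compute_forces(Sys& S, const FF& ff, bool use_table = true) {
  sys_wrap(S);
  std::fill(S.f.begin(), S.f.end(), 0.0);
  S.pe = 0.0; S.W[0] = S.W[1] = S.W[2] = 0.0;
  double cut2 = S.cutoff * S.cutoff;

  // non-bonded pairs: tail-tail (attractive, tabulated taper) and
  // head-involving (short WCA core only), on separate pair lists
  double hh_cut = RC_FACT * ff.b_head;
  double hh_cut2 = hh_cut * hh_cut;
  {
    const double* __restrict w = S.w.data();
    double* __restrict fo = S.f.data();
    const double L0 = S.L[0], L1 = S.L[1], L2 = S.L[2];
    const double h0 = 0.5 * L0, h1 = 0.5 * L1, h2 = 0.5 * L2;
    double pe = 0.0, W0 = 0.0, W1 = 0.0, W2 = 0.0;
    const double r2core = S.tab.r2min;
    {
      const int* __restrict pi = S.pt_i.data();
      const int* __restrict pj = S.pt_j.data();
      const int np = (int)S.pt_i.size();
      for (int k = 0; k < np; ++k) {
        int i = pi[k], j = pj[k];
        double d0 = w[3 * i] - w[3 * j];
        if (d0 > h0) d0 -= L0; else if (d0 < -h0) d0 += L0;
        double d1 = w[3 * i + 1] - w[3 * j + 1];
        if (d1 > h1) d1 -= L1; else if (d1 < -h1) d1 += L1;
        double d2 = w[3 * i + 2] - w[3 * j + 2];
        if (d2 > h2) d2 -= L2; else if (d2 < -h2) d2 += L2;
        double r2 = d0 * d0 + d1 * d1 + d2 * d2;
        if (r2 >= cut2) continue;
        double e, c;
        if (r2 >= r2core) {
          if (use_table) {
            e = S.tab.lookup(r2, &c);
          } else {
            // exact taper (analysis path: forces consistent with energies
            // to machine precision)
            double r = sqrt(r2), fr = 0.0;
            e = 0.0;
            taper_ef(r, RC_FACT * ff.b_tail, ff.omega, ff.eps_p, &e, &fr);
            c = fr / r;
          }
        } else {
          if (r2 < 1e-12) stop("overlapping beads (%d, %d)", i + 1, j + 1);
          double r = sqrt(r2), fr = 0.0;
          e = 0.0;
          wca_ef(r, ff.b_tail, ff.eps_rep, &e, &fr);
          e += -ff.eps_p;
          c = fr / r;
        }
        double f0 = c * d0, f1 = c * d1, f2 = c * d2;
        fo[3 * i] += f0; fo[3 * i + 1] += f1; fo[3 * i + 2] += f2;
        fo[3 * j] -= f0; fo[3 * j + 1] -= f1; fo[3 * j + 2] -= f2;
        pe += e;
        W0 += d0 * f0; W1 += d1 * f1; W2 += d2 * f2;
      }
    }
    {
      const int* __restrict pi = S.ph_i.data();
      const int* __restrict pj = S.ph_j.data();
      const int np = (int)S.ph_i.size();
      for (int k = 0; k < np; ++k) {
        int i = pi[k], j = pj[k];
        double d0 = w[3 * i] - w[3 * j];
        if (d0 > h0) d0 -= L0; else if (d0 < -h0) d0 += L0;
        double d1 = w[3 * i + 1] - w[3 * j + 1];
        if (d1 > h1) d1 -= L1; else if (d1 < -h1) d1 += L1;
        double d2 = w[3 * i + 2] - w[3 * j + 2];
        if (d2 > h2) d2 -= L2; else if (d2 < -h2) d2 += L2;
        double r2 = d0 * d0 + d1 * d1 + d2 * d2;
        if (r2 >= hh_cut2) continue;
        if (r2 < 1e-12) stop("overlapping beads (%d, %d)", i + 1, j + 1);
        double r = sqrt(r2), e = 0.0, fr = 0.0;
        wca_ef(r, ff.b_head, ff.eps_rep, &e, &fr);
        double c = fr / r;
        double f0 = c * d0, f1 = c * d1, f2 = c * d2;
        fo[3 * i] += f0; fo[3 * i + 1] += f1; fo[3 * i + 2] += f2;
        fo[3 * j] -= f0; fo[3 * j + 1] -= f1; fo[3 * j + 2] -= f2;
        pe += e;
        W0 += d0 * f0; W1 += d1 * f1; W2 += d2 * f2;
      }
    }
    S.pe += pe;
    S.W[0] += W0; S.W[1] += W1; S.W[2] += W2;
  }

  // cargo interactions (cargo beads are excluded from the pair list)
  for (size_t cix = 0; cix < S.cargo.size(); ++cix) {
    int c = S.cargo[cix];
    double cut_c = (ff.r_cargo - 0.5 * ff.b_tail) + RC_FACT + ff.omega + 0.5;
    double cc2 = cut_c * cut_c;
    for (int j = 0; j < S.n; ++j) {
      if (j == c || S.role[j] == ROLE_CARGO) continue;
      double d0 = mind(S.w[3 * c] - S.w[3 * j], S.L[0]);
      double d1 = mind(S.w[3 * c + 1] - S.w[3 * j + 1], S.L[1]);
      double d2 = mind(S.w[3 * c + 2] - S.w[3 * j + 2], S.L[2]);
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (r2 >= cc2) continue;
      double r = sqrt(r2), e, fr;
      pair_ef_cargo(r, S.role[j], ff, &e, &fr);
      if (e == 0.0 && fr == 0.0) continue;
      double cf = fr / r;
      double f0 = cf * d0, f1 = cf * d1, f2 = cf * d2;
      S.f[3 * c] += f0; S.f[3 * c + 1] += f1; S.f[3 * c + 2] += f2;
      S.f[3 * j] -= f0; S.f[3 * j + 1] -= f1; S.f[3 * j + 2] -= f2;
      S.pe += e;
      S.W[0] += d0 * f0; S.W[1] += d1 * f1; S.W[2] += d2 * f2;
    }
  }

  // bonds
  int nb = (int)S.bonds.size() / 2;
  for (int k = 0; k < nb; ++k) {
    int i = S.bonds[2 * k], j = S.bonds[2 * k + 1];
    double d0 = mind(S.w[3 * i] - S.w[3 * j], S.L[0]);
    double d1 = mind(S.w[3 * i + 1] - S.w[3 * j + 1], S.L[1]);
    double d2 = mind(S.w[3 * i + 2] - S.w[3 * j + 2], S.L[2]);
    double r = sqrt(d0 * d0 + d1 * d1 + d2 * d2);
    bool tt = (S.role[i] == ROLE_TAIL && S.role[j] == ROLE_TAIL);
    double b = tt ? ff.b_tail : ff.b_head;
    double e, fr;
    bond_ef(r, b, ff, &e, &fr);
    double c = fr / r;
    double f0 = c * d0, f1 = c * d1, f2 = c * d2;
    S.f[3 * i] += f0; S.f[3 * i + 1] += f1; S.f[3 * i + 2] += f2;
    S.f[3 * j] -= f0; S.f[3 * j + 1] -= f1; S.f[3 * j + 2] -= f2;
    S.pe += e;
    S.W[0] += d0 * f0; S.W[1] += d1 * f1; S.W[2] += d2 * f2;
  }

  // angles: E = k (1 + cos theta) over triplets (i, j, k), j central
  int na = (int)S.angles.size() / 3;
  for (int a = 0; a < na; ++a) {
    double ka = S.angle_k[a];
    if (ka == 0.0) continue;
    int i = S.angles[3 * a], j = S.angles[3 * a + 1], k = S.angles[3 * a + 2];
    double aij[3], akj[3];
    for (int d = 0; d < 3; ++d) {
      aij[d] = mind(S.w[3 * i + d] - S.w[3 * j + d], S.L[d]);
      akj[d] = mind(S.w[3 * k + d] - S.w[3 * j + d], S.L[d]);
    }
    double r1 = sqrt(aij[0]*aij[0] + aij[1]*aij[1] + aij[2]*aij[2]);
    double r2 = sqrt(akj[0]*akj[0] + akj[1]*akj[1] + akj[2]*akj[2]);
    if (r1 < 1e-12 || r2 < 1e-12) stop("degenerate angle (zero bond length)");
    double dot = aij[0]*akj[0] + aij[1]*akj[1] + aij[2]*akj[2];
    double ct = dot / (r1 * r2);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    S.pe += ka * (1.0 + ct);
    double fi[3], fk[3];
    for (int d = 0; d < 3; ++d) {
      fi[d] = -ka * (akj[d] / (r1 * r2) - ct * aij[d] / (r1 * r1));
      fk[d] = -ka * (aij[d] / (r1 * r2) - ct * akj[d] / (r2 * r2));
      S.f[3 * i + d] += fi[d];
      S.f[3 * k + d] += fk[d];
      S.f[3 * j + d] -= fi[d] + fk[d];
    }
    S.W[0] += aij[0] * fi[0] + akj[0] * fk[0];
    S.W[1] += aij[1] * fi[1] + akj[1] * fk[1];
    S.W[2] += aij[2] * fi[2] + akj[2] * fk[2];
  }
}

static Sys sys_from_r(NumericMatrix pos, NumericMatrix vel, IntegerVector role,
                      NumericVector mass, IntegerMatrix bonds,
                      IntegerMatrix angles, NumericVector angle_k,
                      NumericVector box, const FF& ff, double skin) {
  Sys S;
  S.n = pos.nrow();
  S.x.resize(3 * S.n); S.v.resize(3 * S.n);
  S.f.assign(3 * S.n, 0.0); S.w.resize(3 * S.n);
  S.mass.resize(S.n); S.role.resize(S.n);
  S.xref.assign(3 * S.n, 0.0); S.baro_disp = 0.0; S.n_rebuilds = 0;
  for (int i = 0; i < S.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      S.x[3 * i + d] = pos(i, d);
      S.v[3 * i + d] = vel(i, d);
    }
    S.mass[i] = mass[i];
    S.role[i] = role[i];
    if (role[i] == ROLE_CARGO) S.cargo.push_back(i);
  }
  S.bonds.resize(2 * bonds.nrow());
  std::vector<std::vector<int> > adj(S.n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    S.bonds[2 * k] = i; S.bonds[2 * k + 1] = j;
    adj[i].push_back(j); adj[j].push_back(i);
  }
  // non-bonded exclusions up to ff.excl_bonds bonds along the chain:
  // depth 1 is the LAMMPS FENE convention (only directly bonded pairs
  // excluded), depth 3 the fully excluded 1-2/1-3/1-4 convention
  S.excl.assign(S.n, std::vector<int>());
  for (int i = 0; i < S.n; ++i) {
    std::vector<int> seen; seen.push_back(i);
    std::vector<int> frontier; frontier.push_back(i);
    for (int depth = 0; depth < ff.excl_bonds; ++depth) {
      std::vector<int> next;
      for (size_t a = 0; a < frontier.size(); ++a)
        for (size_t b = 0; b < adj[frontier[a]].size(); ++b) {
          int v = adj[frontier[a]][b];
          bool known = false;
          for (size_t c = 0; c < seen.size(); ++c)
            if (seen[c] == v) { known = true; break; }
          if (!known) { seen.push_back(v); next.push_back(v); }
        }
      frontier = next;
    }
    for (size_t c = 1; c < seen.size(); ++c) S.excl[i].push_back(seen[c]);
  }
  S.angles.resize(3 * angles.nrow());
  for (int k = 0; k < angles.nrow(); ++k)
    for (int d = 0; d < 3; ++d) S.angles[3 * k + d] = angles(k, d) - 1;
  S.angle_k.assign(angle_k.begin(), angle_k.end());
  for (int d = 0; d < 3; ++d) S.L[d] = box[d];
  S.cutoff = RC_FACT * ff.b_tail + ff.omega;
  S.rlist = S.cutoff + skin;
  S.cutoff_h = RC_FACT * ff.b_head;
  S.rlist_h = S.cutoff_h + skin;
  S.tab.init(ff);
  return S;
}

// [[Rcpp::export]]
List cpp_compute(NumericMatrix pos, NumericMatrix vel, IntegerVector role,
                 NumericVector mass, IntegerMatrix bonds, IntegerMatrix angles,
                 NumericVector angle_k, NumericVector box, List ff_) {
  FF ff = ff_from_list(ff_);
  Sys S = sys_from_r(pos, vel, role, mass, bonds, angles, angle_k, box, ff, 0.4);
  build_nlist(S);
  compute_forces(S, ff, false);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = S.f[3 * i + d];
  double ke[3] = {0, 0, 0};
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d)
      ke[d] += 0.5 * S.mass[i] * S.v[3 * i + d] * S.v[3 * i + d];
  return List::create(_["energy"] = S.pe, _["forces"] = F,
                      _["virial"] = NumericVector::create(S.W[0], S.W[1], S.W[2]),
                      _["kinetic"] = NumericVector::create(ke[0], ke[1], ke[2]));
}

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 hashed on (seed, step, bead), four uniforms
// to two Box-Muller pairs per bead per step.

static inline uint64_t smix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t h) {
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
// three standard normals for one bead at one absolute step
static inline void gauss3(uint64_t seed, uint64_t step, uint32_t bead,
                          double* g) {
  uint64_t h = smix(smix(seed ^ (step * 0x9E3779B97F4A7C15ULL)) + bead + 1);
  uint64_t k1 = smix(h), k2 = smix(k1), k3 = smix(k2), k4 = smix(k3);
  double r1 = sqrt(-2.0 * log(u01(k1))), a1 = 2.0 * M_PI * u01(k2);
  double r2 = sqrt(-2.0 * log(u01(k3))), a2 = 2.0 * M_PI * u01(k4);
  g[0] = r1 * cos(a1);
  g[1] = r1 * sin(a1);
  g[2] = r2 * cos(a2);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector role,
             NumericVector mass, IntegerMatrix bonds, IntegerMatrix angles,
             NumericVector angle_k, NumericVector box, List ff_, List ip_,
             int n_steps, double step0) {
  FF ff = ff_from_list(ff_);
  double dt     = as<double>(ip_["dt"]);
  double gamma  = as<double>(ip_["gamma"]);
  double kT     = as<double>(ip_["temperature"]);
  bool   baro   = as<bool>(ip_["barostat"]);
  double tau_p  = as<double>(ip_["tau_p"]);
  int    nb     = as<int>(ip_["baro_every"]);
  double mxs    = as<double>(ip_["baro_max_scale"]);
  double seed_d = as<double>(ip_["seed"]);
  uint64_t seed = (uint64_t)seed_d;
  double skin   = as<double>(ip_["skin"]);

  Sys S = sys_from_r(pos, vel, role, mass, bonds, angles, angle_k, box, ff, skin);
  build_nlist(S);
  compute_forces(S, ff);

  // GJF coefficients (friction force -gamma m v, so a, b are mass-free)
  double gb = gamma * dt / 2.0;
  double ca = (1.0 - gb) / (1.0 + gb);
  double cb = 1.0 / (1.0 + gb);

  std::vector<double> fold(3 * S.n), beta(3 * S.n, 0.0);
  std::vector<double> sigb(S.n);
  for (int i = 0; i < S.n; ++i)
    sigb[i] = sqrt(2.0 * gamma * S.mass[i] * kT * dt);

  // time averages over the run
  double sW[3] = {0, 0, 0}, sKE[3] = {0, 0, 0}, sPE = 0.0, sA = 0.0;
  long nsamp = 0;

  for (int s = 0; s < n_steps; ++s) {
    uint64_t astep = (uint64_t)(step0 + s);
    double maxdx = 0.0;
    for (int i = 0; i < S.n; ++i) {
      double m = S.mass[i];
      double g3[3] = {0, 0, 0};
      if (gamma > 0) gauss3(seed, astep, (uint32_t)i, g3);
      double ddx = 0.0;
      for (int d = 0; d < 3; ++d) {
        int id = 3 * i + d;
        double bet = sigb[i] * g3[d];
        beta[id] = bet;
        fold[id] = S.f[id];
        double dx = cb * dt * S.v[id] + cb * dt * dt / (2.0 * m) * S.f[id]
                  + cb * dt / (2.0 * m) * bet;
        S.x[id] += dx;
        ddx += dx * dx;
      }
      if (ddx > maxdx) maxdx = ddx;
    }
    if (maxdx > 0.25)
      stop("integration unstable: bead moved %f sigma in one step", sqrt(maxdx));
    if (nlist_stale(S)) build_nlist(S);
    compute_forces(S, ff);
    for (int i = 0; i < S.n; ++i) {
      double m = S.mass[i];
      for (int d = 0; d < 3; ++d) {
        int id = 3 * i + d;
        S.v[id] = ca * S.v[id] + dt / (2.0 * m) * (ca * fold[id] + S.f[id])
                + cb / m * beta[id];
      }
    }
    // accumulate instantaneous averages (sampled every nb-th step)
    if ((s + 1) % nb == 0 || s == n_steps - 1) {
      for (int d = 0; d < 3; ++d) sW[d] += S.W[d];
      for (int i = 0; i < S.n; ++i)
        for (int d = 0; d < 3; ++d)
          sKE[d] += 0.5 * S.mass[i] * S.v[3 * i + d] * S.v[3 * i + d];
      sPE += S.pe;
      sA += S.L[0] * S.L[1];
      nsamp++;
    }

    if (baro && ((s + 1) % nb == 0)) {
      double V = S.L[0] * S.L[1] * S.L[2];
      double ke2[2] = {0, 0};
      for (int i = 0; i < S.n; ++i) {
        ke2[0] += S.mass[i] * S.v[3 * i] * S.v[3 * i];
        ke2[1] += S.mass[i] * S.v[3 * i + 1] * S.v[3 * i + 1];
      }
      double pl = (ke2[0] + ke2[1] + S.W[0] + S.W[1]) / (2.0 * V);
      double mu = 1.0 + (nb * dt / tau_p) * pl;
      if (mu > 1.0 + mxs) mu = 1.0 + mxs;
      if (mu < 1.0 - mxs) mu = 1.0 - mxs;
      S.L[0] *= mu; S.L[1] *= mu;
      for (int i = 0; i < S.n; ++i) {
        S.x[3 * i] *= mu;
        S.x[3 * i + 1] *= mu;
      }
      S.baro_disp += fabs(mu - 1.0) * std::max(S.L[0], S.L[1]);
      if (nlist_stale(S)) build_nlist(S);
      compute_forces(S, ff);
    }
  }

  NumericMatrix P(S.n, 3), V(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) {
      P(i, d) = S.x[3 * i + d];
      V(i, d) = S.v[3 * i + d];
    }
  double inv = (nsamp > 0) ? 1.0 / nsamp : 0.0;
  return List::create(
    _["positions"] = P, _["velocities"] = V,
    _["box"] = NumericVector::create(S.L[0], S.L[1], S.L[2]),
    _["step"] = step0 + n_steps,
    _["energy"] = S.pe,
    _["mean_pe"] = sPE * inv,
    _["mean_virial"] = NumericVector::create(sW[0] * inv, sW[1] * inv, sW[2] * inv),
    _["mean_kinetic"] = NumericVector::create(sKE[0] * inv, sKE[1] * inv, sKE[2] * inv),
    _["mean_area"] = sA * inv,
    _["n_rebuilds"] = (double)S.n_rebuilds);
}

// ---------------------------------------------------------------------------
// Geometry helpers shared by the analysis modules

// All pairs (i, j), i < j, with minimum-image distance below cutoff.
// [[Rcpp::export]]
IntegerMatrix cpp_close_pairs(NumericMatrix pos, NumericVector box,
                              double cutoff) {
  int n = pos.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> out;
  // cell binning
  int nc[3];
  bool cells = true;
  int cap = (int)ceil(cbrt(8.0 * n + 64.0));
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)floor(box[d] / cutoff);
    if (nc[d] > cap) nc[d] = cap;
    if (nc[d] < 3) cells = false;
    if (nc[d] < 1) nc[d] = 1;
  }
  std::vector<double> w(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double L = box[d];
      w[3 * i + d] = pos(i, d) - L * floor(pos(i, d) / L);
    }
  if (!cells) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r2 = 0;
        for (int d = 0; d < 3; ++d) {
          double dx = mind(w[3 * i + d] - w[3 * j + d], box[d]);
          r2 += dx * dx;
        }
        if (r2 < c2) { out.push_back(i + 1); out.push_back(j + 1); }
      }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)(w[3 * i + d] / box[d] * nc[d]);
        if (c[d] >= nc[d]) c[d] = nc[d] - 1;
        if (c[d] < 0) c[d] = 0;
      }
      int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      nxt[i] = head[ci]; head[ci] = i;
    }
    for (int i = 0; i < n; ++i) {
      int cx = -1, cy = -1, cz = -1;
      {
        int c[3];
        for (int d = 0; d < 3; ++d) {
          c[d] = (int)(w[3 * i + d] / box[d] * nc[d]);
          if (c[d] >= nc[d]) c[d] = nc[d] - 1;
          if (c[d] < 0) c[d] = 0;
        }
        cx = c[0]; cy = c[1]; cz = c[2];
      }
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx_ = -1; dx_ <= 1; ++dx_) {
            int ex = (cx + dx_ + nc[0]) % nc[0];
            int ey = (cy + dy + nc[1]) % nc[1];
            int ez = (cz + dz + nc[2]) % nc[2];
            int cj = (ez * nc[1] + ey) * nc[0] + ex;
            for (int j = head[cj]; j != -1; j = nxt[j]) {
              if (j <= i) continue;
              double r2 = 0;
              for (int d = 0; d < 3; ++d) {
                double dd = mind(w[3 * i + d] - w[3 * j + d], box[d]);
                r2 += dd * dd;
              }
              if (r2 < c2) { out.push_back(i + 1); out.push_back(j + 1); }
            }
          }
    }
  }
  IntegerMatrix M((int)out.size() / 2, 2);
  for (int k = 0; k < M.nrow(); ++k) {
    M(k, 0) = out[2 * k]; M(k, 1) = out[2 * k + 1];
  }
  return M;
}

// Occupancy grid: cell (ix, iy, iz) is blocked if its centre lies within
// radius[i] of any bead i (minimum image in periodic dims). Grid spans the
// box with nx * ny * nz cells.
// [[Rcpp::export]]
IntegerVector cpp_occupancy(NumericMatrix pos, NumericVector radius,
                            NumericVector box, int nx, int ny, int nz,
                            LogicalVector periodic) {
  int n = pos.nrow();
  double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  IntegerVector occ(nx * ny * nz, 0);
  for (int i = 0; i < n; ++i) {
    double R = radius[i];
    if (R <= 0) continue;
    double px = pos(i, 0) - box[0] * floor(pos(i, 0) / box[0]);
    double py = pos(i, 1) - box[1] * floor(pos(i, 1) / box[1]);
    double pz = pos(i, 2) - box[2] * floor(pos(i, 2) / box[2]);
    int ix0 = (int)floor((px - R) / hx - 0.5), ix1 = (int)ceil((px + R) / hx - 0.5);
    int iy0 = (int)floor((py - R) / hy - 0.5), iy1 = (int)ceil((py + R) / hy - 0.5);
    int iz0 = (int)floor((pz - R) / hz - 0.5), iz1 = (int)ceil((pz + R) / hz - 0.5);
    double R2 = R * R;
    for (int iz = iz0; iz <= iz1; ++iz) {
      int jz = iz;
      if (periodic[2]) jz = ((iz % nz) + nz) % nz;
      else if (iz < 0 || iz >= nz) continue;
      double cz = (iz + 0.5) * hz;
      double dz = pz - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        int jy = iy;
        if (periodic[1]) jy = ((iy % ny) + ny) % ny;
        else if (iy < 0 || iy >= ny) continue;
        double cy = (iy + 0.5) * hy;
        double dy = py - cy;
        for (int ix = ix0; ix <= ix1; ++ix) {
          int jx = ix;
          if (periodic[0]) jx = ((ix % nx) + nx) % nx;
          else if (ix < 0 || ix >= nx) continue;
          double cx = (ix + 0.5) * hx;
          double dx = px - cx;
          if (dx * dx + dy * dy + dz * dz <= R2)
            occ[(jz * ny + jy) * nx + jx] = 1;
        }
      }
    }
  }
  return occ;
}

// Connected components (6-connectivity) of free (occ == 0) cells.
// Returns labels: 0 for blocked, 1.. for components.
// [[Rcpp::export]]
IntegerVector cpp_free_components(IntegerVector occ, int nx, int ny, int nz,
                                  LogicalVector periodic) {
  int ntot = nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s0 = 0; s0 < ntot; ++s0) {
    if (occ[s0] != 0 || lab[s0] != 0) continue;
    next++;
    lab[s0] = next;
    stack.clear();
    stack.push_back(s0);
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int ex = cx + off[k][0], ey = cy + off[k][1], ez = cz + off[k][2];
        if (periodic[0]) ex = (ex + nx) % nx; else if (ex < 0 || ex >= nx) continue;
        if (periodic[1]) ey = (ey + ny) % ny; else if (ey < 0 || ey >= ny) continue;
        if (periodic[2]) ez = (ez + nz) % nz; else if (ez < 0 || ez >= nz) continue;
        int e = (ez * ny + ey) * nx + ex;
        if (occ[e] == 0 && lab[e] == 0) {
          lab[e] = next;
          stack.push_back(e);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Monte-Carlo conformation flips: reflect one half of a bolalipid through
// the plane that contains its junction bead and is perpendicular to the
// local membrane normal (z for flat membranes, the radial direction for
// tubes). The reflection is an isometry, preserves all bond lengths and the
// moved half's internal angles, and is its own inverse, so a Metropolis
// acceptance on the energy difference samples the canonical ensemble. Used
// to equilibrate the U/straight conformation ratio, whose spontaneous
// kinetics (a head crossing the hydrophobic core) are far slower than any
// other relaxation in the system.

static double local_energy(const Sys& S, const FF& ff, const int* moved,
                           int nmoved, const std::vector<int>& mol) {
  // pair energy of moved beads with all beads outside the moved set,
  // plus all angle energies of the molecule
  double e = 0.0;
  double cut2 = S.cutoff * S.cutoff;
  for (int a = 0; a < nmoved; ++a) {
    int i = moved[a];
    for (int j = 0; j < S.n; ++j) {
      bool in_moved = false;
      for (int b = 0; b < nmoved; ++b) if (moved[b] == j) { in_moved = true; break; }
      if (in_moved || j == i) continue;
      if (pair_excluded(S, i, j)) continue;
      double d0 = mind(S.w[3 * i] - S.w[3 * j], S.L[0]);
      double d1 = mind(S.w[3 * i + 1] - S.w[3 * j + 1], S.L[1]);
      double d2 = mind(S.w[3 * i + 2] - S.w[3 * j + 2], S.L[2]);
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (r2 >= cut2) continue;
      if (r2 < 1e-12) return 1e30; // overlap: certain rejection
      double ee, fr;
      if (S.role[j] == ROLE_CARGO || S.role[i] == ROLE_CARGO) {
        int other = (S.role[i] == ROLE_CARGO) ? S.role[j] : S.role[i];
        double cutc = (ff.r_cargo - 0.5 * ff.b_tail) + RC_FACT + ff.omega + 0.5;
        if (r2 >= cutc * cutc) continue;
        pair_ef_cargo(sqrt(r2), other, ff, &ee, &fr);
      } else {
        pair_ef_lipid(sqrt(r2), S.role[i], S.role[j], ff, &ee, &fr);
      }
      e += ee;
    }
  }
  // angles of this molecule
  int na = (int)S.angles.size() / 3;
  for (int a = 0; a < na; ++a) {
    int i = S.angles[3 * a], j = S.angles[3 * a + 1], k = S.angles[3 * a + 2];
    bool rel = false;
    for (size_t m = 0; m < mol.size(); ++m)
      if (mol[m] == i || mol[m] == j || mol[m] == k) { rel = true; break; }
    if (!rel || S.angle_k[a] == 0.0) continue;
    double v1[3], v2[3];
    for (int d = 0; d < 3; ++d) {
      v1[d] = mind(S.w[3 * i + d] - S.w[3 * j + d], S.L[d]);
      v2[d] = mind(S.w[3 * k + d] - S.w[3 * j + d], S.L[d]);
    }
    double n1 = sqrt(v1[0]*v1[0] + v1[1]*v1[1] + v1[2]*v1[2]);
    double n2 = sqrt(v2[0]*v2[0] + v2[1]*v2[1] + v2[2]*v2[2]);
    double ct = (v1[0]*v2[0] + v1[1]*v2[1] + v1[2]*v2[2]) / (n1 * n2);
    if (ct > 1) ct = 1; if (ct < -1) ct = -1;
    e += S.angle_k[a] * (1.0 + ct);
  }
  return e;
}

// evaluate local energy with candidate wrapped coordinates for the two
// moved beads (written temporarily into S.w)
static double local_energy_at(Sys& S, const FF& ff, const int* moved,
                              const double* cand, const std::vector<int>& mol) {
  double save[6];
  for (int a = 0; a < 2; ++a)
    for (int d = 0; d < 3; ++d) {
      save[3 * a + d] = S.w[3 * moved[a] + d];
      S.w[3 * moved[a] + d] = cand[3 * a + d];
    }
  double e = local_energy(S, ff, moved, 2, mol);
  for (int a = 0; a < 2; ++a)
    for (int d = 0; d < 3; ++d) S.w[3 * moved[a] + d] = save[3 * a + d];
  return e;
}

static inline void rot_about(const double* n, double phi, const double* v,
                             double* out) {
  double c = cos(phi), sn = sin(phi);
  double cx = n[1] * v[2] - n[2] * v[1];
  double cy = n[2] * v[0] - n[0] * v[2];
  double cz = n[0] * v[1] - n[1] * v[0];
  double dot = n[0] * v[0] + n[1] * v[1] + n[2] * v[2];
  out[0] = v[0] * c + cx * sn + n[0] * dot * (1 - c);
  out[1] = v[1] * c + cy * sn + n[1] * dot * (1 - c);
  out[2] = v[2] * c + cz * sn + n[2] * dot * (1 - c);
}

// mode 0: reflect along z; mode 1: reflect along the in-plane radial
// direction about axis_xy (membrane tubes)
// [[Rcpp::export]]
List cpp_mc_flip(NumericMatrix pos, IntegerVector role, NumericVector mass,
                 IntegerMatrix bonds, IntegerMatrix angles,
                 NumericVector angle_k, NumericVector box, List ff_,
                 IntegerMatrix bola_beads, double kT, int n_attempts,
                 double seed_d, double counter0, int mode,
                 NumericVector axis_xy) {
  FF ff = ff_from_list(ff_);
  NumericMatrix vel(pos.nrow(), 3);
  Sys S = sys_from_r(pos, vel, role, mass, bonds, angles, angle_k, box, ff, 0.4);
  sys_wrap(S);
  uint64_t seed = (uint64_t)seed_d;
  uint64_t ctr = (uint64_t)counter0;
  int nb = bola_beads.nrow();
  if (nb == 0)
    return List::create(_["positions"] = pos, _["accepted"] = 0,
                        _["counter"] = counter0);
  int accepted = 0;
  for (int t = 0; t < n_attempts; ++t) {
    double u1 = u01(smix(seed ^ smix(ctr++)));
    double u2 = u01(smix(seed ^ smix(ctr++)));
    double u3 = u01(smix(seed ^ smix(ctr++)));
    int b = (int)(u1 * nb); if (b >= nb) b = nb - 1;
    bool first_half = (u2 < 0.5);
    // moved beads and pivot (junction bead of the moved half)
    int moved[2], pivot;
    std::vector<int> mol(6);
    for (int d = 0; d < 6; ++d) mol[d] = bola_beads(b, d) - 1;
    if (first_half) { moved[0] = mol[0]; moved[1] = mol[1]; pivot = mol[2]; }
    else            { moved[0] = mol[5]; moved[1] = mol[4]; pivot = mol[3]; }
    // reflection normal
    double nx = 0, ny = 0, nz = 1;
    if (mode == 1) {
      double px = S.w[3 * pivot] - axis_xy[0];
      double py = S.w[3 * pivot + 1] - axis_xy[1];
      px = mind(px, S.L[0]); py = mind(py, S.L[1]);
      double nrm = sqrt(px * px + py * py);
      if (nrm < 1e-9) continue;
      nx = px / nrm; ny = py / nrm; nz = 0;
    }
    // orientational-bias selection: the reflected half is additionally
    // rotated about the normal through the pivot; K trial azimuths are
    // weighted by their Boltzmann factors (forward set around the
    // reflected image, reverse set around the current position, which the
    // reflection maps into the forward orbit), giving the standard
    // configurational-bias acceptance W_fwd / W_rev. Needed because a
    // blind reflection lands in occupied space of the target leaflet
    // essentially always at liquid densities.
    const int K = 16;
    double nrm[3] = {nx, ny, nz};
    double rel_old[6], rel_ref[6];
    for (int a = 0; a < 2; ++a) {
      int i = moved[a];
      rel_old[3 * a]     = mind(S.w[3 * i] - S.w[3 * pivot], S.L[0]);
      rel_old[3 * a + 1] = mind(S.w[3 * i + 1] - S.w[3 * pivot + 1], S.L[1]);
      rel_old[3 * a + 2] = mind(S.w[3 * i + 2] - S.w[3 * pivot + 2], S.L[2]);
      double proj = rel_old[3 * a] * nx + rel_old[3 * a + 1] * ny +
                    rel_old[3 * a + 2] * nz;
      for (int d = 0; d < 3; ++d)
        rel_ref[3 * a + d] = rel_old[3 * a + d] - 2 * proj * nrm[d];
    }
    double piv[3] = {S.w[3 * pivot], S.w[3 * pivot + 1], S.w[3 * pivot + 2]};
    double e_old = local_energy(S, ff, moved, 2, mol);
    double cand[6], trial[16 * 6], wtrial[16];
    double Wf = 0.0;
    for (int k = 0; k < K; ++k) {
      double phi = 2.0 * M_PI * u01(smix(seed ^ smix(ctr++)));
      for (int a = 0; a < 2; ++a) {
        double out[3];
        rot_about(nrm, phi, &rel_ref[3 * a], out);
        for (int d = 0; d < 3; ++d) cand[3 * a + d] = piv[d] + out[d];
      }
      double e = local_energy_at(S, ff, moved, cand, mol);
      wtrial[k] = (e < 1e29) ? exp(-(e - e_old) / kT) : 0.0;
      Wf += wtrial[k];
      for (int d = 0; d < 6; ++d) trial[6 * k + d] = cand[d];
    }
    if (Wf <= 0) continue;
    // select a forward trial
    double pick = u01(smix(seed ^ smix(ctr++))) * Wf;
    int sel = 0;
    for (; sel < K - 1; ++sel) { pick -= wtrial[sel]; if (pick <= 0) break; }
    // reverse weights: current position plus K-1 rotations of it
    double Wr = 1.0; // exp(-(e_old - e_old)/kT)
    for (int k = 0; k < K - 1; ++k) {
      double phi = 2.0 * M_PI * u01(smix(seed ^ smix(ctr++)));
      for (int a = 0; a < 2; ++a) {
        double out[3];
        rot_about(nrm, phi, &rel_old[3 * a], out);
        for (int d = 0; d < 3; ++d) cand[3 * a + d] = piv[d] + out[d];
      }
      double e = local_energy_at(S, ff, moved, cand, mol);
      Wr += (e < 1e29) ? exp(-(e - e_old) / kT) : 0.0;
    }
    double u = u01(smix(seed ^ smix(ctr++)));
    if (u < Wf / Wr) {
      accepted++;
      // re-anchor unwrapped coordinates to the pivot's unwrapped position
      for (int a = 0; a < 2; ++a) {
        int i = moved[a];
        for (int d = 0; d < 3; ++d) {
          double q = trial[6 * sel + 3 * a + d] - piv[d];
          S.w[3 * i + d] = piv[d] + q;
          S.x[3 * i + d] = S.x[3 * pivot + d] + q;
        }
      }
    }
  }
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = S.x[3 * i + d];
  return List::create(_["positions"] = out, _["accepted"] = accepted,
                      _["counter"] = (double)ctr);
}
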