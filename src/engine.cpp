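// Molecular-dynamics core: shifted nonbonded kernels, neighbor lists,
// leapfrog + SHAKE, Berendsen weak coupling, soft-core decoupling.
// Units: nm, ps, amu, e, K, kJ/mol; pressure in bar.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <sstream>
using namespace Rcpp;

static const double F_ELEC   = 138.935485;  // kJ mol-1 nm e-2
static const double KB_MD    = 0.00831446;  // kJ mol-1 K-1
static const double PRESFAC  = 16.6054;     // bar per (kJ mol-1 nm-3)
static const double FIELDFAC = 96.4853;     // (kJ mol-1 nm-1 e-1) per (V nm-1)

// ---------------------------------------------------------------------------
// Polynomial shift for a 1/r^p term (GROMACS form): the force gets
// A(r-r1)^2 + B(r-r1)^3 added beyond r1 so that force and its derivative
// vanish at rc; the potential is offset so it vanishes at rc and is
// constant-shifted below r1.
struct ShiftCoef { double A, B, C; };

static ShiftCoef shift_coef(int p, double r1, double rc) {
  double D = rc - r1;
  ShiftCoef s;
  s.A = -double(p) * ((p + 4) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * D * D);
  s.B =  double(p) * ((p + 3) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * D * D * D);
  s.C = 1.0 / std::pow(rc, p) - s.A / 3.0 * D * D * D - s.B / 4.0 * D * D * D * D;
  return s;
}

// phi = shifted 1/r^p, fmag = -d(phi)/dr (generic form, used off hot path)
static inline void shift_eval(double r, int p, double r1, double rc,
                              const ShiftCoef &s, double &phi, double &fmag) {
  if (r >= rc) { phi = 0.0; fmag = 0.0; return; }
  double rp = std::pow(r, p);
  phi  = 1.0 / rp - s.C;
  fmag = p / (rp * r);
  if (r > r1) {
    double d = r - r1;
    phi  -= s.A / 3.0 * d * d * d + s.B / 4.0 * d * d * d * d;
    fmag += s.A * d * d + s.B * d * d * d;
  }
}

struct PairCoefs {
  double rcut, rshift_lj;
  ShiftCoef s12, s6, s1;
};

static PairCoefs make_coefs(double rshift_lj, double rcut) {
  PairCoefs pc;
  pc.rcut = rcut; pc.rshift_lj = rshift_lj;
  pc.s12 = shift_coef(12, rshift_lj, rcut);
  pc.s6  = shift_coef(6,  rshift_lj, rcut);
  pc.s1  = shift_coef(1,  0.0,       rcut);
  return pc;
}

// Shifted LJ from precomputed c12 = 4 eps sig^12, c6 = 4 eps sig^6.
// E, and F = -dE/dr (positive = repulsive).
static inline void lj_kernel_c(double r, double c12, double c6,
                               const PairCoefs &pc, double &E, double &F) {
  if (r >= pc.rcut) { E = 0.0; F = 0.0; return; }
  double ir = 1.0 / r, ir2 = ir * ir;
  double ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
  double p12 = ir12 - pc.s12.C, f12 = 12.0 * ir12 * ir;
  double p6  = ir6  - pc.s6.C,  f6  = 6.0 * ir6 * ir;
  if (r > pc.rshift_lj) {
    double d = r - pc.rshift_lj, d2 = d * d, d3 = d2 * d;
    p12 -= pc.s12.A / 3.0 * d3 + pc.s12.B / 4.0 * d3 * d;
    f12 += pc.s12.A * d2 + pc.s12.B * d3;
    p6  -= pc.s6.A / 3.0 * d3 + pc.s6.B / 4.0 * d3 * d;
    f6  += pc.s6.A * d2 + pc.s6.B * d3;
  }
  E = c12 * p12 - c6 * p6;
  F = c12 * f12 - c6 * f6;
}

static inline void lj_kernel(double r, double eps, double sig, const PairCoefs &pc,
                             double &E, double &F) {
  double s2 = sig * sig, s6 = s2 * s2 * s2;
  lj_kernel_c(r, 4.0 * eps * s6 * s6, 4.0 * eps * s6, pc, E, F);
}

static inline void coul_kernel(double r, double qq_scaled, const PairCoefs &pc,
                               double &E, double &F) {
  if (r >= pc.rcut) { E = 0.0; F = 0.0; return; }
  double ir = 1.0 / r;
  double d2 = r * r, d3 = d2 * r;
  E = qq_scaled * (ir - pc.s1.A / 3.0 * d3 - pc.s1.B / 4.0 * d3 * r - pc.s1.C);
  F = qq_scaled * (ir * ir + pc.s1.A * d2 + pc.s1.B * d3);
}

// Soft-core separation-shifted form. The plain pair Hamiltonian V(r) (LJ with
// pair sigma + Coulomb, both shifted) is evaluated at
//   rA = (r^6 + alpha * sig_ref^6 * (1 - lambda))^(1/6)
// and scaled by lambda. lambda = 1 recovers the plain kernels exactly.
static inline void softcore_kernel(double r, double lambda, bool has_lj,
                                   double eps, double sig, double qq_scaled,
                                   double alpha, double sig_q, const PairCoefs &pc,
                                   double &E, double &F, double &dHdl) {
  if (lambda <= 0.0) { E = 0.0; F = 0.0; dHdl = 0.0; }
  E = 0.0; F = 0.0; dHdl = 0.0;
  // LJ part
  if (has_lj) {
    double s6 = std::pow(sig, 6);
    double rA6 = std::pow(r, 6) + alpha * s6 * (1.0 - lambda);
    double rA = std::pow(rA6, 1.0 / 6.0);
    double e, f;
    lj_kernel(rA, eps, sig, pc, e, f);
    double r5_over_rA5 = std::pow(r, 5) / std::pow(rA, 5);
    E    += lambda * e;
    F    += lambda * f * r5_over_rA5;
    dHdl += e + lambda * f * alpha * s6 / (6.0 * std::pow(rA, 5));
  }
  // Coulomb part (reference sigma for the radius shift)
  if (qq_scaled != 0.0) {
    double s6 = std::pow(sig_q, 6);
    double rA6 = std::pow(r, 6) + alpha * s6 * (1.0 - lambda);
    double rA = std::pow(rA6, 1.0 / 6.0);
    double e, f;
    coul_kernel(rA, qq_scaled, pc, e, f);
    double r5_over_rA5 = std::pow(r, 5) / std::pow(rA, 5);
    E    += lambda * e;
    F    += lambda * f * r5_over_rA5;
    dHdl += e + lambda * f * alpha * s6 / (6.0 * std::pow(rA, 5));
  }
  if (lambda <= 0.0) { E = 0.0; F = 0.0; } // fully decoupled: no interaction
}

// ---------------------------------------------------------------------------
// Exported scalar/vector kernels (used by the forcefield / free_energy layer
// and by the engine itself, so both routes share one implementation).

// [[Rcpp::export]]
List ljshift_eval_cpp(NumericVector r, double eps, double sigma,
                      double r_shift, double r_cut) {
  PairCoefs pc = make_coefs(r_shift, r_cut);
  int n = r.size();
  NumericVector E(n), F(n);
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("lj_shifted: r must be > 0");
    lj_kernel(r[i], eps, sigma, pc, E[i], F[i]);
  }
  return List::create(_["energy"] = E, _["force"] = F);
}

// [[Rcpp::export]]
List coulshift_eval_cpp(NumericVector r, double qa, double qb,
                        double eps_r, double r_cut) {
  PairCoefs pc = make_coefs(0.9 * r_cut, r_cut); // LJ part unused
  double qq = F_ELEC * qa * qb / eps_r;
  int n = r.size();
  NumericVector E(n), F(n);
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("coulomb_shifted: r must be > 0");
    coul_kernel(r[i], qq, pc, E[i], F[i]);
  }
  return List::create(_["energy"] = E, _["force"] = F);
}

// [[Rcpp::export]]
List softcore_eval_cpp(NumericVector r, double lambda, bool has_lj,
                       double eps, double sigma, double qa, double qb,
                       double eps_r, double alpha, double sigma_q,
                       double r_shift, double r_cut) {
  PairCoefs pc = make_coefs(r_shift, r_cut);
  double qq = F_ELEC * qa * qb / eps_r;
  int n = r.size();
  NumericVector E(n), F(n), D(n);
  for (int i = 0; i < n; ++i)
    softcore_kernel(r[i], lambda, has_lj, eps, sigma, qq, alpha, sigma_q, pc,
                    E[i], F[i], D[i]);
  return List::create(_["energy"] = E, _["force"] = F, _["dHdl"] = D);
}

// ---------------------------------------------------------------------------
// System container decoded from the R side (0-based indices everywhere).

struct Sys {
  int n;
  std::vector<double> pos, vel, mass, charge;
  double box[3], ibox[3];
  std::vector<int> ljt;        // LJ type index, -1 = no LJ
  int nlj;
  std::vector<double> eps, sig; // nlj x nlj, row-major
  std::vector<double> c12, c6;  // precomputed 4 eps sig^12 / sig^6
  // bonded terms
  std::vector<int> coni, conj;  std::vector<double> cond;
  std::vector<int> angi, angj, angk, angf; std::vector<double> ang0, angK;
  std::vector<int> bndi, bndj;  std::vector<double> bnd0, bndk;
  std::vector<int> molid;
  std::vector<bool> solute;
  // exclusions: per-site sorted partner lists
  std::vector<std::vector<int>> excl;
  bool any_solute;
  // electrostatic charge groups (one per charged molecule): interactions are
  // gated by the distance between group center sites (the bead core), the
  // convention the model was parameterized with
  std::vector<int> grp_center;               // center site per group
  std::vector<std::vector<int>> grp_mem;     // charged member sites per group
  std::vector<int> center2grp;               // site -> group index (-1)
};

static Sys decode_sys(List sys, bool site_gating) {
  Sys S;
  NumericMatrix pos = sys["pos"], vel = sys["vel"];
  S.n = pos.nrow();
  S.pos.resize(3 * S.n); S.vel.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) { S.pos[3*i+d] = pos(i,d); S.vel[3*i+d] = vel(i,d); }
  NumericVector box = sys["box"];
  for (int d = 0; d < 3; ++d) { S.box[d] = box[d]; S.ibox[d] = 1.0 / box[d]; }
  S.mass  = as<std::vector<double>>(sys["mass"]);
  S.charge= as<std::vector<double>>(sys["charge"]);
  S.ljt   = as<std::vector<int>>(sys["ljt"]);
  S.nlj   = as<int>(sys["nlj"]);
  S.eps   = as<std::vector<double>>(sys["eps"]);
  S.sig   = as<std::vector<double>>(sys["sig"]);
  S.c12.resize(S.eps.size()); S.c6.resize(S.eps.size());
  for (size_t k = 0; k < S.eps.size(); ++k) {
    double s2 = S.sig[k] * S.sig[k], s6 = s2 * s2 * s2;
    S.c6[k] = 4.0 * S.eps[k] * s6;
    S.c12[k] = 4.0 * S.eps[k] * s6 * s6;
  }
  S.coni  = as<std::vector<int>>(sys["coni"]);
  S.conj  = as<std::vector<int>>(sys["conj"]);
  S.cond  = as<std::vector<double>>(sys["cond"]);
  S.angi  = as<std::vector<int>>(sys["angi"]);
  S.angj  = as<std::vector<int>>(sys["angj"]);
  S.angk  = as<std::vector<int>>(sys["angk"]);
  S.ang0  = as<std::vector<double>>(sys["ang0"]);
  S.angK  = as<std::vector<double>>(sys["angK"]);
  S.angf  = as<std::vector<int>>(sys["angf"]);
  S.bndi  = as<std::vector<int>>(sys["bndi"]);
  S.bndj  = as<std::vector<int>>(sys["bndj"]);
  S.bnd0  = as<std::vector<double>>(sys["bnd0"]);
  S.bndk  = as<std::vector<double>>(sys["bndk"]);
  S.molid = as<std::vector<int>>(sys["molid"]);
  LogicalVector sol = sys["solute"];
  S.solute.resize(S.n);
  S.any_solute = false;
  for (int i = 0; i < S.n; ++i) { S.solute[i] = sol[i]; if (sol[i]) S.any_solute = true; }
  IntegerVector ei = sys["excl_i"], ej = sys["excl_j"];
  S.excl.assign(S.n, {});
  for (int k = 0; k < ei.size(); ++k) {
    S.excl[ei[k]].push_back(ej[k]);
    S.excl[ej[k]].push_back(ei[k]);
  }
  for (auto &v : S.excl) std::sort(v.begin(), v.end());
  // build charge groups from molecule ids
  S.center2grp.assign(S.n, -1);
  {
    int nmol = 0;
    for (int i = 0; i < S.n; ++i) nmol = std::max(nmol, S.molid[i] + 1);
    std::vector<std::vector<int>> mol_sites(nmol);
    for (int i = 0; i < S.n; ++i) mol_sites[S.molid[i]].push_back(i);
    for (int m = 0; m < nmol; ++m) {
      std::vector<int> charged;
      for (int i : mol_sites[m]) if (S.charge[i] != 0.0) charged.push_back(i);
      if (charged.empty()) continue;
      if (site_gating) {
        // strictly site-based cutoff: every charged site is its own group
        for (int i : charged) {
          S.center2grp[i] = (int)S.grp_center.size();
          S.grp_center.push_back(i);
          S.grp_mem.push_back(std::vector<int>{i});
        }
      } else {
        int center = -1;
        for (int i : mol_sites[m]) if (S.ljt[i] >= 0) { center = i; break; }
        if (center < 0) center = charged[0];
        S.center2grp[center] = (int)S.grp_center.size();
        S.grp_center.push_back(center);
        S.grp_mem.push_back(charged);
      }
    }
  }
  return S;
}

static inline bool excluded(const Sys &S, int i, int j) {
  const std::vector<int> &e = S.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

// branch-free nearest integer (|x| is always a few box lengths here);
// avoids the std::round libcall on baseline x86-64 targets
static inline double fast_round(double x) {
  return (double)(long long)(x + (x >= 0 ? 0.5 : -0.5));
}

static inline void min_image(const double *box, const double *ibox,
                             double &dx, double &dy, double &dz) {
  dx -= box[0] * fast_round(dx * ibox[0]);
  dy -= box[1] * fast_round(dy * ibox[1]);
  dz -= box[2] * fast_round(dz * ibox[2]);
}

// ---------------------------------------------------------------------------
// Neighbor (Verlet pair) lists over a subset of sites; cell grid when the box
// allows >= 3 cells per dimension, brute force otherwise.

struct PairList { std::vector<int> pi, pj; };

static void build_pairs(const Sys &S, const std::vector<int> &sel,
                        double rlist, PairList &pl) {
  pl.pi.clear(); pl.pj.clear();
  int m = sel.size();
  double rl2 = rlist * rlist;
  int nc[3];
  bool cells_ok = true;
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(S.box[d] / rlist));
    if (nc[d] < 3) cells_ok = false;
  }
  if (!cells_ok || m < 200) {
    for (int a = 0; a < m; ++a) {
      int i = sel[a];
      for (int b = a + 1; b < m; ++b) {
        int j = sel[b];
        double dx = S.pos[3*i] - S.pos[3*j], dy = S.pos[3*i+1] - S.pos[3*j+1],
               dz = S.pos[3*i+2] - S.pos[3*j+2];
        min_image(S.box, S.ibox, dx, dy, dz);
        if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(S, i, j)) {
          pl.pi.push_back(i); pl.pj.push_back(j);
        }
      }
    }
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> cell(ncell);
  auto cidx = [&](double x, int d) {
    double w = x / S.box[d];
    w -= std::floor(w);
    int c = (int)(w * nc[d]);
    if (c >= nc[d]) c = nc[d] - 1;
    return c;
  };
  for (int a = 0; a < m; ++a) {
    int i = sel[a];
    int cx = cidx(S.pos[3*i], 0), cy = cidx(S.pos[3*i+1], 1), cz = cidx(S.pos[3*i+2], 2);
    cell[(cz * nc[1] + cy) * nc[0] + cx].push_back(i);
  }
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c0 = (cz * nc[1] + cy) * nc[0] + cx;
        const std::vector<int> &v0 = cell[c0];
        for (int oz = -1; oz <= 1; ++oz)
          for (int oy = -1; oy <= 1; ++oy)
            for (int ox = -1; ox <= 1; ++ox) {
              int gx = (cx + ox + nc[0]) % nc[0];
              int gy = (cy + oy + nc[1]) % nc[1];
              int gz = (cz + oz + nc[2]) % nc[2];
              int c1 = (gz * nc[1] + gy) * nc[0] + gx;
              if (c1 < c0) continue;
              const std::vector<int> &v1 = cell[c1];
              for (size_t a = 0; a < v0.size(); ++a) {
                int i = v0[a];
                size_t bstart = (c1 == c0) ? a + 1 : 0;
                for (size_t b = bstart; b < v1.size(); ++b) {
                  int j = v1[b];
                  double dx = S.pos[3*i] - S.pos[3*j], dy = S.pos[3*i+1] - S.pos[3*j+1],
                         dz = S.pos[3*i+2] - S.pos[3*j+2];
                  min_image(S.box, S.ibox, dx, dy, dz);
                  if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(S, i, j)) {
                    pl.pi.push_back(std::min(i, j)); pl.pj.push_back(std::max(i, j));
                  }
                }
              }
            }
      }
}

// ---------------------------------------------------------------------------
// Force evaluation. Fills force array, per-term energies, virial tensor and
// the soft-core dH/dlambda accumulator.

struct ForceOut {
  std::vector<double> f;
  double E_lj, E_coul, E_bond, E_angle, E_field, E_bias, dHdl;
  double W[9]; // virial tensor sum r_ij (x) f_ij, pair/bonded terms only
};

struct Opts {
  double rcut, rshift, eps_r, Ez, lambda, sc_alpha, sc_sigma_q;
  double umb_k, umb_z0;
  bool site_gating;
};

static void eval_forces(const Sys &S, const Opts &o, const PairCoefs &pc,
                        const PairList &plj, const PairList &plc, ForceOut &out) {
  out.f.assign(3 * S.n, 0.0);
  out.E_lj = out.E_coul = out.E_bond = out.E_angle = out.E_field = out.E_bias = 0.0;
  out.dHdl = 0.0;
  for (int k = 0; k < 9; ++k) out.W[k] = 0.0;
  double rc2 = o.rcut * o.rcut;

  auto add_pair_force = [&](int i, int j, double dx, double dy, double dz,
                            double Fmag_over_r) {
    double fx = Fmag_over_r * dx, fy = Fmag_over_r * dy, fz = Fmag_over_r * dz;
    out.f[3*i]   += fx; out.f[3*i+1] += fy; out.f[3*i+2] += fz;
    out.f[3*j]   -= fx; out.f[3*j+1] -= fy; out.f[3*j+2] -= fz;
    out.W[0] += dx * fx; out.W[1] += dx * fy; out.W[2] += dx * fz;
    out.W[3] += dy * fx; out.W[4] += dy * fy; out.W[5] += dy * fz;
    out.W[6] += dz * fx; out.W[7] += dz * fy; out.W[8] += dz * fz;
  };

  bool sc_active = S.any_solute && o.lambda < 1.0;

  // LJ pairs
  for (size_t k = 0; k < plj.pi.size(); ++k) {
    int i = plj.pi[k], j = plj.pj[k];
    double dx = S.pos[3*i] - S.pos[3*j], dy = S.pos[3*i+1] - S.pos[3*j+1],
           dz = S.pos[3*i+2] - S.pos[3*j+2];
    min_image(S.box, S.ibox, dx, dy, dz);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-5) {
      std::ostringstream msg;
      msg << "overlapping sites " << i + 1 << " and " << j + 1
          << " (molecules " << S.molid[i] + 1 << ", " << S.molid[j] + 1 << ")";
      stop(msg.str());
    }
    int tt = S.ljt[i] * S.nlj + S.ljt[j];
    double E, F;
    if (sc_active && (S.solute[i] != S.solute[j])) {
      double dH;
      softcore_kernel(r, o.lambda, true, S.eps[tt], S.sig[tt], 0.0,
                      o.sc_alpha, o.sc_sigma_q, pc, E, F, dH);
      out.dHdl += dH;
    } else {
      lj_kernel_c(r, S.c12[tt], S.c6[tt], pc, E, F);
    }
    out.E_lj += E;
    add_pair_force(i, j, dx, dy, dz, F / r);
  }

  // Coulomb: group pairs gated by center distance, expanded to member sites
  for (size_t k = 0; k < plc.pi.size(); ++k) {
    int ci = plc.pi[k], cj = plc.pj[k];
    double dcx = S.pos[3*ci] - S.pos[3*cj], dcy = S.pos[3*ci+1] - S.pos[3*cj+1],
           dcz = S.pos[3*ci+2] - S.pos[3*cj+2];
    double rx = dcx, ry = dcy, rz = dcz;
    min_image(S.box, S.ibox, rx, ry, rz);
    if (rx*rx + ry*ry + rz*rz >= rc2) continue;
    // periodic shift chosen by the center pair, applied to all member pairs
    double shx = rx - dcx, shy = ry - dcy, shz = rz - dcz;
    const std::vector<int> &ma = S.grp_mem[S.center2grp[ci]];
    const std::vector<int> &mb = S.grp_mem[S.center2grp[cj]];
    for (int i : ma) for (int j : mb) {
      if (S.molid[i] == S.molid[j] && excluded(S, i, j)) continue;
      double dx = S.pos[3*i] - S.pos[3*j] + shx;
      double dy = S.pos[3*i+1] - S.pos[3*j+1] + shy;
      double dz = S.pos[3*i+2] - S.pos[3*j+2] + shz;
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-5) {
        std::ostringstream msg;
        msg << "overlapping charged sites " << i + 1 << " and " << j + 1
            << " (molecules " << S.molid[i] + 1 << ", " << S.molid[j] + 1 << ")";
        stop(msg.str());
      }
      double qq = F_ELEC * S.charge[i] * S.charge[j] / o.eps_r;
      double E, F;
      if (sc_active && (S.solute[i] != S.solute[j])) {
        double dH;
        softcore_kernel(r, o.lambda, false, 0.0, 0.47, qq, o.sc_alpha,
                        o.sc_sigma_q, pc, E, F, dH);
        out.dHdl += dH;
      } else {
        coul_kernel(r, qq, pc, E, F);
      }
      out.E_coul += E;
      add_pair_force(i, j, dx, dy, dz, F / r);
    }
  }

  // Harmonic bonds
  for (size_t k = 0; k < S.bndi.size(); ++k) {
    int i = S.bndi[k], j = S.bndj[k];
    double dx = S.pos[3*i] - S.pos[3*j], dy = S.pos[3*i+1] - S.pos[3*j+1],
           dz = S.pos[3*i+2] - S.pos[3*j+2];
    min_image(S.box, S.ibox, dx, dy, dz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dev = r - S.bnd0[k];
    out.E_bond += 0.5 * S.bndk[k] * dev * dev;
    double F = -S.bndk[k] * dev; // along +r = repulsive direction
    add_pair_force(i, j, dx, dy, dz, F / r);
  }

  // Harmonic angles (in theta), theta0 = 0 regularized via sin floor
  for (size_t k = 0; k < S.angi.size(); ++k) {
    int i = S.angi[k], j = S.angj[k], kk = S.angk[k];
    double ax = S.pos[3*i] - S.pos[3*j], ay = S.pos[3*i+1] - S.pos[3*j+1],
           az = S.pos[3*i+2] - S.pos[3*j+2];
    double bx = S.pos[3*kk] - S.pos[3*j], by = S.pos[3*kk+1] - S.pos[3*j+1],
           bz = S.pos[3*kk+2] - S.pos[3*j+2];
    min_image(S.box, S.ibox, ax, ay, az);
    min_image(S.box, S.ibox, bx, by, bz);
    double la = std::sqrt(ax*ax + ay*ay + az*az);
    double lb = std::sqrt(bx*bx + by*by + bz*bz);
    double ct = (ax*bx + ay*by + az*bz) / (la * lb);
    ct = std::max(-1.0, std::min(1.0, ct));
    double coef; // = -dV/dcos(theta)
    if (S.angf[k] == 2) {
      // cosine-harmonic (G96) form: V = K/2 (cos th - cos th0)^2
      double dc = ct - std::cos(S.ang0[k]);
      out.E_angle += 0.5 * S.angK[k] * dc * dc;
      coef = -S.angK[k] * dc;
    } else {
      // harmonic in theta with the sin regularization near theta0 = 0
      double th = std::acos(ct);
      double dth = th - S.ang0[k];
      out.E_angle += 0.5 * S.angK[k] * dth * dth;
      double st = std::sin(th);
      if (th < 1e-4 && S.ang0[k] == 0.0) coef = S.angK[k];
      else coef = S.angK[k] * dth / std::max(st, 1e-6);
    }
    // F_i = coef * d(cos)/d r_i etc.
    double uax = ax / la, uay = ay / la, uaz = az / la;
    double ubx = bx / lb, uby = by / lb, ubz = bz / lb;
    double fix = coef * (ubx - ct * uax) / la;
    double fiy = coef * (uby - ct * uay) / la;
    double fiz = coef * (ubz - ct * uaz) / la;
    double fkx = coef * (uax - ct * ubx) / lb;
    double fky = coef * (uay - ct * uby) / lb;
    double fkz = coef * (uaz - ct * ubz) / lb;
    out.f[3*i]   += fix; out.f[3*i+1]  += fiy; out.f[3*i+2]  += fiz;
    out.f[3*kk]  += fkx; out.f[3*kk+1] += fky; out.f[3*kk+2] += fkz;
    out.f[3*j]   -= fix + fkx; out.f[3*j+1] -= fiy + fky; out.f[3*j+2] -= fiz + fkz;
    // virial: sum over sites of r (x) F with j as local origin
    out.W[0] += ax * fix + bx * fkx; out.W[1] += ax * fiy + bx * fky;
    out.W[2] += ax * fiz + bx * fkz;
    out.W[3] += ay * fix + by * fkx; out.W[4] += ay * fiy + by * fky;
    out.W[5] += ay * fiz + by * fkz;
    out.W[6] += az * fix + bz * fkx; out.W[7] += az * fiy + bz * fky;
    out.W[8] += az * fiz + bz * fkz;
  }

  // Uniform external field along z (external force: no virial contribution)
  if (o.Ez != 0.0) {
    for (int i = 0; i < S.n; ++i) {
      if (S.charge[i] == 0.0) continue;
      double fz = S.charge[i] * o.Ez * FIELDFAC;
      out.f[3*i+2] += fz;
      out.E_field  -= fz * S.pos[3*i+2];
    }
  }

  // Umbrella bias on solute center-of-mass z
  if (o.umb_k > 0.0 && S.any_solute) {
    double mz = 0.0, mtot = 0.0;
    for (int i = 0; i < S.n; ++i) if (S.solute[i]) {
      mz += S.mass[i] * S.pos[3*i+2]; mtot += S.mass[i];
    }
    double zc = mz / mtot;
    double dzc = zc - o.umb_z0;
    dzc -= S.box[2] * fast_round(dzc * S.ibox[2]);
    out.E_bias += 0.5 * o.umb_k * dzc * dzc;
    double Fz = -o.umb_k * dzc;
    for (int i = 0; i < S.n; ++i) if (S.solute[i])
      out.f[3*i+2] += Fz * S.mass[i] / mtot;
  }
}

static Opts decode_opts(List opt) {
  Opts o;
  o.rcut   = as<double>(opt["r_cut"]);
  o.rshift = as<double>(opt["r_shift_lj"]);
  o.eps_r  = as<double>(opt["eps_r"]);
  o.Ez     = as<double>(opt["field_z"]);
  o.lambda = as<double>(opt["lambda"]);
  o.sc_alpha = as<double>(opt["sc_alpha"]);
  o.sc_sigma_q = as<double>(opt["sc_sigma_q"]);
  o.umb_k  = as<double>(opt["umbrella_k"]);
  o.umb_z0 = as<double>(opt["umbrella_z0"]);
  o.site_gating = as<bool>(opt["site_gating"]);
  return o;
}

static void make_selections(const Sys &S, std::vector<int> &lj_sel,
                            std::vector<int> &q_sel) {
  lj_sel.clear(); q_sel.clear();
  for (int i = 0; i < S.n; ++i)
    if (S.ljt[i] >= 0) lj_sel.push_back(i);
  q_sel = S.grp_center;  // electrostatics paired by group centers
}

// [[Rcpp::export]]
List compute_forces_cpp(List sys, List opt) {
  Opts o = decode_opts(opt);
  Sys S = decode_sys(sys, o.site_gating);
  PairCoefs pc = make_coefs(o.rshift, o.rcut);
  std::vector<int> lj_sel, q_sel;
  make_selections(S, lj_sel, q_sel);
  PairList plj, plc;
  build_pairs(S, lj_sel, o.rcut, plj);
  build_pairs(S, q_sel, o.rcut, plc);
  ForceOut out;
  eval_forces(S, o, pc, plj, plc, out);
  NumericMatrix f(S.n, 3), W(3, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) f(i, d) = out.f[3*i+d];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) W(a, b) = out.W[3*a+b];
  return List::create(
    _["forces"] = f,
    _["energies"] = NumericVector::create(
      _["lj"] = out.E_lj, _["coulomb"] = out.E_coul, _["bond"] = out.E_bond,
      _["angle"] = out.E_angle, _["field"] = out.E_field, _["bias"] = out.E_bias),
    _["virial"] = W,
    _["dHdl"] = out.dHdl);
}

// ---------------------------------------------------------------------------
// SHAKE: iterative pair corrections against reference geometry.
// Returns total multipliers per constraint (for the constraint virial).

static int shake(const Sys &S, const std::vector<double> &ref,
                 std::vector<double> &pos, double tol, int maxit,
                 std::vector<double> &gtot) {
  size_t nc = S.coni.size();
  gtot.assign(nc, 0.0);
  if (nc == 0) return 0;
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (size_t c = 0; c < nc; ++c) {
      int i = S.coni[c], j = S.conj[c];
      double d0 = S.cond[c];
      double sx = pos[3*i] - pos[3*j], sy = pos[3*i+1] - pos[3*j+1],
             sz = pos[3*i+2] - pos[3*j+2];
      min_image(S.box, S.ibox, sx, sy, sz);
      double s2 = sx*sx + sy*sy + sz*sz;
      double diff = s2 - d0 * d0;
      if (std::fabs(diff) > 2.0 * d0 * tol * d0) done = false; else continue;
      double rx = ref[3*i] - ref[3*j], ry = ref[3*i+1] - ref[3*j+1],
             rz = ref[3*i+2] - ref[3*j+2];
      min_image(S.box, S.ibox, rx, ry, rz);
      double sr = sx*rx + sy*ry + sz*rz;
      double im = 1.0 / S.mass[i] + 1.0 / S.mass[j];
      double g = diff / (2.0 * sr * im);
      gtot[c] += g;
      pos[3*i]   -= g * rx / S.mass[i];
      pos[3*i+1] -= g * ry / S.mass[i];
      pos[3*i+2] -= g * rz / S.mass[i];
      pos[3*j]   += g * rx / S.mass[j];
      pos[3*j+1] += g * ry / S.mass[j];
      pos[3*j+2] += g * rz / S.mass[j];
    }
    if (done) return it;
  }
  return -1;
}

// [[Rcpp::export]]
NumericMatrix shake_cpp(NumericMatrix ref, NumericMatrix pos, NumericVector box,
                        IntegerVector ci, IntegerVector cj, NumericVector d0,
                        NumericVector mass, double tol, int maxit) {
  Sys S;
  S.n = pos.nrow();
  S.pos.resize(3 * S.n);
  S.mass = as<std::vector<double>>(mass);
  for (int d = 0; d < 3; ++d) { S.box[d] = box[d]; S.ibox[d] = 1.0 / box[d]; }
  S.coni = as<std::vector<int>>(ci);
  S.conj = as<std::vector<int>>(cj);
  S.cond = as<std::vector<double>>(d0);
  std::vector<double> refv(3 * S.n), posv(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) { refv[3*i+d] = ref(i, d); posv[3*i+d] = pos(i, d); }
  std::vector<double> gtot;
  int it = shake(S, refv, posv, tol, maxit, gtot);
  if (it < 0) {
    // identify first offending constraint for the error message
    stop("constraint solver failed to converge within max iterations");
  }
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = posv[3*i+d];
  return out;
}

// ---------------------------------------------------------------------------
// MD driver: leapfrog + SHAKE + Berendsen weak coupling.

// ensembles: 0 NVE, 1 NVT, 2 NPT (isotropic), 3 NPzAT (z only), 4 NPzPxyT
// [[Rcpp::export]]
List run_md_cpp(List sys, List prot) {
  Opts o = decode_opts(prot);
  Sys S = decode_sys(sys, o.site_gating);
  PairCoefs pc = make_coefs(o.rshift, o.rcut);

  double dt      = as<double>(prot["dt"]);
  int    nsteps  = as<int>(prot["n_steps"]);
  int    ens     = as<int>(prot["ensemble_code"]);
  double T0      = as<double>(prot["temperature"]);
  double tauT    = as<double>(prot["tau_t"]);
  double P0      = as<double>(prot["pressure"]);
  double tauP    = as<double>(prot["tau_p"]);
  double kappa   = as<double>(prot["compressibility"]);
  double skin    = as<double>(prot["skin"]);
  int    nstlist = as<int>(prot["nstlist"]);
  int    logst   = as<int>(prot["log_stride"]);
  int    trajst  = as<int>(prot["traj_stride"]);
  int    comst   = as<int>(prot["com_stride"]);
  double sh_tol  = as<double>(prot["shake_tol"]);
  int    sh_max  = as<int>(prot["shake_maxit"]);

  int n = S.n;
  size_t ncons = S.coni.size();
  int ndf = 3 * n - (int)ncons - (comst > 0 ? 3 : 0);
  if (ndf < 1) ndf = 1;

  std::vector<int> lj_sel, q_sel;
  make_selections(S, lj_sel, q_sel);
  PairList plj, plc;
  // nstlist > 0: fixed-interval updates with list radius = cutoff (the
  // parameterization protocol); nstlist = 0: displacement-triggered Verlet
  // lists with the skin
  double rlist = nstlist > 0 ? o.rcut : o.rcut + skin;
  std::vector<double> pos_at_build(S.pos);
  build_pairs(S, lj_sel, rlist, plj);
  build_pairs(S, q_sel, rlist, plc);

  ForceOut fo;
  std::vector<double> vold(3 * n), oldpos(3 * n), gtot;
  int nlog = nsteps / std::max(logst, 1) + 1;
  NumericMatrix log(nlog, 22);
  int logrow = 0;
  List frames;
  std::vector<double> frame_times;
  std::vector<double> frame_boxes;

  double mtot = 0.0;
  for (int i = 0; i < n; ++i) mtot += S.mass[i];

  for (int step = 0; step < nsteps; ++step) {
    // neighbor list validity
    bool rebuild;
    if (nstlist > 0) {
      rebuild = (step % nstlist == 0);
    } else {
      double maxd2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double dx = S.pos[3*i] - pos_at_build[3*i],
               dy = S.pos[3*i+1] - pos_at_build[3*i+1],
               dz = S.pos[3*i+2] - pos_at_build[3*i+2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 > maxd2) maxd2 = d2;
      }
      rebuild = (step == 0 || maxd2 > 0.25 * skin * skin);
    }
    if (rebuild) {
      build_pairs(S, lj_sel, rlist, plj);
      build_pairs(S, q_sel, rlist, plc);
      pos_at_build = S.pos;
    }

    eval_forces(S, o, pc, plj, plc, fo);
    double Epot = fo.E_lj + fo.E_coul + fo.E_bond + fo.E_angle + fo.E_field + fo.E_bias;

    // leapfrog velocity update
    vold = S.vel;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        S.vel[3*i+d] += fo.f[3*i+d] / S.mass[i] * dt;

    // COM motion removal
    if (comst > 0 && step % comst == 0) {
      double px = 0, py = 0, pz = 0;
      for (int i = 0; i < n; ++i) {
        px += S.mass[i] * S.vel[3*i]; py += S.mass[i] * S.vel[3*i+1];
        pz += S.mass[i] * S.vel[3*i+2];
      }
      px /= mtot; py /= mtot; pz /= mtot;
      for (int i = 0; i < n; ++i) {
        S.vel[3*i] -= px; S.vel[3*i+1] -= py; S.vel[3*i+2] -= pz;
      }
    }

    // on-step kinetic estimate (average of half-step velocities)
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      double vx = 0.5 * (vold[3*i] + S.vel[3*i]);
      double vy = 0.5 * (vold[3*i+1] + S.vel[3*i+1]);
      double vz = 0.5 * (vold[3*i+2] + S.vel[3*i+2]);
      ke += 0.5 * S.mass[i] * (vx*vx + vy*vy + vz*vz);
    }
    double Tkin = 2.0 * ke / (ndf * KB_MD);

    // Berendsen thermostat
    if (ens != 0 && tauT > 0 && Tkin > 0) {
      double lam = std::sqrt(1.0 + dt / tauT * (T0 / Tkin - 1.0));
      lam = std::max(0.8, std::min(1.25, lam));
      for (int i = 0; i < 3 * n; ++i) S.vel[i] *= lam;
    }

    if (T0 > 0 && Tkin > 10.0 * T0 && step > 10)
      stop("integration blow-up: kinetic temperature exceeded 10x target");

    // position update + constraints
    oldpos = S.pos;
    for (int i = 0; i < 3 * n; ++i) S.pos[i] += S.vel[i] * dt;
    double Wc[9] = {0,0,0,0,0,0,0,0,0};
    if (ncons > 0) {
      int it = shake(S, oldpos, S.pos, sh_tol, sh_max, gtot);
      if (it < 0) stop("constraint solver failed to converge");
      for (int i = 0; i < 3 * n; ++i) S.vel[i] = (S.pos[i] - oldpos[i]) / dt;
      // constraint virial from accumulated multipliers
      for (size_t c = 0; c < ncons; ++c) {
        int i = S.coni[c], j = S.conj[c];
        double rx = oldpos[3*i] - oldpos[3*j], ry = oldpos[3*i+1] - oldpos[3*j+1],
               rz = oldpos[3*i+2] - oldpos[3*j+2];
        min_image(S.box, S.ibox, rx, ry, rz);
        double gdt = -gtot[c] / (dt * dt);
        Wc[0] += gdt * rx * rx; Wc[1] += gdt * rx * ry; Wc[2] += gdt * rx * rz;
        Wc[3] += gdt * ry * rx; Wc[4] += gdt * ry * ry; Wc[5] += gdt * ry * rz;
        Wc[6] += gdt * rz * rx; Wc[7] += gdt * rz * ry; Wc[8] += gdt * rz * rz;
      }
    }

    // pressure tensor (kinetic on-step + pair virial + constraint virial)
    double Ptens[3] = {0, 0, 0}; // diagonal, bar
    double V = S.box[0] * S.box[1] * S.box[2];
    {
      double K[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i) {
        double vx = 0.5 * (vold[3*i] + S.vel[3*i]);
        double vy = 0.5 * (vold[3*i+1] + S.vel[3*i+1]);
        double vz = 0.5 * (vold[3*i+2] + S.vel[3*i+2]);
        K[0] += S.mass[i] * vx * vx; K[1] += S.mass[i] * vy * vy;
        K[2] += S.mass[i] * vz * vz;
      }
      Ptens[0] = (K[0] + fo.W[0] + Wc[0]) / V * PRESFAC;
      Ptens[1] = (K[1] + fo.W[4] + Wc[4]) / V * PRESFAC;
      Ptens[2] = (K[2] + fo.W[8] + Wc[8]) / V * PRESFAC;
    }

    // Berendsen barostat
    if (ens >= 2 && tauP > 0) {
      double mu[3] = {1.0, 1.0, 1.0};
      auto mufac = [&](double P) {
        double m = std::cbrt(1.0 - dt / tauP * kappa * (P0 - P));
        return std::max(0.98, std::min(1.02, m));
      };
      if (ens == 2) {
        double m = mufac((Ptens[0] + Ptens[1] + Ptens[2]) / 3.0);
        mu[0] = mu[1] = mu[2] = m;
      } else if (ens == 3) {
        mu[2] = mufac(Ptens[2]);
      } else if (ens == 4) {
        double mxy = mufac(0.5 * (Ptens[0] + Ptens[1]));
        mu[0] = mu[1] = mxy;
        mu[2] = mufac(Ptens[2]);
      }
      for (int d = 0; d < 3; ++d) { S.box[d] *= mu[d]; S.ibox[d] = 1.0 / S.box[d]; }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) S.pos[3*i+d] *= mu[d];
      if (ncons > 0 && (mu[0] != 1.0 || mu[1] != 1.0 || mu[2] != 1.0)) {
        // restore exact constraint lengths after the affine scaling
        std::vector<double> ref = S.pos;
        shake(S, ref, S.pos, sh_tol, sh_max, gtot);
      }
    }

    // logging
    double t = (step + 1) * dt;
    if ((step + 1) % std::max(logst, 1) == 0 && logrow < nlog) {
      double Mx = 0, My = 0, Mz = 0;
      for (int i = 0; i < n; ++i) if (S.charge[i] != 0.0) {
        Mx += S.charge[i] * S.pos[3*i]; My += S.charge[i] * S.pos[3*i+1];
        Mz += S.charge[i] * S.pos[3*i+2];
      }
      double Vnow = S.box[0] * S.box[1] * S.box[2];
      double row[22] = {
        t, fo.E_lj, fo.E_coul, fo.E_bond, fo.E_angle, fo.E_field, fo.E_bias,
        Epot, ke, Tkin, Ptens[0], Ptens[1], Ptens[2],
        (Ptens[0] + Ptens[1] + Ptens[2]) / 3.0, Vnow,
        S.box[0], S.box[1], S.box[2], Mx, My, Mz, fo.dHdl
      };
      for (int cidx = 0; cidx < 22; ++cidx) log(logrow, cidx) = row[cidx];
      ++logrow;
    }
    if (trajst > 0 && (step + 1) % trajst == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) fr(i, d) = S.pos[3*i+d];
      frames.push_back(fr);
      frame_times.push_back(t);
      frame_boxes.push_back(S.box[0]);
      frame_boxes.push_back(S.box[1]);
      frame_boxes.push_back(S.box[2]);
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix posOut(n, 3), velOut(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { posOut(i, d) = S.pos[3*i+d]; velOut(i, d) = S.vel[3*i+d]; }
  NumericMatrix logOut(logrow, 22);
  for (int r = 0; r < logrow; ++r)
    for (int cidx = 0; cidx < 22; ++cidx) logOut(r, cidx) = log(r, cidx);
  NumericMatrix fb(frame_times.size(), 3);
  for (size_t r = 0; r < frame_times.size(); ++r)
    for (int d = 0; d < 3; ++d) fb(r, d) = frame_boxes[3*r+d];
  return List::create(
    _["pos"] = posOut, _["vel"] = velOut,
    _["box"] = NumericVector::create(S.box[0], S.box[1], S.box[2]),
    _["log"] = logOut,
    _["frames"] = frames,
    _["frame_times"] = NumericVector(frame_times.begin(), frame_times.end()),
    _["frame_boxes"] = fb,
    _["ndf"] = ndf);
}

// ---------------------------------------------------------------------------
// RDF pair-distance histogram accumulation for one frame (minimum image).
// sel_a / sel_b are 0-based site indices; same selection => self-pairs skipped.

// [[Rcpp::export]]
NumericVector rdf_accum_cpp(NumericMatrix pos, NumericVector box,
                            IntegerVector sel_a, IntegerVector sel_b,
                            double bin, int nbins, bool same) {
  NumericVector counts(nbins);
  double b[3] = {box[0], box[1], box[2]};
  double ib[3] = {1.0 / b[0], 1.0 / b[1], 1.0 / b[2]};
  double rmax = bin * nbins, rmax2 = rmax * rmax;
  int na = sel_a.size(), nb = sel_b.size();
  for (int a = 0; a < na; ++a) {
    int i = sel_a[a];
    int bstart = same ? a + 1 : 0;
    for (int bb = bstart; bb < nb; ++bb) {
      int j = sel_b[bb];
      if (!same && i == j) continue;
      double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1),
             dz = pos(i,2) - pos(j,2);
      min_image(b, ib, dx, dy, dz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rmax2) continue;
      int k = (int)(std::sqrt(r2) / bin);
      if (k < nbins) counts[k] += same ? 2.0 : 1.0;
    }
  }
  return counts;
}
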