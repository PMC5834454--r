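// Compiled core of the one-bead-per-residue model: energy/forces with a
// Verlet neighbour list, steepest-descent minimization, and BAOAB Langevin
// dynamics. Units: nm, Da, kJ/mol, ps (so kT = 0.00831446 * T kJ/mol and
// 1 Da nm^2/ps^2 = 1 kJ/mol). Randomness comes from R's RNG so that runs
// are reproducible under set.seed() on every platform.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

const double KB = 0.008314462618; // kJ mol-1 K-1

// Fast integer-state RNG for the thermostat noise (xoshiro256++ with
// Box-Muller), seeded from R's RNG so that set.seed() fixes trajectories
// reproducibly on every platform.
struct FastRng {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static uint64_t splitmix64(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit FastRng(uint64_t seed) : has_spare(false) {
    for (int k = 0; k < 4; ++k) s[k] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double u01() { return (next() >> 11) * 1.1102230246251565e-16; }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = u01(), u2 = u01();
    while (u1 <= 1e-300) u1 = u01();
    double m = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = m * std::sin(a);
    has_spare = true;
    return m * std::cos(a);
  }
};

struct Sys {
  int n;
  std::vector<double> h, q, mass, sigma;
  std::vector<int> mobile;
  std::vector<int> bi, bj;
  double bond_r0, bond_k;
  double eps_max, rc_hp;
  int comb_rule; // 0 arithmetic, 1 geometric
  double kappa_inv, rc_el;
  int diel_mode; // 0 constant, 1 saturating
  double diel_eps, diel_c, diel_lambda;
  double k_wall;
  double box_lo[3], box_hi[3];
  bool has_mem;
  double mem_zlo, mem_zhi, mem_rpore;
  std::unordered_set<long long> excl;
  std::vector<std::vector<int>> adj; // bonded partners per bead
  double rc_list;

  bool excluded(int i, int j) const {
    const std::vector<int>& a = adj[i];
    for (size_t k = 0; k < a.size(); ++k)
      if (a[k] == j) return true;
    return false;
  }
};

Sys parse_sys(const List& L) {
  Sys S;
  NumericVector h = L["h"], q = L["q"], m = L["mass"], s = L["sigma"];
  IntegerVector mob = L["mobile"];
  S.n = h.size();
  S.h.assign(h.begin(), h.end());
  S.q.assign(q.begin(), q.end());
  S.mass.assign(m.begin(), m.end());
  S.sigma.assign(s.begin(), s.end());
  S.mobile.assign(mob.begin(), mob.end());
  IntegerMatrix bonds = L["bonds"];
  S.adj.resize(S.n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    S.bi.push_back(bonds(k, 0));
    S.bj.push_back(bonds(k, 1));
    S.adj[bonds(k, 0)].push_back(bonds(k, 1));
    S.adj[bonds(k, 1)].push_back(bonds(k, 0));
  }
  S.bond_r0 = as<double>(L["bond_r0"]);
  S.bond_k = as<double>(L["bond_k"]);
  S.eps_max = as<double>(L["eps_max"]);
  S.rc_hp = as<double>(L["rc_hp"]);
  S.comb_rule = as<int>(L["comb_rule"]);
  S.kappa_inv = as<double>(L["kappa_inv"]);
  S.rc_el = as<double>(L["rc_el"]);
  S.diel_mode = as<int>(L["diel_mode"]);
  S.diel_eps = as<double>(L["diel_eps"]);
  S.diel_c = as<double>(L["diel_c"]);
  S.diel_lambda = as<double>(L["diel_lambda"]);
  S.k_wall = as<double>(L["k_wall"]);
  NumericVector lo = L["box_lo"], hi = L["box_hi"];
  for (int d = 0; d < 3; ++d) { S.box_lo[d] = lo[d]; S.box_hi[d] = hi[d]; }
  S.has_mem = as<bool>(L["has_mem"]);
  S.mem_zlo = as<double>(L["mem_zlo"]);
  S.mem_zhi = as<double>(L["mem_zhi"]);
  S.mem_rpore = as<double>(L["mem_rpore"]);
  double smax = 0.0;
  for (int i = 0; i < S.n; ++i) smax = std::max(smax, S.sigma[i]);
  double rmin_max = std::pow(2.0, 1.0 / 6.0) * smax;
  S.rc_list = std::max(std::max(S.rc_hp, S.rc_el), rmin_max);
  return S;
}

inline double lambda_pair(const Sys& S, int i, int j) {
  if (S.comb_rule == 0) return 0.5 * (S.h[i] + S.h[j]);
  return std::sqrt(S.h[i] * S.h[j]);
}

// hydrophobicity-scaled 12-6 with force-shift truncation
inline double ah_energy(double r, double lam, double eps, double sij,
                        double rc, double* dUdr) {
  double rmin = std::pow(2.0, 1.0 / 6.0) * sij;
  double rcp = std::max(rc, rmin);
  if (r >= rcp) { *dUdr = 0.0; return 0.0; }
  double sr6c = std::pow(sij / rcp, 6.0), sr12c = sr6c * sr6c;
  double uA = 4.0 * eps * (sr12c - sr6c);
  double dA = 4.0 * eps * (-12.0 * sr12c + 6.0 * sr6c) / rcp;
  double A = lam * uA, B = lam * dA;
  double sr6 = std::pow(sij / r, 6.0), sr12 = sr6 * sr6;
  double u = 4.0 * eps * (sr12 - sr6);
  double du = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
  double U, dU;
  if (r < rmin) { U = u + (1.0 - lam) * eps; dU = du; }
  else { U = lam * u; dU = lam * du; }
  U -= A + B * (r - rcp);
  dU -= B;
  *dUdr = dU;
  return U;
}

// Yukawa with distance-dependent dielectric, energy-shifted at rc_el
inline double el_energy(double r, double qq, const Sys& S, double scale,
                        double* dUdr) {
  const double KE = 138.935458;
  auto gfun = [&](double rr) {
    double er = (S.diel_mode == 0)
                    ? S.diel_eps
                    : S.diel_eps * (1.0 - S.diel_c * std::exp(-rr / S.diel_lambda));
    return std::exp(-rr / S.kappa_inv) / (er * rr);
  };
  double er = (S.diel_mode == 0)
                  ? S.diel_eps
                  : S.diel_eps * (1.0 - S.diel_c * std::exp(-r / S.diel_lambda));
  double deps = (S.diel_mode == 0)
                    ? 0.0
                    : S.diel_eps * S.diel_c / S.diel_lambda *
                          std::exp(-r / S.diel_lambda);
  double ex = std::exp(-r / S.kappa_inv);
  double dg = ex * (-1.0 / (S.kappa_inv * er * r) - 1.0 / (er * r * r) -
                    deps / (er * er * r));
  *dUdr = scale * KE * qq * dg;
  return scale * KE * qq * (gfun(r) - gfun(S.rc_el));
}

struct NList {
  std::vector<int> pi, pj;
  // per-pair precomputed parameters
  std::vector<double> sij, lam0, qq, rcp, rcp2, shiftA, shiftB;
  std::vector<double> ref;
  double skin = 0.35;
};

inline void maybe_add_pair(const std::vector<double>& pos, const Sys& S,
                           NList& L, int i, int j, double sixth) {
  if (!S.mobile[i] && !S.mobile[j]) return;
  if (S.excluded(i, j)) return;
  // per-pair interaction radius: hydrophobic/WCA range, extended to the
  // electrostatic cutoff only when both beads carry charge
  double sij = 0.5 * (S.sigma[i] + S.sigma[j]);
  double qq = S.q[i] * S.q[j];
  double rcp = std::max(S.rc_hp, sixth * sij);
  double rl = rcp;
  if (qq != 0.0) rl = std::max(rl, S.rc_el);
  rl += L.skin;
  double dx = pos[3 * i] - pos[3 * j];
  double dy = pos[3 * i + 1] - pos[3 * j + 1];
  double dz = pos[3 * i + 2] - pos[3 * j + 2];
  if (dx * dx + dy * dy + dz * dz >= rl * rl) return;
  L.pi.push_back(i);
  L.pj.push_back(j);
  L.sij.push_back(sij);
  L.lam0.push_back(lambda_pair(S, i, j));
  L.qq.push_back(qq);
  L.rcp.push_back(rcp);
  L.rcp2.push_back(rcp * rcp);
  // unscaled LJ value and slope at the truncation radius
  double s2 = (sij * sij) / (rcp * rcp);
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  L.shiftA.push_back(4.0 * S.eps_max * (s12 - s6));
  L.shiftB.push_back(4.0 * S.eps_max * (-12.0 * s12 + 6.0 * s6) / rcp);
}

void build_list(const std::vector<double>& pos, const Sys& S, NList& L) {
  L.pi.clear(); L.pj.clear();
  L.sij.clear(); L.lam0.clear(); L.qq.clear();
  L.rcp.clear(); L.rcp2.clear(); L.shiftA.clear(); L.shiftB.clear();
  const double sixth = std::pow(2.0, 1.0 / 6.0);
  // global list radius (largest possible pair radius) sets the cell edge
  double smax = 0.0, qmax = 0.0;
  for (int i = 0; i < S.n; ++i) {
    smax = std::max(smax, S.sigma[i]);
    qmax = std::max(qmax, std::fabs(S.q[i]));
  }
  double rl_max = std::max(S.rc_hp, sixth * smax);
  if (qmax > 0.0) rl_max = std::max(rl_max, S.rc_el);
  rl_max += L.skin;

  // bounding box of the current coordinates (beads may sit outside the soft
  // walls transiently)
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = pos[d]; hi[d] = pos[d]; }
  for (int i = 1; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pos[3 * i + d]);
      hi[d] = std::max(hi[d], pos[3 * i + d]);
    }
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)((hi[d] - lo[d]) / rl_max) + 1);
  long long ncell = (long long)nc[0] * nc[1] * nc[2];
  if (ncell > 4000000LL || S.n < 64) {
    // degenerate geometry or tiny system: plain O(n^2) build
    for (int i = 0; i < S.n - 1; ++i)
      for (int j = i + 1; j < S.n; ++j) maybe_add_pair(pos, S, L, i, j, sixth);
    L.ref = pos;
    return;
  }
  std::vector<int> cell_of(S.n), head((size_t)ncell, -1), next(S.n, -1);
  for (int i = 0; i < S.n; ++i) {
    int cx = std::min(nc[0] - 1, std::max(0, (int)((pos[3 * i] - lo[0]) / rl_max)));
    int cy = std::min(nc[1] - 1, std::max(0, (int)((pos[3 * i + 1] - lo[1]) / rl_max)));
    int cz = std::min(nc[2] - 1, std::max(0, (int)((pos[3 * i + 2] - lo[2]) / rl_max)));
    int c = cx + nc[0] * (cy + nc[1] * cz);
    cell_of[i] = c;
    next[i] = head[c];
    head[c] = i;
  }
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c = cx + nc[0] * (cy + nc[1] * cz);
        for (int i = head[c]; i >= 0; i = next[i]) {
          // same cell: j after i in the linked list
          for (int j = next[i]; j >= 0; j = next[j])
            maybe_add_pair(pos, S, L, std::min(i, j), std::max(i, j), sixth);
          // half of the 26 neighbour cells
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = (dz == 0 ? 0 : -1); dy <= 1; ++dy)
              for (int dx = (dz == 0 && dy == 0 ? 1 : -1); dx <= 1; ++dx) {
                int ex = cx + dx, ey = cy + dy, ez = cz + dz;
                if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                    ez < 0 || ez >= nc[2])
                  continue;
                int c2 = ex + nc[0] * (ey + nc[1] * ez);
                for (int j = head[c2]; j >= 0; j = next[j])
                  maybe_add_pair(pos, S, L, std::min(i, j), std::max(i, j),
                                 sixth);
              }
          }
      }
  L.ref = pos;
}

bool needs_rebuild(const std::vector<double>& pos, const Sys& S,
                   const NList& L) {
  double lim2 = 0.25 * L.skin * L.skin;
  for (int i = 0; i < S.n; ++i) {
    if (!S.mobile[i]) continue;
    double dx = pos[3 * i] - L.ref[3 * i];
    double dy = pos[3 * i + 1] - L.ref[3 * i + 1];
    double dz = pos[3 * i + 2] - L.ref[3 * i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

struct Terms {
  double bond = 0, hp = 0, el = 0, wall = 0;
  double total() const { return bond + hp + el + wall; }
};

Terms compute_ef(const std::vector<double>& pos, const Sys& S, const NList& L,
                 double s_hp, double s_el, std::vector<double>& F) {
  Terms T;
  std::fill(F.begin(), F.end(), 0.0);

  for (size_t k = 0; k < S.bi.size(); ++k) {
    int i = S.bi[k], j = S.bj[k];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-6) stop("Overlapping bonded beads %d and %d.", i + 1, j + 1);
    double dU = S.bond_k * (r - S.bond_r0);
    T.bond += 0.5 * S.bond_k * (r - S.bond_r0) * (r - S.bond_r0);
    double fr = -dU / r;
    F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
    F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
  }

  for (size_t k = 0; k < L.pi.size(); ++k) {
    int i = L.pi[k], j = L.pj[k];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double qq = L.qq[k];
    bool do_hp = r2 < L.rcp2[k];
    bool do_el = (qq != 0.0 && s_el > 0.0 && r2 < S.rc_el * S.rc_el);
    if (!do_hp && !do_el) continue;
    if (r2 < 1e-12) stop("Overlapping beads %d and %d at r = 0.", i + 1, j + 1);
    double r = std::sqrt(r2);
    double fr = 0.0;
    if (do_hp) {
      double sij = L.sij[k];
      double lam = s_hp * L.lam0[k];
      double s2 = (sij * sij) / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      double u = 4.0 * S.eps_max * (s12 - s6);
      double du = 4.0 * S.eps_max * (-12.0 * s12 + 6.0 * s6) / r;
      double U, dU;
      if (s6 > 0.5) { // r < rmin  <=>  (sij/r)^6 > 1/2
        U = u + (1.0 - lam) * S.eps_max;
        dU = du;
      } else {
        U = lam * u;
        dU = lam * du;
      }
      U -= lam * (L.shiftA[k] + L.shiftB[k] * (r - L.rcp[k]));
      dU -= lam * L.shiftB[k];
      T.hp += U;
      fr += -dU / r;
    }
    if (do_el) {
      double dU;
      T.el += el_energy(r, qq, S, s_el, &dU);
      fr += -dU / r;
    }
    if (fr != 0.0) {
      F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
      F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
    }
  }

  for (int i = 0; i < S.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      double x = pos[3 * i + d];
      if (x < S.box_lo[d]) {
        double dl = S.box_lo[d] - x;
        T.wall += 0.5 * S.k_wall * dl * dl;
        F[3 * i + d] += S.k_wall * dl;
      } else if (x > S.box_hi[d]) {
        double dl = x - S.box_hi[d];
        T.wall += 0.5 * S.k_wall * dl * dl;
        F[3 * i + d] -= S.k_wall * dl;
      }
    }
    if (S.has_mem) {
      double z = pos[3 * i + 2];
      double rxy = std::sqrt(pos[3 * i] * pos[3 * i] +
                             pos[3 * i + 1] * pos[3 * i + 1]);
      if (z > S.mem_zlo && z < S.mem_zhi && rxy > S.mem_rpore) {
        double d_top = S.mem_zhi - z, d_bot = z - S.mem_zlo,
               d_in = rxy - S.mem_rpore;
        double dl = std::min(std::min(d_top, d_bot), d_in);
        T.wall += 0.5 * S.k_wall * dl * dl;
        if (dl == d_top) {
          F[3 * i + 2] += S.k_wall * dl;
        } else if (dl == d_bot) {
          F[3 * i + 2] -= S.k_wall * dl;
        } else if (rxy > 0) {
          F[3 * i] -= S.k_wall * dl * pos[3 * i] / rxy;
          F[3 * i + 1] -= S.k_wall * dl * pos[3 * i + 1] / rxy;
        }
      }
    }
  }
  return T;
}

} // namespace

// [[Rcpp::export]]
List engine_energy_forces(NumericMatrix pos, List sys, double scale_hp = 1.0,
                          double scale_el = 1.0) {
  Sys S = parse_sys(sys);
  std::vector<double> p(3 * S.n), F(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  NList L;
  build_list(p, S, L);
  Terms T = compute_ef(p, S, L, scale_hp, scale_el, F);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(
      _["energy"] = T.total(), _["forces"] = Fm,
      _["terms"] = List::create(_["bond"] = T.bond, _["hydrophobic"] = T.hp,
                                _["electrostatic"] = T.el, _["wall"] = T.wall));
}

// [[Rcpp::export]]
List engine_minimize(NumericMatrix pos, List sys, int max_iter = 2000,
                     double f_tol = 10.0, double step0 = 0.01,
                     double max_step = 0.1, double scale_hp = 1.0,
                     double scale_el = 1.0) {
  Sys S = parse_sys(sys);
  std::vector<double> p(3 * S.n), F(3 * S.n), Ftrial(3 * S.n),
      ptrial(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  NList L;
  build_list(p, S, L);
  Terms T = compute_ef(p, S, L, scale_hp, scale_el, F);
  double E = T.total();
  if (!std::isfinite(E)) stop("Non-finite energy in the starting configuration.");
  std::vector<double> epath;
  epath.push_back(E);
  double step = step0;
  int it = 0;
  bool converged = false;
  double fmax = 0.0;
  for (it = 0; it < max_iter; ++it) {
    fmax = 0.0;
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      for (int d = 0; d < 3; ++d)
        fmax = std::max(fmax, std::fabs(F[3 * i + d]));
    }
    if (fmax < f_tol) { converged = true; break; }
    double h = step / fmax;
    for (int i = 0; i < S.n; ++i) {
      for (int d = 0; d < 3; ++d) {
        ptrial[3 * i + d] =
            p[3 * i + d] + (S.mobile[i] ? h * F[3 * i + d] : 0.0);
      }
    }
    if (needs_rebuild(ptrial, S, L)) build_list(ptrial, S, L);
    Terms Tt = compute_ef(ptrial, S, L, scale_hp, scale_el, Ftrial);
    double Et = Tt.total();
    if (std::isfinite(Et) && Et < E) {
      p = ptrial;
      F = Ftrial;
      E = Et;
      epath.push_back(E);
      step = std::min(step * 1.2, max_step);
    } else {
      step *= 0.5;
      if (step < 1e-9) break;
    }
  }
  NumericMatrix pm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) pm(i, d) = p[3 * i + d];
  return List::create(_["pos"] = pm, _["energy"] = E, _["n_iter"] = it,
                      _["converged"] = converged, _["f_max"] = fmax,
                      _["energy_path"] = wrap(epath));
}

// [[Rcpp::export]]
List engine_langevin(NumericMatrix pos, List sys, double dt, double temperature,
                     double gamma, int n_steps, int stride, int discard,
                     NumericVector sched_steps, NumericVector sched_scales,
                     bool init_velocities = true, Nullable<NumericMatrix> vel0 =
                         R_NilValue) {
  Sys S = parse_sys(sys);
  std::vector<double> p(3 * S.n), v(3 * S.n, 0.0), F(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);

  double kT = KB * temperature;
  FastRng rng((uint64_t)(unif_rand() * 9007199254740992.0));
  std::vector<double> noise_sd(S.n);
  for (int i = 0; i < S.n; ++i) noise_sd[i] = std::sqrt(kT / S.mass[i]);
  if (init_velocities) {
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      for (int d = 0; d < 3; ++d) v[3 * i + d] = noise_sd[i] * rng.normal();
    }
  } else if (vel0.isNotNull()) {
    NumericMatrix vv(vel0);
    for (int i = 0; i < S.n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = vv(i, d);
  }

  auto sched = [&](int step) {
    int m = sched_steps.size();
    if (m == 0) return 1.0;
    if (step <= sched_steps[0]) return (double)sched_scales[0];
    if (step >= sched_steps[m - 1]) return (double)sched_scales[m - 1];
    for (int k = 1; k < m; ++k) {
      if (step <= sched_steps[k]) {
        double f = (step - sched_steps[k - 1]) /
                   (sched_steps[k] - sched_steps[k - 1]);
        return sched_scales[k - 1] + f * (sched_scales[k] - sched_scales[k - 1]);
      }
    }
    return (double)sched_scales[m - 1];
  };

  NList L;
  build_list(p, S, L);
  compute_ef(p, S, L, sched(0), sched(0), F);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  int n_mobile = 0;
  for (int i = 0; i < S.n; ++i) n_mobile += S.mobile[i];
  if (n_mobile == 0) stop("No mobile beads to integrate.");

  int n_frames = 0;
  if (n_steps > discard) n_frames = (n_steps - discard) / stride;
  NumericVector frames((R_xlen_t)n_frames * S.n * 3);
  frames.attr("dim") = IntegerVector::create(S.n, 3, n_frames);
  NumericVector ke_temp(n_frames), frame_step(n_frames);
  int fidx = 0;
  int n_rebuilds = 0;
  std::vector<double> pold(3 * S.n);

  for (int step = 0; step < n_steps; ++step) {
    double s = sched(step);
    pold = p;
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      double hdt = 0.5 * dt / S.mass[i];
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += hdt * F[3 * i + d];       // B
        p[3 * i + d] += 0.5 * dt * v[3 * i + d];  // A
      }
      double sd = c2 * noise_sd[i];
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] = c1 * v[3 * i + d] + sd * rng.normal(); // O
        p[3 * i + d] += 0.5 * dt * v[3 * i + d];  // A
      }
    }
    if (needs_rebuild(p, S, L)) { build_list(p, S, L); ++n_rebuilds; }
    compute_ef(p, S, L, s, s, F);
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      double hdt = 0.5 * dt / S.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdt * F[3 * i + d]; // B
    }
    // stability checks
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      double dx = p[3 * i] - pold[3 * i];
      double dy = p[3 * i + 1] - pold[3 * i + 1];
      double dz = p[3 * i + 2] - pold[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (!std::isfinite(d2) || d2 > 1.0) {
        stop("Bead %d moved more than 1 nm at step %d: timestep too large.",
             i + 1, step + 1);
      }
    }
    int s1 = step + 1;
    if (s1 > discard && (s1 - discard) % stride == 0 && fidx < n_frames) {
      double ke = 0.0;
      for (int i = 0; i < S.n; ++i) {
        if (!S.mobile[i]) continue;
        for (int d = 0; d < 3; ++d)
          ke += 0.5 * S.mass[i] * v[3 * i + d] * v[3 * i + d];
      }
      ke_temp[fidx] = 2.0 * ke / (3.0 * n_mobile * KB);
      frame_step[fidx] = s1;
      for (int i = 0; i < S.n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)fidx * S.n * 3 + d * S.n + i] = p[3 * i + d];
      ++fidx;
    }
  }

  NumericMatrix pm(S.n, 3), vm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) {
      pm(i, d) = p[3 * i + d];
      vm(i, d) = v[3 * i + d];
    }
  return List::create(_["frames"] = frames, _["steps"] = frame_step,
                      _["ke_temp"] = ke_temp, _["pos"] = pm, _["vel"] = vm,
                      _["n_rebuilds"] = n_rebuilds);
}
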