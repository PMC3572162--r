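// Compiled core: pair/bonded energies and forces, Ewald summation, and the
// Langevin (BAOAB) integrator. Units: length in Angstrom, energy in kT,
// reduced masses and time; the Coulomb prefactor is the Bjerrum length.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct FFPar {
  double lB;        // Bjerrum length, A
  double sigma;     // soft LJ length, A
  double eps;       // LJ strength, kT
  double rcut;      // Coulomb cutoff (method "cutoff"/Ewald real space), A
  int    method;    // 0 none, 1 direct (no cutoff), 2 cutoff (min image), 3 ewald
  double alpha;     // Ewald splitting
  int    kmax;      // Ewald reciprocal cutoff (integer triplets)
  bool   excl_lj;   // exclude 1-2 pairs from short-range repulsion
  bool   excl_coul; // exclude 1-2 pairs from Coulomb
  double cap_energy;// WCA energy at which the linear overlap cap engages, kT
  // derived
  double xc, xcap, ucap, fcap;
  void derive() {
    xc = std::pow(2.0, 1.0 / 6.0) * sigma;
    double s = (1.0 + std::sqrt(cap_energy)) / 2.0;   // (sigma/x)^6 at cap
    xcap = sigma * std::pow(s, -1.0 / 6.0);
    double s6 = std::pow(sigma / xcap, 6.0);
    ucap = 4.0 * eps * (s6 * s6 - s6) + eps;
    fcap = -4.0 * eps * (-12.0 * s6 * s6 + 6.0 * s6) / xcap; // -dU/dx > 0
  }
};

// WCA on the hard-core-shifted distance x = r - Rij, linearly capped inside.
// Returns energy; *dudx set to dU/dx.
inline double wca_x(double x, const FFPar& p, double* dudx) {
  if (x >= p.xc) { *dudx = 0.0; return 0.0; }
  if (x > p.xcap) {
    double sr = p.sigma / x, s6 = sr * sr * sr; s6 *= s6;
    *dudx = 4.0 * p.eps * (-12.0 * s6 * s6 + 6.0 * s6) / x;
    return 4.0 * p.eps * (s6 * s6 - s6) + p.eps;
  }
  *dudx = -p.fcap;
  return p.ucap + p.fcap * (p.xcap - x);
}

inline void min_image(double* d, double box) {
  if (box <= 0.0) return;
  double half = 0.5 * box;
  for (int k = 0; k < 3; ++k) {
    // unwrapped coordinates rarely exceed one box; branches beat rounding here
    while (d[k] > half) d[k] -= box;
    while (d[k] < -half) d[k] += box;
  }
}

struct System {
  int n;
  std::vector<double> x;          // 3n
  std::vector<double> q, R, m;
  double box;
  // bonded terms
  std::vector<int> bi, bj; std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak; std::vector<double> aka, aphi0;
  // per-bead sorted exclusion lists (1-2 neighbours)
  std::vector<std::vector<int>> excl;
  bool overlap_flag = false;
};

inline bool excluded(const System& S, int i, int j) {
  const std::vector<int>& e = S.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

void bonded_forces(const System& S, std::vector<double>& f,
                   double& e_bond, double& e_angle) {
  e_bond = 0.0; e_angle = 0.0;
  const double* x = S.x.data();
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
    min_image(d, S.box);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double dr = r - S.br0[b];
    e_bond += 0.5 * S.bk[b] * dr * dr;
    double fac = -S.bk[b] * dr / std::max(r, 1e-12);
    for (int k = 0; k < 3; ++k) { f[3*i+k] += fac * d[k]; f[3*j+k] -= fac * d[k]; }
  }
  for (size_t a = 0; a < S.ai.size(); ++a) {
    int i = S.ai[a], j = S.aj[a], k = S.ak[a];
    double v1[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
    double v2[3] = { x[3*k] - x[3*j], x[3*k+1] - x[3*j+1], x[3*k+2] - x[3*j+2] };
    min_image(v1, S.box); min_image(v2, S.box);
    double n1 = std::sqrt(v1[0]*v1[0] + v1[1]*v1[1] + v1[2]*v1[2]);
    double n2 = std::sqrt(v2[0]*v2[0] + v2[1]*v2[1] + v2[2]*v2[2]);
    double c = (v1[0]*v2[0] + v1[1]*v2[1] + v1[2]*v2[2]) / (n1 * n2);
    c = std::max(-1.0, std::min(1.0, c));
    double phi = std::acos(c);
    double dphi = phi - S.aphi0[a];
    e_angle += 0.5 * S.aka[a] * dphi * dphi;
    double s = std::max(std::sqrt(1.0 - c * c), 1e-6);
    double dude = S.aka[a] * dphi;            // dU/dphi
    // F_i = dU/dphi * (u2 - c u1) / (|v1| sin phi), analogous for k
    for (int d = 0; d < 3; ++d) {
      double u1 = v1[d] / n1, u2 = v2[d] / n2;
      double fi = dude * (u2 - c * u1) / (n1 * s);
      double fk = dude * (u1 - c * u2) / (n2 * s);
      f[3*i+d] += fi; f[3*k+d] += fk; f[3*j+d] -= (fi + fk);
    }
  }
}

// pair interaction (short-range repulsion + real-space electrostatics)
inline void pair_force(System& S, const FFPar& p, int i, int j,
                       std::vector<double>& f, double& e_lj, double& e_coul) {
  double d[3] = { S.x[3*i] - S.x[3*j], S.x[3*i+1] - S.x[3*j+1], S.x[3*i+2] - S.x[3*j+2] };
  min_image(d, S.box);
  double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
  double r = std::sqrt(r2);
  if (r < 1e-12) r = 1e-12;
  double fac = 0.0;  // (1/r) dU/dr, negated later via fac = -dU/dr / r
  // short-range repulsion
  bool exb = (!S.excl[i].empty() || !S.excl[j].empty()) && excluded(S, i, j);
  if (!(p.excl_lj && exb)) {
    double Rij = S.R[i] + S.R[j];
    double xsh = r - Rij;
    if (xsh < p.xc) {
      if (xsh <= 0.0) S.overlap_flag = true;
      double dudx; e_lj += wca_x(xsh, p, &dudx);
      fac += -dudx / r;
    }
  }
  // electrostatics
  if (p.method != 0 && S.q[i] != 0.0 && S.q[j] != 0.0 && !(p.excl_coul && exb)) {
    double qq = p.lB * S.q[i] * S.q[j];
    if (p.method == 1) {                       // direct, no cutoff
      e_coul += qq / r;
      fac += qq / (r2 * r);
    } else if (p.method == 2) {                // truncated & shifted
      if (r < p.rcut) { e_coul += qq * (1.0 / r - 1.0 / p.rcut); fac += qq / (r2 * r); }
    } else if (p.method == 3) {                // Ewald real space
      if (r < p.rcut) {
        double ar = p.alpha * r;
        double er = std::erfc(ar);
        e_coul += qq * er / r;
        fac += qq * (er / r + 2.0 * p.alpha / std::sqrt(M_PI) * std::exp(-ar * ar)) / r2;
      }
    }
  }
  if (fac != 0.0) for (int k = 0; k < 3; ++k) { f[3*i+k] += fac * d[k]; f[3*j+k] -= fac * d[k]; }
}

// Ewald reciprocal + self (+ neutral background assumed). Adds to f.
double ewald_kspace(const System& S, const FFPar& p, std::vector<double>& f) {
  double V = S.box * S.box * S.box;
  double twopiL = 2.0 * M_PI / S.box;
  double pref = p.lB * 2.0 * M_PI / V;
  double e = 0.0;
  int km = p.kmax;
  for (int kx = -km; kx <= km; ++kx)
    for (int ky = -km; ky <= km; ++ky)
      for (int kz = -km; kz <= km; ++kz) {
        int k2i = kx*kx + ky*ky + kz*kz;
        if (k2i == 0 || k2i > km * km) continue;
        double kv[3] = { twopiL * kx, twopiL * ky, twopiL * kz };
        double k2 = kv[0]*kv[0] + kv[1]*kv[1] + kv[2]*kv[2];
        double a = std::exp(-k2 / (4.0 * p.alpha * p.alpha)) / k2;
        double sre = 0.0, sim = 0.0;
        std::vector<double> cs(S.n), sn(S.n);
        for (int i = 0; i < S.n; ++i) {
          double kr = kv[0]*S.x[3*i] + kv[1]*S.x[3*i+1] + kv[2]*S.x[3*i+2];
          cs[i] = std::cos(kr); sn[i] = std::sin(kr);
          sre += S.q[i] * cs[i]; sim += S.q[i] * sn[i];
        }
        e += pref * a * (sre * sre + sim * sim);
        for (int i = 0; i < S.n; ++i) {
          double fi = 2.0 * pref * a * S.q[i] * (sn[i] * sre - cs[i] * sim);
          for (int d = 0; d < 3; ++d) f[3*i+d] += fi * kv[d];
        }
      }
  double q2 = 0.0;
  for (int i = 0; i < S.n; ++i) q2 += S.q[i] * S.q[i];
  e -= p.lB * p.alpha / std::sqrt(M_PI) * q2;   // self term
  return e;
}

// ---- neighbour machinery -------------------------------------------------
struct NeighbourList {
  std::vector<int> pairs_i, pairs_j;  // flat pair list
  std::vector<double> xref;
  double rlist = 0.0, skin = 0.0;
  bool valid = false;

  void build(const System& S, double rneed, double skin_) {
    skin = skin_; rlist = rneed + skin;
    pairs_i.clear(); pairs_j.clear();
    xref = S.x;
    int n = S.n;
    if (S.box <= 0.0 || S.box / rlist < 3.0) {     // brute force
      for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
        double d[3] = { S.x[3*i] - S.x[3*j], S.x[3*i+1] - S.x[3*j+1], S.x[3*i+2] - S.x[3*j+2] };
        min_image(d, S.box);
        if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < rlist * rlist) { pairs_i.push_back(i); pairs_j.push_back(j); }
      }
      valid = true; return;
    }
    int nc = (int)std::floor(S.box / rlist);
    double cw = S.box / nc;
    std::vector<std::vector<int>> cells(nc * nc * nc);
    auto cidx = [&](double v) {
      int c = (int)std::floor(v / cw) % nc; if (c < 0) c += nc; return c;
    };
    for (int i = 0; i < n; ++i) {
      double px = S.x[3*i] - S.box * std::floor(S.x[3*i] / S.box);
      double py = S.x[3*i+1] - S.box * std::floor(S.x[3*i+1] / S.box);
      double pz = S.x[3*i+2] - S.box * std::floor(S.x[3*i+2] / S.box);
      cells[(cidx(px) * nc + cidx(py)) * nc + cidx(pz)].push_back(i);
    }
    double rl2 = rlist * rlist;
    for (int cx = 0; cx < nc; ++cx) for (int cy = 0; cy < nc; ++cy) for (int cz = 0; cz < nc; ++cz) {
      const std::vector<int>& A = cells[(cx * nc + cy) * nc + cz];
      if (A.empty()) continue;
      for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) for (int oz = -1; oz <= 1; ++oz) {
        int bx = (cx + ox + nc) % nc, by = (cy + oy + nc) % nc, bz = (cz + oz + nc) % nc;
        int ci = (cx * nc + cy) * nc + cz, cj = (bx * nc + by) * nc + bz;
        if (cj < ci) continue;
        const std::vector<int>& B = cells[cj];
        for (size_t u = 0; u < A.size(); ++u) {
          size_t vstart = (ci == cj) ? u + 1 : 0;
          for (size_t v = vstart; v < B.size(); ++v) {
            int i = A[u], j = B[v];
            double d[3] = { S.x[3*i] - S.x[3*j], S.x[3*i+1] - S.x[3*j+1], S.x[3*i+2] - S.x[3*j+2] };
            min_image(d, S.box);
            if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < rl2) { pairs_i.push_back(i); pairs_j.push_back(j); }
          }
        }
      }
    }
    valid = true;
  }

  bool stale(const System& S) const {
    if (!valid) return true;
    double lim = 0.25 * skin * skin;   // (skin/2)^2
    for (int i = 0; i < S.n; ++i) {
      double dx = S.x[3*i] - xref[3*i], dy = S.x[3*i+1] - xref[3*i+1], dz = S.x[3*i+2] - xref[3*i+2];
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }
};

double max_pair_reach(const System& S, const FFPar& p) {
  double maxR = 0.0;
  for (int i = 0; i < S.n; ++i) maxR = std::max(maxR, S.R[i]);
  double reach = 2.0 * maxR + p.xc;
  if (p.method == 1) reach = 1e30;   // direct sum: every pair interacts
  if (p.method == 2 || p.method == 3) reach = std::max(reach, p.rcut);
  return reach;
}

// total forces; neighbour list supplied by caller (rebuilt if stale)
double total_forces(System& S, const FFPar& p, NeighbourList& nl,
                    std::vector<double>& f, double skin,
                    double* eb = nullptr, double* ea = nullptr,
                    double* el = nullptr, double* ec = nullptr) {
  std::fill(f.begin(), f.end(), 0.0);
  S.overlap_flag = false;
  double e_bond, e_angle, e_lj = 0.0, e_coul = 0.0;
  bonded_forces(S, f, e_bond, e_angle);
  if (nl.stale(S)) nl.build(S, max_pair_reach(S, p), skin);
  for (size_t u = 0; u < nl.pairs_i.size(); ++u)
    pair_force(S, p, nl.pairs_i[u], nl.pairs_j[u], f, e_lj, e_coul);
  if (p.method == 3) e_coul += ewald_kspace(S, p, f);
  if (eb) *eb = e_bond; if (ea) *ea = e_angle; if (el) *el = e_lj; if (ec) *ec = e_coul;
  return e_bond + e_angle + e_lj + e_coul;
}

System make_system(const NumericMatrix& pos, double box,
                   const NumericVector& charge, const NumericVector& hard_radius,
                   const NumericVector& mass,
                   const IntegerMatrix& bonds, const NumericVector& bond_k,
                   const NumericVector& bond_r0,
                   const IntegerMatrix& angles, const NumericVector& angle_k,
                   const NumericVector& angle_phi0) {
  System S;
  S.n = pos.nrow(); S.box = box;
  S.x.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i) for (int d = 0; d < 3; ++d) S.x[3*i+d] = pos(i, d);
  S.q.assign(charge.begin(), charge.end());
  S.R.assign(hard_radius.begin(), hard_radius.end());
  S.m.assign(mass.begin(), mass.end());
  int nb = bonds.nrow();
  S.bi.resize(nb); S.bj.resize(nb);
  for (int b = 0; b < nb; ++b) { S.bi[b] = bonds(b, 0) - 1; S.bj[b] = bonds(b, 1) - 1; }
  S.bk.assign(bond_k.begin(), bond_k.end());
  S.br0.assign(bond_r0.begin(), bond_r0.end());
  int na = angles.nrow();
  S.ai.resize(na); S.aj.resize(na); S.ak.resize(na);
  for (int a = 0; a < na; ++a) {
    S.ai[a] = angles(a, 0) - 1; S.aj[a] = angles(a, 1) - 1; S.ak[a] = angles(a, 2) - 1;
  }
  S.aka.assign(angle_k.begin(), angle_k.end());
  S.aphi0.assign(angle_phi0.begin(), angle_phi0.end());
  S.excl.assign(S.n, {});
  for (int b = 0; b < nb; ++b) { S.excl[S.bi[b]].push_back(S.bj[b]); S.excl[S.bj[b]].push_back(S.bi[b]); }
  for (int i = 0; i < S.n; ++i) std::sort(S.excl[i].begin(), S.excl[i].end());
  return S;
}

FFPar make_ffpar(const List& ff) {
  FFPar p;
  p.lB = as<double>(ff["bjerrum_length"]);
  p.sigma = as<double>(ff["sigma"]);
  p.eps = as<double>(ff["epsilon_lj"]);
  p.rcut = as<double>(ff["coulomb_cutoff"]);
  std::string m = as<std::string>(ff["electrostatics"]);
  p.method = (m == "none") ? 0 : (m == "direct") ? 1 : (m == "cutoff") ? 2 : 3;
  p.alpha = as<double>(ff["ewald_alpha"]);
  p.kmax = as<int>(ff["ewald_kmax"]);
  p.excl_lj = as<bool>(ff["exclude_bonded_lj"]);
  p.excl_coul = as<bool>(ff["exclude_bonded_coulomb"]);
  p.cap_energy = as<double>(ff["overlap_cap"]);
  p.derive();
  return p;
}

// deterministic gaussian generator (Box-Muller over mt19937_64)
struct Gauss {
  std::mt19937_64 rng;
  bool have = false; double spare = 0.0;
  explicit Gauss(uint64_t seed) : rng(seed) {}
  double uni() { return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    if (have) { have = false; return spare; }
    double u1 = uni(), u2 = uni();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 2.0 * M_PI * u2;
    spare = r * std::sin(t); have = true;
    return r * std::cos(t);
  }
};

} // namespace

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix pos, double box,
                          NumericVector charge, NumericVector hard_radius,
                          NumericVector mass,
                          IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                          IntegerMatrix angles, NumericVector angle_k, NumericVector angle_phi0,
                          List ff) {
  System S = make_system(pos, box, charge, hard_radius, mass,
                         bonds, bond_k, bond_r0, angles, angle_k, angle_phi0);
  FFPar p = make_ffpar(ff);
  NeighbourList nl;
  std::vector<double> f(3 * S.n);
  double eb, ea, el, ec;
  double e = total_forces(S, p, nl, f, 0.0, &eb, &ea, &el, &ec);
  if (!std::isfinite(e)) stop("non-finite energy (bond %f angle %f lj %f coul %f)", eb, ea, el, ec);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) for (int d = 0; d < 3; ++d) F(i, d) = f[3*i+d];
  return List::create(_["energy"] = e, _["forces"] = F,
                      _["terms"] = NumericVector::create(
                        _["bond"] = eb, _["angle"] = ea, _["repulsion"] = el,
                        _["coulomb"] = ec),
                      _["overlap"] = S.overlap_flag);
}

// [[Rcpp::export]]
List cg_run_langevin_cpp(NumericMatrix pos0, NumericMatrix vel0, double box,
                         NumericVector charge, NumericVector hard_radius,
                         NumericVector mass,
                         IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                         IntegerMatrix angles, NumericVector angle_k, NumericVector angle_phi0,
                         List ff, double dt, double gamma, double kT,
                         int n_steps, int stride, double seed, double skin,
                         double max_step_disp) {
  System S = make_system(pos0, box, charge, hard_radius, mass,
                         bonds, bond_k, bond_r0, angles, angle_k, angle_phi0);
  FFPar p = make_ffpar(ff);
  NeighbourList nl;
  int n = S.n;
  std::vector<double> v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) v[3*i+d] = vel0(i, d);
  Gauss gauss((uint64_t)seed);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  double e = total_forces(S, p, nl, f, skin);
  int n_out = n_steps / stride;
  List frames(n_out);
  IntegerVector out_steps(n_out);
  NumericVector out_epot(n_out), out_ekin(n_out);
  int io = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) { double im = dt * 0.5 / S.m[i];
      for (int d = 0; d < 3; ++d) v[3*i+d] += im * f[3*i+d]; }
    // A
    for (int i = 0; i < 3 * n; ++i) S.x[i] += 0.5 * dt * v[i];
    // O
    for (int i = 0; i < n; ++i) { double sd = c2 * std::sqrt(kT / S.m[i]);
      for (int d = 0; d < 3; ++d) v[3*i+d] = c1 * v[3*i+d] + sd * gauss(); }
    // A
    for (int i = 0; i < 3 * n; ++i) S.x[i] += 0.5 * dt * v[i];
    // safety: displacement per step bounded
    for (int i = 0; i < n; ++i) {
      double sp2 = 0.0; for (int d = 0; d < 3; ++d) sp2 += v[3*i+d] * v[3*i+d];
      if (dt * std::sqrt(sp2) > max_step_disp)
        stop("per-step displacement %.2f A of bead %d exceeds the safety bound at step %d",
             dt * std::sqrt(sp2), i + 1, step);
    }
    e = total_forces(S, p, nl, f, skin);
    if (!std::isfinite(e)) stop("non-finite energy at step %d", step);
    // B
    for (int i = 0; i < n; ++i) { double im = dt * 0.5 / S.m[i];
      for (int d = 0; d < 3; ++d) v[3*i+d] += im * f[3*i+d]; }
    if (step % stride == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fr(i, d) = S.x[3*i+d];
      double ke = 0.0;
      for (int i = 0; i < n; ++i) { double s2 = 0.0;
        for (int d = 0; d < 3; ++d) s2 += v[3*i+d] * v[3*i+d];
        ke += 0.5 * S.m[i] * s2; }
      frames[io] = fr; out_steps[io] = step; out_epot[io] = e; out_ekin[io] = ke;
      ++io;
      if (io % 16 == 0) Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
    xf(i, d) = S.x[3*i+d]; vf(i, d) = v[3*i+d];
  }
  return List::create(_["frames"] = frames, _["steps"] = out_steps,
                      _["potential"] = out_epot, _["kinetic"] = out_ekin,
                      _["positions"] = xf, _["velocities"] = vf);
}

// [[Rcpp::export]]
NumericVector cg_pair_distances_cpp(NumericMatrix a, NumericMatrix b, double box) {
  int na = a.nrow(), nb = b.nrow();
  NumericVector out(na * nb);
  int u = 0;
  for (int i = 0; i < na; ++i) for (int j = 0; j < nb; ++j) {
    double d[3] = { a(i,0) - b(j,0), a(i,1) - b(j,1), a(i,2) - b(j,2) };
    min_image(d, box);
    out[u++] = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  }
  return out;
}
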