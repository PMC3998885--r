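// Compiled core of the coarse-grained actomyosin engine: potential energy and
// analytic forces for every term, RATTLE bond constraints, and the
// underdamped Langevin integrator with umbrella biasing.
//
// Units: Angstrom, kcal/mol, radians. Reduced mass/time units for dynamics.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// Deterministic, compiler-independent generator (xoshiro256** seeded by
// splitmix64) with a manual Box-Muller transform.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
};

static inline double wrap_pi_d(double x) {
  // wrap into [-pi, pi) without fmod
  double u = (x + M_PI) / (2.0 * M_PI);
  return x - 2.0 * M_PI * std::floor(u);
}

// ------------------------------------------------------ contact scan ------
// Brute-force residue-pair contact detection on heavy atoms: returns 0-based
// residue index pairs (i < j) with at least one atom pair within cutoff.
// [[Rcpp::export]]
IntegerMatrix heavy_contact_pairs_cpp(NumericMatrix atoms, IntegerVector res,
                                      int nres, double cutoff) {
  int na = atoms.nrow();
  double c2 = cutoff * cutoff;
  std::vector<std::pair<int, int> > hits;
  std::vector<signed char> seen((size_t)nres * 1, 0);
  // use a set keyed by i*nres+j to avoid duplicates
  std::vector<uint8_t> mark;
  mark.assign((size_t)nres * (size_t)nres, 0);
  for (int a = 0; a < na; ++a) {
    double xa = atoms(a, 0), ya = atoms(a, 1), za = atoms(a, 2);
    int ra = res[a];
    for (int b = a + 1; b < na; ++b) {
      int rb = res[b];
      if (ra == rb) continue;
      double dx = xa - atoms(b, 0);
      if (std::fabs(dx) > cutoff) continue;
      double dy = ya - atoms(b, 1), dz = za - atoms(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        int i = ra < rb ? ra : rb, j = ra < rb ? rb : ra;
        size_t key = (size_t)i * (size_t)nres + (size_t)j;
        if (!mark[key]) { mark[key] = 1; hits.push_back(std::make_pair(i, j)); }
      }
    }
  }
  (void)seen;
  IntegerMatrix out(hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    out(k, 0) = hits[k].first;
    out(k, 1) = hits[k].second;
  }
  return out;
}

// ------------------------------------------------------------ model -------
struct PairList {
  std::vector<int> i, j;
  std::vector<double> aux;  // r0 / qq as needed
  std::vector<double> sw1, sw2, sw3;  // per-pair switch params (native)
};

struct CGModel {
  int n;
  std::vector<int> bi, bj; std::vector<double> b0;
  std::vector<int> ai, aj, ak; std::vector<double> th0;
  std::vector<int> di, dj, dk, dl; std::vector<double> ph0;
  PairList native, nonnative, ligand, elec, vdw;
  double nn_rsw, nn_b, nn_c;
  double lj_rsw, lj_b, lj_c;
  std::vector<int> anchor_idx; std::vector<double> anchor_ref;
  std::vector<int> tip_idx; std::vector<double> tip_ref;
  double rail_omega;
  std::vector<int> motor_idx;
  // parameters
  double k_angle, k_dih1, k_dih3, eps_native, eps_nonnative, nonnative_C,
    nonnative_cutoff, k_spring_contact, k_ligand, dh_prefactor, debye_A,
    elec_cutoff, lj_eps, lj_sigma, k_spring_lj, lj_cutoff, k_rail, k_anchor,
    k_umb_z, k_umb_theta;
  bool has_window; double win_zA, win_th;

  // neighbor-list state
  bool use_nlist;
  double skin;
  std::vector<int> nn_act, el_act, vd_act;
  std::vector<double> Xbuild;

  void from_list(const List& m) {
    n = as<int>(m["n"]);
    IntegerMatrix B = m["bonds"];
    NumericVector b0v = m["b0"];
    for (int k = 0; k < B.nrow(); ++k) {
      bi.push_back(B(k, 0)); bj.push_back(B(k, 1)); b0.push_back(b0v[k]);
    }
    IntegerMatrix A = m["angles"]; NumericVector th = m["theta0"];
    for (int k = 0; k < A.nrow(); ++k) {
      ai.push_back(A(k, 0)); aj.push_back(A(k, 1)); ak.push_back(A(k, 2));
      th0.push_back(th[k]);
    }
    IntegerMatrix D = m["dihedrals"]; NumericVector ph = m["phi0"];
    for (int k = 0; k < D.nrow(); ++k) {
      di.push_back(D(k, 0)); dj.push_back(D(k, 1));
      dk.push_back(D(k, 2)); dl.push_back(D(k, 3));
      ph0.push_back(ph[k]);
    }
    IntegerMatrix N = m["native"]; NumericVector r0 = m["r0"];
    NumericMatrix nsw = m["native_switch"];
    for (int k = 0; k < N.nrow(); ++k) {
      native.i.push_back(N(k, 0)); native.j.push_back(N(k, 1));
      native.aux.push_back(r0[k]);
      native.sw1.push_back(nsw(k, 0)); native.sw2.push_back(nsw(k, 1));
      native.sw3.push_back(nsw(k, 2));
    }
    IntegerMatrix NN = m["nonnative"];
    for (int k = 0; k < NN.nrow(); ++k) {
      nonnative.i.push_back(NN(k, 0)); nonnative.j.push_back(NN(k, 1));
    }
    NumericVector nns = m["nonnative_switch"];
    nn_rsw = nns[0]; nn_b = nns[1]; nn_c = nns[2];
    IntegerMatrix L = m["ligand_pairs"]; NumericVector lr0 = m["lr0"];
    for (int k = 0; k < L.nrow(); ++k) {
      ligand.i.push_back(L(k, 0)); ligand.j.push_back(L(k, 1));
      ligand.aux.push_back(lr0[k]);
    }
    IntegerMatrix E = m["elec"]; NumericVector qq = m["qq"];
    for (int k = 0; k < E.nrow(); ++k) {
      elec.i.push_back(E(k, 0)); elec.j.push_back(E(k, 1));
      elec.aux.push_back(qq[k]);
    }
    IntegerMatrix V = m["vdw"];
    for (int k = 0; k < V.nrow(); ++k) {
      vdw.i.push_back(V(k, 0)); vdw.j.push_back(V(k, 1));
    }
    NumericVector ljs = m["lj_switch"];
    lj_rsw = ljs[0]; lj_b = ljs[1]; lj_c = ljs[2];
    IntegerVector anc = m["anchor_idx"];
    anchor_idx.assign(anc.begin(), anc.end());
    NumericMatrix ar = m["anchor_ref"];
    anchor_ref.resize(anchor_idx.size() * 3);
    for (size_t k = 0; k < anchor_idx.size(); ++k)
      for (int d = 0; d < 3; ++d) anchor_ref[3 * k + d] = ar(k, d);
    IntegerVector tip = m["tip_idx"];
    tip_idx.assign(tip.begin(), tip.end());
    NumericMatrix tr = m["tip_ref"];
    tip_ref.resize(tip_idx.size() * 3);
    for (size_t k = 0; k < tip_idx.size(); ++k)
      for (int d = 0; d < 3; ++d) tip_ref[3 * k + d] = tr(k, d);
    rail_omega = as<double>(m["rail_omega"]);
    IntegerVector mo = m["motor_idx"];
    motor_idx.assign(mo.begin(), mo.end());
    List p = m["params"];
    k_angle = as<double>(p["k_angle"]);
    k_dih1 = as<double>(p["k_dih1"]);
    k_dih3 = as<double>(p["k_dih3"]);
    eps_native = as<double>(p["eps_native"]);
    eps_nonnative = as<double>(p["eps_nonnative"]);
    nonnative_C = as<double>(p["nonnative_C"]);
    nonnative_cutoff = as<double>(p["nonnative_cutoff"]);
    k_spring_contact = as<double>(p["k_spring_contact"]);
    k_ligand = as<double>(p["k_ligand"]);
    dh_prefactor = as<double>(p["dh_prefactor"]);
    debye_A = as<double>(p["debye_length_A"]);
    elec_cutoff = as<double>(p["elec_cutoff"]);
    lj_eps = as<double>(p["lj_eps"]);
    lj_sigma = as<double>(p["lj_sigma"]);
    k_spring_lj = as<double>(p["k_spring_lj"]);
    lj_cutoff = as<double>(p["lj_cutoff"]);
    k_rail = as<double>(p["k_rail"]);
    k_anchor = as<double>(p["k_anchor"]);
    k_umb_z = as<double>(p["k_umb_z"]);
    k_umb_theta = as<double>(p["k_umb_theta"]);
    NumericVector w = m["window"];
    has_window = w.size() == 2;
    if (has_window) { win_zA = w[0]; win_th = w[1]; }
    use_nlist = false;
    skin = 2.0;
  }

  void build_nlist(const std::vector<double>& X) {
    nn_act.clear(); el_act.clear(); vd_act.clear();
    double c;
    c = nonnative_cutoff + skin;
    for (size_t k = 0; k < nonnative.i.size(); ++k) {
      double dx = X[3 * nonnative.i[k]] - X[3 * nonnative.j[k]];
      double dy = X[3 * nonnative.i[k] + 1] - X[3 * nonnative.j[k] + 1];
      double dz = X[3 * nonnative.i[k] + 2] - X[3 * nonnative.j[k] + 2];
      if (dx * dx + dy * dy + dz * dz < c * c) nn_act.push_back((int)k);
    }
    c = elec_cutoff + skin;
    for (size_t k = 0; k < elec.i.size(); ++k) {
      double dx = X[3 * elec.i[k]] - X[3 * elec.j[k]];
      double dy = X[3 * elec.i[k] + 1] - X[3 * elec.j[k] + 1];
      double dz = X[3 * elec.i[k] + 2] - X[3 * elec.j[k] + 2];
      if (dx * dx + dy * dy + dz * dz < c * c) el_act.push_back((int)k);
    }
    c = lj_cutoff + skin;
    for (size_t k = 0; k < vdw.i.size(); ++k) {
      double dx = X[3 * vdw.i[k]] - X[3 * vdw.j[k]];
      double dy = X[3 * vdw.i[k] + 1] - X[3 * vdw.j[k] + 1];
      double dz = X[3 * vdw.i[k] + 2] - X[3 * vdw.j[k] + 2];
      if (dx * dx + dy * dy + dz * dz < c * c) vd_act.push_back((int)k);
    }
    Xbuild = X;
  }

  bool nlist_stale(const std::vector<double>& X) const {
    if (Xbuild.size() != X.size()) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = X[3 * i] - Xbuild[3 * i];
      double dy = X[3 * i + 1] - Xbuild[3 * i + 1];
      double dz = X[3 * i + 2] - Xbuild[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// terms order
enum { T_ANGLE, T_DIH, T_NATIVE, T_NONNAT, T_LIG, T_ELEC, T_VDW, T_RAIL,
       T_ANCHOR, T_UMB, NTERMS };
static const char* TERM_NAMES[NTERMS] = {
  "angle", "dihedral", "native", "nonnative", "ligand", "elec", "vdw",
  "rail", "anchor", "umbrella" };

static inline void add_pair_force(std::vector<double>* F, int i, int j,
                                  double dVdr, double dx, double dy,
                                  double dz, double r) {
  if (!F) return;
  double f = dVdr / r;
  (*F)[3 * i]     -= f * dx; (*F)[3 * i + 1] -= f * dy; (*F)[3 * i + 2] -= f * dz;
  (*F)[3 * j]     += f * dx; (*F)[3 * j + 1] += f * dy; (*F)[3 * j + 2] += f * dz;
}

// Full potential energy and (optionally) forces. F may be null.
static double energy_forces(CGModel& M, const std::vector<double>& X,
                            std::vector<double>* F, double* terms) {
  for (int t = 0; t < NTERMS; ++t) terms[t] = 0.0;
  if (F) std::fill(F->begin(), F->end(), 0.0);

  // bond angles: V = k (theta - theta0)^2
  for (size_t k = 0; k < M.ai.size(); ++k) {
    int i = M.ai[k], j = M.aj[k], l = M.ak[k];
    double ux = X[3 * i] - X[3 * j], uy = X[3 * i + 1] - X[3 * j + 1],
      uz = X[3 * i + 2] - X[3 * j + 2];
    double vx = X[3 * l] - X[3 * j], vy = X[3 * l + 1] - X[3 * j + 1],
      vz = X[3 * l + 2] - X[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0 - 1e-12) c = 1.0 - 1e-12;
    if (c < -1.0 + 1e-12) c = -1.0 + 1e-12;
    double th = std::acos(c);
    double d = th - M.th0[k];
    terms[T_ANGLE] += M.k_angle * d * d;
    if (F) {
      double s = std::sqrt(1.0 - c * c);
      double dVdth = 2.0 * M.k_angle * d;
      double coef = -dVdth / s;  // dV/dcos
      // dcos/dri etc.
      double dcix = (vx / (nu * nv)) - c * ux / (nu * nu);
      double dciy = (vy / (nu * nv)) - c * uy / (nu * nu);
      double dciz = (vz / (nu * nv)) - c * uz / (nu * nu);
      double dclx = (ux / (nu * nv)) - c * vx / (nv * nv);
      double dcly = (uy / (nu * nv)) - c * vy / (nv * nv);
      double dclz = (uz / (nu * nv)) - c * vz / (nv * nv);
      (*F)[3 * i] -= coef * dcix; (*F)[3 * i + 1] -= coef * dciy;
      (*F)[3 * i + 2] -= coef * dciz;
      (*F)[3 * l] -= coef * dclx; (*F)[3 * l + 1] -= coef * dcly;
      (*F)[3 * l + 2] -= coef * dclz;
      (*F)[3 * j] += coef * (dcix + dclx);
      (*F)[3 * j + 1] += coef * (dciy + dcly);
      (*F)[3 * j + 2] += coef * (dciz + dclz);
    }
  }

  // dihedrals: V = k1 [1 - cos(phi - phi0)] + k3 [1 - cos 3(phi - phi0)]
  for (size_t k = 0; k < M.di.size(); ++k) {
    int i1 = M.di[k], i2 = M.dj[k], i3 = M.dk[k], i4 = M.dl[k];
    double b1x = X[3 * i2] - X[3 * i1], b1y = X[3 * i2 + 1] - X[3 * i1 + 1],
      b1z = X[3 * i2 + 2] - X[3 * i1 + 2];
    double b2x = X[3 * i3] - X[3 * i2], b2y = X[3 * i3 + 1] - X[3 * i2 + 1],
      b2z = X[3 * i3 + 2] - X[3 * i2 + 2];
    double b3x = X[3 * i4] - X[3 * i3], b3y = X[3 * i4 + 1] - X[3 * i3 + 1],
      b3z = X[3 * i4 + 2] - X[3 * i3 + 2];
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
      n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
      n2z = b2x * b3y - b2y * b3x;
    double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
    double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1sq < 1e-16 || n2sq < 1e-16)
      stop("degenerate dihedral (three collinear beads)");
    double m1x = n1y * b2z - n1z * b2y, m1y = n1z * b2x - n1x * b2z,
      m1z = n1x * b2y - n1y * b2x;
    double xx = n1x * n2x + n1y * n2y + n1z * n2z;
    double yy = (m1x * n2x + m1y * n2y + m1z * n2z) / nb2;
    double phi = std::atan2(yy, xx);
    double d = phi - M.ph0[k];
    terms[T_DIH] += M.k_dih1 * (1.0 - std::cos(d)) +
      M.k_dih3 * (1.0 - std::cos(3.0 * d));
    if (F) {
      double dVdphi = M.k_dih1 * std::sin(d) +
        3.0 * M.k_dih3 * std::sin(3.0 * d);
      double g1 = nb2 / n1sq, g4 = -nb2 / n2sq;
      double f1x = g1 * n1x, f1y = g1 * n1y, f1z = g1 * n1z;
      double f4x = g4 * n2x, f4y = g4 * n2y, f4z = g4 * n2z;
      double p = (b1x * b2x + b1y * b2y + b1z * b2z) / (nb2 * nb2);
      double q = (b3x * b2x + b3y * b2y + b3z * b2z) / (nb2 * nb2);
      double f2x = -(1.0 + p) * f1x + q * f4x;
      double f2y = -(1.0 + p) * f1y + q * f4y;
      double f2z = -(1.0 + p) * f1z + q * f4z;
      double f3x = p * f1x - (1.0 + q) * f4x;
      double f3y = p * f1y - (1.0 + q) * f4y;
      double f3z = p * f1z - (1.0 + q) * f4z;
      (*F)[3 * i1] -= dVdphi * f1x; (*F)[3 * i1 + 1] -= dVdphi * f1y;
      (*F)[3 * i1 + 2] -= dVdphi * f1z;
      (*F)[3 * i2] -= dVdphi * f2x; (*F)[3 * i2 + 1] -= dVdphi * f2y;
      (*F)[3 * i2 + 2] -= dVdphi * f2z;
      (*F)[3 * i3] -= dVdphi * f3x; (*F)[3 * i3 + 1] -= dVdphi * f3y;
      (*F)[3 * i3 + 2] -= dVdphi * f3z;
      (*F)[3 * i4] -= dVdphi * f4x; (*F)[3 * i4 + 1] -= dVdphi * f4y;
      (*F)[3 * i4 + 2] -= dVdphi * f4z;
    }
  }

  // native 12-10 contacts with spring continuation
  for (size_t k = 0; k < M.native.i.size(); ++k) {
    int i = M.native.i[k], j = M.native.j[k];
    double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
      dz = X[3 * i + 2] - X[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("zero distance in native pair");
    double r0 = M.native.aux[k], rsw = M.native.sw1[k];
    double V, dV;
    if (r >= rsw) {
      double s = r0 / r;
      double s2 = s * s, s4 = s2 * s2, s10 = s4 * s4 * s2, s12 = s10 * s2;
      V = M.eps_native * (5.0 * s12 - 6.0 * s10);
      dV = -60.0 * M.eps_native * (r0 / (r * r)) * (s12 / s - s10 / s);
    } else {
      double b = M.native.sw2[k], c = M.native.sw3[k];
      V = M.k_spring_contact * (r - b) * (r - b) + c;
      dV = 2.0 * M.k_spring_contact * (r - b);
    }
    terms[T_NATIVE] += V;
    add_pair_force(F, i, j, dV, dx, dy, dz, r);
  }

  // nonnative repulsion
  {
    double cut2 = M.nonnative_cutoff * M.nonnative_cutoff;
    const std::vector<int>* act = M.use_nlist ? &M.nn_act : 0;
    size_t nk = act ? act->size() : M.nonnative.i.size();
    for (size_t kk = 0; kk < nk; ++kk) {
      size_t k = act ? (size_t)(*act)[kk] : kk;
      int i = M.nonnative.i[k], j = M.nonnative.j[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
        dz = X[3 * i + 2] - X[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      double V, dV;
      if (r >= M.nn_rsw) {
        double s = M.nonnative_C / r;
        double s2 = s * s, s4 = s2 * s2, s12 = s4 * s4 * s4;
        V = M.eps_nonnative * s12;
        dV = -12.0 * V / r;
      } else {
        V = M.k_spring_contact * (r - M.nn_b) * (r - M.nn_b) + M.nn_c;
        dV = 2.0 * M.k_spring_contact * (r - M.nn_b);
      }
      terms[T_NONNAT] += V;
      add_pair_force(F, i, j, dV, dx, dy, dz, r);
    }
  }

  // ligand restraints: V = k (r - r0)^2
  for (size_t k = 0; k < M.ligand.i.size(); ++k) {
    int i = M.ligand.i[k], j = M.ligand.j[k];
    double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
      dz = X[3 * i + 2] - X[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - M.ligand.aux[k];
    terms[T_LIG] += M.k_ligand * d * d;
    add_pair_force(F, i, j, 2.0 * M.k_ligand * d, dx, dy, dz, r);
  }

  // Debye-Hueckel electrostatics across the myosin-actin interface
  {
    double cut2 = M.elec_cutoff * M.elec_cutoff;
    const std::vector<int>* act = M.use_nlist ? &M.el_act : 0;
    size_t nk = act ? act->size() : M.elec.i.size();
    for (size_t kk = 0; kk < nk; ++kk) {
      size_t k = act ? (size_t)(*act)[kk] : kk;
      int i = M.elec.i[k], j = M.elec.j[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
        dz = X[3 * i + 2] - X[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      double V = M.dh_prefactor * M.elec.aux[k] *
        std::exp(-r / M.debye_A) / r;
      double dV = -V * (1.0 / r + 1.0 / M.debye_A);
      terms[T_ELEC] += V;
      add_pair_force(F, i, j, dV, dx, dy, dz, r);
    }
  }

  // 12-6 Lennard-Jones across the interface with spring continuation
  {
    double cut2 = M.lj_cutoff * M.lj_cutoff;
    const std::vector<int>* act = M.use_nlist ? &M.vd_act : 0;
    size_t nk = act ? act->size() : M.vdw.i.size();
    for (size_t kk = 0; kk < nk; ++kk) {
      size_t k = act ? (size_t)(*act)[kk] : kk;
      int i = M.vdw.i[k], j = M.vdw.j[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
        dz = X[3 * i + 2] - X[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      double V, dV;
      if (r >= M.lj_rsw) {
        double s = M.lj_sigma / r;
        double s2 = s * s, s6 = s2 * s2 * s2, s12 = s6 * s6;
        V = M.lj_eps * (s12 - 2.0 * s6);
        dV = -12.0 * M.lj_eps * (M.lj_sigma / (r * r)) * (s12 / s - s6 / s);
      } else {
        V = M.k_spring_lj * (r - M.lj_b) * (r - M.lj_b) + M.lj_c;
        dV = 2.0 * M.k_spring_lj * (r - M.lj_b);
      }
      terms[T_VDW] += V;
      add_pair_force(F, i, j, dV, dx, dy, dz, r);
    }
  }

  // curtain rail: each tip particle restrained to the helical rail through
  // its reference position (zero force along the rail)
  for (size_t k = 0; k < M.tip_idx.size(); ++k) {
    int i = M.tip_idx[k];
    double x0 = M.tip_ref[3 * k], y0 = M.tip_ref[3 * k + 1],
      z0 = M.tip_ref[3 * k + 2];
    double x = X[3 * i], y = X[3 * i + 1], z = X[3 * i + 2];
    double ph = M.rail_omega * (z - z0);
    double c = std::cos(ph), s = std::sin(ph);
    double Xr = x0 * c - y0 * s, Yr = x0 * s + y0 * c;
    double ex = x - Xr, ey = y - Yr;
    terms[T_RAIL] += 0.5 * M.k_rail * (ex * ex + ey * ey);
    if (F) {
      (*F)[3 * i] -= M.k_rail * ex;
      (*F)[3 * i + 1] -= M.k_rail * ey;
      // dXr/dz = -omega*Yr ; dYr/dz = omega*Xr
      (*F)[3 * i + 2] -= M.k_rail * (ex * (M.rail_omega * Yr) -
                                     ey * (M.rail_omega * Xr));
    }
  }

  // actin anchors: V = 1/2 k |r - r0|^2
  for (size_t k = 0; k < M.anchor_idx.size(); ++k) {
    int i = M.anchor_idx[k];
    double dx = X[3 * i] - M.anchor_ref[3 * k];
    double dy = X[3 * i + 1] - M.anchor_ref[3 * k + 1];
    double dz = X[3 * i + 2] - M.anchor_ref[3 * k + 2];
    terms[T_ANCHOR] += 0.5 * M.k_anchor * (dx * dx + dy * dy + dz * dz);
    if (F) {
      (*F)[3 * i] -= M.k_anchor * dx;
      (*F)[3 * i + 1] -= M.k_anchor * dy;
      (*F)[3 * i + 2] -= M.k_anchor * dz;
    }
  }

  // umbrella bias on the motor-domain centroid in (z, theta)
  if (M.has_window && M.motor_idx.size()) {
    int N = (int)M.motor_idx.size();
    double mx = 0, my = 0, mz = 0;
    for (int k = 0; k < N; ++k) {
      int i = M.motor_idx[k];
      mx += X[3 * i]; my += X[3 * i + 1]; mz += X[3 * i + 2];
    }
    mx /= N; my /= N; mz /= N;
    double rho2 = mx * mx + my * my;
    if (rho2 < 1e-12) stop("motor centroid on the filament axis");
    double th = std::atan2(my, mx);
    double dth = wrap_pi_d(th - M.win_th);
    double dz = mz - M.win_zA;
    terms[T_UMB] += 0.5 * M.k_umb_z * dz * dz +
      0.5 * M.k_umb_theta * dth * dth;
    if (F) {
      double fz = M.k_umb_z * dz / N;
      double fth = M.k_umb_theta * dth / N;
      for (int k = 0; k < N; ++k) {
        int i = M.motor_idx[k];
        (*F)[3 * i] -= fth * (-my / rho2);
        (*F)[3 * i + 1] -= fth * (mx / rho2);
        (*F)[3 * i + 2] -= fz;
      }
    }
  }

  double tot = 0;
  for (int t = 0; t < NTERMS; ++t) {
    if (!std::isfinite(terms[t]))
      stop(std::string("non-finite energy in term '") + TERM_NAMES[t] + "'");
    tot += terms[t];
  }
  return tot;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix X, List model, bool want_forces = false,
                   bool use_nlist = false) {
  CGModel M;
  M.from_list(model);
  std::vector<double> x(M.n * 3);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = X(i, d);
  M.use_nlist = use_nlist;
  if (use_nlist) M.build_nlist(x);
  std::vector<double> F;
  if (want_forces) F.resize(M.n * 3);
  double terms[NTERMS];
  double tot = energy_forces(M, x, want_forces ? &F : 0, terms);
  NumericVector tv(NTERMS);
  CharacterVector tn(NTERMS);
  for (int t = 0; t < NTERMS; ++t) { tv[t] = terms[t]; tn[t] = TERM_NAMES[t]; }
  tv.attr("names") = tn;
  List out = List::create(_["total"] = tot, _["terms"] = tv);
  if (want_forces) {
    NumericMatrix Fm(M.n, 3);
    for (int i = 0; i < M.n; ++i)
      for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
    out["forces"] = Fm;
  }
  return out;
}

// ------------------------------------------------------------ RATTLE ------
static void rattle_positions(const std::vector<int>& bi,
                             const std::vector<int>& bj,
                             const std::vector<double>& b0,
                             const std::vector<double>& Xprev,
                             std::vector<double>& X,
                             std::vector<double>* V, double dt,
                             double tol, int maxit, bool* ok) {
  size_t nb = bi.size();
  *ok = true;
  if (!nb) return;
  for (int it = 0; it < maxit; ++it) {
    double worst = 0.0;
    for (size_t k = 0; k < nb; ++k) {
      int i = bi[k], j = bj[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
        dz = X[3 * i + 2] - X[3 * j + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double diff = d2 - b0[k] * b0[k];
      double rel = std::fabs(diff) / (b0[k] * b0[k]);
      if (rel > worst) worst = rel;
      if (rel < tol) continue;
      double rx = Xprev[3 * i] - Xprev[3 * j],
        ry = Xprev[3 * i + 1] - Xprev[3 * j + 1],
        rz = Xprev[3 * i + 2] - Xprev[3 * j + 2];
      double denom = 2.0 * (dx * rx + dy * ry + dz * rz) * 2.0;  // 1/mi+1/mj=2
      if (std::fabs(denom) < 1e-12) continue;
      double g = diff / denom;
      X[3 * i] -= g * rx; X[3 * i + 1] -= g * ry; X[3 * i + 2] -= g * rz;
      X[3 * j] += g * rx; X[3 * j + 1] += g * ry; X[3 * j + 2] += g * rz;
      if (V) {
        double gv = g / dt;
        (*V)[3 * i] -= gv * rx; (*V)[3 * i + 1] -= gv * ry;
        (*V)[3 * i + 2] -= gv * rz;
        (*V)[3 * j] += gv * rx; (*V)[3 * j + 1] += gv * ry;
        (*V)[3 * j + 2] += gv * rz;
      }
    }
    if (worst < tol) return;
  }
  *ok = false;
}

static void rattle_velocities(const std::vector<int>& bi,
                              const std::vector<int>& bj,
                              const std::vector<double>& X,
                              std::vector<double>& V,
                              double tol, int maxit) {
  size_t nb = bi.size();
  if (!nb) return;
  for (int it = 0; it < maxit; ++it) {
    double worst = 0.0;
    for (size_t k = 0; k < nb; ++k) {
      int i = bi[k], j = bj[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
        dz = X[3 * i + 2] - X[3 * j + 2];
      double vx = V[3 * i] - V[3 * j], vy = V[3 * i + 1] - V[3 * j + 1],
        vz = V[3 * i + 2] - V[3 * j + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double dot = dx * vx + dy * vy + dz * vz;
      double rel = std::fabs(dot) / d2;
      if (rel > worst) worst = rel;
      if (rel < tol) continue;
      double kcoef = dot / (d2 * 2.0);
      V[3 * i] -= kcoef * dx; V[3 * i + 1] -= kcoef * dy;
      V[3 * i + 2] -= kcoef * dz;
      V[3 * j] += kcoef * dx; V[3 * j + 1] += kcoef * dy;
      V[3 * j + 2] += kcoef * dz;
    }
    if (worst < tol) return;
  }
}

// [[Rcpp::export]]
NumericMatrix rattle_positions_cpp(NumericMatrix Xprev, NumericMatrix Xnew,
                                   IntegerMatrix bonds, NumericVector b0,
                                   double tol = 1e-12, int maxit = 500) {
  int n = Xnew.nrow();
  std::vector<double> xp(3 * n), x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xp[3 * i + d] = Xprev(i, d);
      x[3 * i + d] = Xnew(i, d);
    }
  std::vector<int> bi, bj;
  std::vector<double> bl;
  for (int k = 0; k < bonds.nrow(); ++k) {
    bi.push_back(bonds(k, 0) - 1); bj.push_back(bonds(k, 1) - 1);
    bl.push_back(b0[k]);
  }
  bool ok;
  rattle_positions(bi, bj, bl, xp, x, 0, 1.0, tol, maxit, &ok);
  if (!ok) stop("RATTLE did not converge in %d iterations", maxit);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}

// ------------------------------------------------------ Langevin run ------
// Velocity-Verlet Langevin (BBK discretization) with RATTLE constraints.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix X0, List model, List lpar) {
  CGModel M;
  M.from_list(model);
  int n = M.n;
  double dt = as<double>(lpar["dt"]);
  double gamma = as<double>(lpar["friction"]);
  double mass = as<double>(lpar["mass"]);
  double temperature = as<double>(lpar["temperature"]);
  long nsteps = (long)as<double>(lpar["n_steps"]);
  int stride = as<int>(lpar["stride"]);
  uint64_t seed = (uint64_t)as<double>(lpar["seed"]);
  bool use_nlist = as<bool>(lpar["use_nlist"]);
  double ctol = as<double>(lpar["constraint_tol"]);
  double kBT = 1.987204259e-3 * temperature;
  double blow = as<double>(lpar["blowup"]);

  std::vector<double> x(3 * n), xprev(3 * n), v(3 * n), f(3 * n), r(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = X0(i, d);

  RNG rng(seed);
  double vsig = std::sqrt(kBT / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = vsig * rng.gauss();
  rattle_velocities(M.bi, M.bj, x, v, 1e-12, 500);

  M.use_nlist = use_nlist;
  if (use_nlist) M.build_nlist(x);
  double terms[NTERMS];
  double epot = energy_forces(M, x, &f, terms);

  double rsig = std::sqrt(2.0 * gamma * mass * kBT / dt);
  for (int i = 0; i < 3 * n; ++i) r[i] = rsig * rng.gauss();

  long nrec = stride > 0 ? nsteps / stride : 0;
  NumericMatrix series(nrec, 4);
  long irec = 0;
  double half = 0.5 * dt / mass;
  double damp1 = 1.0 - 0.5 * gamma * dt;
  double damp2 = 1.0 / (1.0 + 0.5 * gamma * dt);
  double max_bond_dev = 0.0;

  for (long step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < 3 * n; ++i)
      v[i] = damp1 * v[i] + half * (f[i] + r[i]);
    xprev = x;
    for (int i = 0; i < 3 * n; ++i) {
      double dx = dt * v[i];
      if (std::fabs(dx) > blow)
        stop("position update exceeded %g A at step %ld; reduce dt",
             blow, step);
      x[i] += dx;
    }
    bool ok;
    rattle_positions(M.bi, M.bj, M.b0, xprev, x, &v, dt, ctol, 500, &ok);
    if (!ok) stop("RATTLE did not converge at step %ld", step);
    if (use_nlist && M.nlist_stale(x)) M.build_nlist(x);
    epot = energy_forces(M, x, &f, terms);
    for (int i = 0; i < 3 * n; ++i) r[i] = rsig * rng.gauss();
    for (int i = 0; i < 3 * n; ++i)
      v[i] = damp2 * (v[i] + half * (f[i] + r[i]));
    rattle_velocities(M.bi, M.bj, x, v, 1e-14, 500);

    if (stride > 0 && step % stride == 0 && irec < nrec) {
      double mx = 0, my = 0, mz = 0;
      int N = (int)M.motor_idx.size();
      if (N) {
        for (int k = 0; k < N; ++k) {
          int i = M.motor_idx[k];
          mx += x[3 * i]; my += x[3 * i + 1]; mz += x[3 * i + 2];
        }
        mx /= N; my /= N; mz /= N;
      }
      double th = std::atan2(my, mx);
      if (th < 0) th += 2.0 * M_PI;
      series(irec, 0) = (double)step;
      series(irec, 1) = mz / 10.0;  // Angstrom -> nm
      series(irec, 2) = th;
      series(irec, 3) = epot;
      ++irec;
    }
    if (step % 1000 == 0) {
      for (size_t k = 0; k < M.bi.size(); ++k) {
        double dx = x[3 * M.bi[k]] - x[3 * M.bj[k]];
        double dy = x[3 * M.bi[k] + 1] - x[3 * M.bj[k] + 1];
        double dz = x[3 * M.bi[k] + 2] - x[3 * M.bj[k] + 2];
        double dev = std::fabs(std::sqrt(dx * dx + dy * dy + dz * dz) -
                               M.b0[k]);
        if (dev > max_bond_dev) max_bond_dev = dev;
      }
    }
  }
  // final bond deviation check
  for (size_t k = 0; k < M.bi.size(); ++k) {
    double dx = x[3 * M.bi[k]] - x[3 * M.bj[k]];
    double dy = x[3 * M.bi[k] + 1] - x[3 * M.bj[k] + 1];
    double dz = x[3 * M.bi[k] + 2] - x[3 * M.bj[k] + 2];
    double dev = std::fabs(std::sqrt(dx * dx + dy * dy + dz * dz) - M.b0[k]);
    if (dev > max_bond_dev) max_bond_dev = dev;
  }

  NumericMatrix Xf(n, 3), Vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Xf(i, d) = x[3 * i + d];
      Vf(i, d) = v[3 * i + d];
    }
  return List::create(_["series"] = series, _["X"] = Xf, _["V"] = Vf,
                      _["max_bond_dev"] = max_bond_dev,
                      _["epot"] = epot);
}
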