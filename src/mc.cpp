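// Metropolis Monte Carlo engines: lattice diffusion on a single free-energy
// landscape (detailed-balance and isotropy checks) and the multi-landscape
// actomyosin stepping simulation with stochastic switching among kinetic
// states and absorption into the rigor state.
//
// Landscapes are in units of thermal energy; coordinates in nm / rad.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

struct MCRNG {
  uint64_t s[4];
  MCRNG(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
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
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Free-energy landscape on a regular (z, theta) grid with helical
// periodicity: F(z + L, theta + twist) = F(z, theta); theta periodic 2*pi.
struct Lscape {
  std::vector<double> F;  // nz * nth, row-major [i*nth + j]
  int nz, nth;
  double z0, dz, L, twist, dth;
  double invL, invdz, inv2pi;
  bool valid;

  void from_list(const List& l) {
    NumericMatrix Fm = l["F"];
    nz = Fm.nrow(); nth = Fm.ncol();
    F.resize((size_t)nz * nth);
    for (int i = 0; i < nz; ++i)
      for (int j = 0; j < nth; ++j) F[(size_t)i * nth + j] = Fm(i, j);
    z0 = as<double>(l["z0"]);
    dz = as<double>(l["dz"]);
    L = as<double>(l["period"]);
    twist = as<double>(l["twist"]);
    dth = 2.0 * M_PI / nth;
    invL = 1.0 / L; invdz = 1.0 / dz; inv2pi = 1.0 / (2.0 * M_PI);
    valid = true;
  }

  // linear interpolation in theta on grid column i (slow path)
  inline double col_eval(int i, double th) const {
    double v = th * inv2pi;
    v -= std::floor(v);
    double uj = v * nth;
    int j = (int)uj;
    if (j >= nth) j = nth - 1;
    double t = uj - j;
    int j1 = j + 1; if (j1 == nth) j1 = 0;
    double a = F[(size_t)i * nth + j], b = F[(size_t)i * nth + j1];
    return a + t * (b - a);  // NaN propagates
  }

  double eval(double z, double th) const {
    double u = (z - z0) * invL;
    double nwrap = std::floor(u);
    double zp = (u - nwrap) * L;  // in [0, L)
    double xi = zp * invdz;
    int i = (int)xi;
    double tz = xi - i;
    if (i >= nz) { i = nz - 1; tz = 1.0; }
    double thp = th - nwrap * twist;
    if (i + 1 < nz) {
      double v = thp * inv2pi;
      v -= std::floor(v);
      double uj = v * nth;
      int j = (int)uj;
      if (j >= nth) j = nth - 1;
      double tj = uj - j;
      int j1 = j + 1; if (j1 == nth) j1 = 0;
      const double* r0 = &F[(size_t)i * nth];
      const double* r1 = r0 + nth;
      double a = r0[j] + tj * (r0[j1] - r0[j]);
      double b = r1[j] + tj * (r1[j1] - r1[j]);
      return a + tz * (b - a);
    }
    // last cell: upper neighbor is the helical image of column 0
    double a = col_eval(i, thp);
    double b = col_eval(0, thp - twist);
    return a + tz * (b - a);
  }
};

// ---------------------------------------------------- single landscape ----
// Lattice Metropolis walk on the landscape's own grid (periodic both ways).
// Returns occupancy counts over the grid after burn-in.
// [[Rcpp::export]]
IntegerMatrix mc_lattice_sample_cpp(NumericMatrix F, double pz,
                                    double nsteps, double burnin,
                                    double seed, int iz0, int ith0) {
  int nz = F.nrow(), nth = F.ncol();
  IntegerMatrix counts(nz, nth);
  MCRNG rng((uint64_t)seed, 1);
  int iz = iz0, ith = ith0;
  double Fc = F(iz, ith);
  long nst = (long)nsteps, nb = (long)burnin;
  for (long s = 0; s < nst; ++s) {
    bool zmove = rng.unif() < pz;
    int dir = rng.unif() < 0.5 ? -1 : 1;
    int izn = iz, ithn = ith;
    if (zmove) izn = ((iz + dir) % nz + nz) % nz;
    else ithn = ((ith + dir) % nth + nth) % nth;
    double Fn = F(izn, ithn);
    double dF = Fn - Fc;
    if (R_finite(Fn) && (dF <= 0 || rng.unif() < std::exp(-dF))) {
      iz = izn; ith = ithn; Fc = Fn;
    }
    if (s >= nb) counts(iz, ith)++;
  }
  return counts;
}

// Unwrapped lattice walk on a (possibly flat) landscape; records the
// unwrapped (iz, ith) indices every `stride` steps.
// [[Rcpp::export]]
NumericMatrix mc_lattice_walk_cpp(NumericMatrix F, double pz, double nsteps,
                                  int stride, double seed,
                                  int iz0, int ith0) {
  int nz = F.nrow(), nth = F.ncol();
  MCRNG rng((uint64_t)seed, 2);
  long iz = iz0, ith = ith0;
  long nst = (long)nsteps;
  long nrec = nst / stride;
  NumericMatrix out(nrec, 3);
  long irec = 0;
  long wi = ((iz % nz) + nz) % nz, wj = ((ith % nth) + nth) % nth;
  double Fc = F(wi, wj);
  for (long s = 1; s <= nst; ++s) {
    bool zmove = rng.unif() < pz;
    int dir = rng.unif() < 0.5 ? -1 : 1;
    long izn = iz, ithn = ith;
    if (zmove) izn += dir; else ithn += dir;
    long wi2 = ((izn % nz) + nz) % nz, wj2 = ((ithn % nth) + nth) % nth;
    double Fn = F(wi2, wj2);
    double dF = Fn - Fc;
    if (R_finite(Fn) && (dF <= 0 || rng.unif() < std::exp(-dF))) {
      iz = izn; ith = ithn; Fc = Fn;
    }
    if (stride > 0 && s % stride == 0 && irec < nrec) {
      out(irec, 0) = (double)s;
      out(irec, 1) = (double)iz;
      out(irec, 2) = (double)ith;
      ++irec;
    }
  }
  return out;
}

// ------------------------------------------------- actomyosin stepping ----
// States (1-based from R): 1 A.Mpre.ADP.Pi, 2 A.Mpost.ADP.Pi, 3 A.Mpre.ADP,
// 4 A.Mpost.ADP, 5 A.Mclosed.ADP, 6 A.Mpost, 7 A.Mclosed, 8 A.Mrigor.
//
// Per MCS: (i) attempt a state change (position preserved); from A.Mclosed
// within the admissible valley region, rigor entry with probability k_w;
// (ii) otherwise pick the move axis (z with probability p_z); (iii) pick the
// direction with probability 1/2; (iv) Metropolis-accept on the free-energy
// difference. Moves into unsampled (NaN) bins are rejected and counted.
// [[Rcpp::export]]
List run_actomyosin_mc_cpp(List landscapes, NumericMatrix trans,
                           List mcpar, int n_traj, double seed,
                           int n_record, int record_stride) {
  int nstate = trans.nrow();  // 8, rigor last
  int rigor = nstate - 1;     // 0-based index of rigor
  int closed = as<int>(mcpar["closed_state"]) - 1;   // A.Mclosed (0-based)
  std::vector<Lscape> ls(nstate);
  for (int s = 0; s < nstate; ++s) {
    if (s == rigor) { ls[s].valid = false; continue; }
    ls[s].from_list(landscapes[s]);
  }
  double dz = as<double>(mcpar["dz"]);
  double dth = as<double>(mcpar["dtheta"]);
  double pz = as<double>(mcpar["p_z"]);
  double kw = as<double>(mcpar["k_w"]);
  double max_steps = as<double>(mcpar["max_steps"]);
  NumericVector adm = mcpar["admissible_z"];  // centers mod L, nm
  double admw = as<double>(mcpar["admissible_halfwidth"]);
  double zs_min = as<double>(mcpar["z_start_min"]);
  double zs_rng = as<double>(mcpar["z_start_range"]);
  double th_slope = as<double>(mcpar["theta_start_slope"]);  // rad per nm
  int state0 = as<int>(mcpar["start_state"]) - 1;
  double L = ls[closed].L;

  NumericVector D(n_traj), z_entry(n_traj), z_final(n_traj), steps(n_traj);
  LogicalVector completed(n_traj), entered(n_traj);
  IntegerMatrix trans_count(nstate, nstate);
  NumericVector rejected_missing(1);
  List recs(std::min(n_record, n_traj));

  // per-state cumulative switch tables
  std::vector<std::vector<double> > cum(nstate);
  std::vector<std::vector<int> > dest(nstate);
  for (int s = 0; s < nstate; ++s) {
    double acc = 0;
    for (int t = 0; t < nstate; ++t) {
      if (t == s) continue;
      double p = trans(s, t);
      if (p > 0) { acc += p; cum[s].push_back(acc); dest[s].push_back(t); }
    }
  }

  for (int tr = 0; tr < n_traj; ++tr) {
    MCRNG rng((uint64_t)seed, 100 + (uint64_t)tr);
    int state = state0;
    double z = zs_min + zs_rng * rng.unif();
    double th = th_slope * z;
    double Fc = ls[state].eval(z, th);
    bool done = false, ent = false;
    double ze = NA_REAL, stepcount = 0;
    bool record = tr < n_record;
    std::vector<double> rec;
    long nst = (long)max_steps;
    for (long s = 1; s <= nst; ++s) {
      stepcount = (double)s;
      double u = rng.unif();
      // (i) state change (rigor entry first when admissible)
      bool switched = false;
      double acc = 0.0;
      if (state == closed) {
        // admissible strong-binding valley: |wrap(z - c)| <= admw
        double zm = z - L * std::floor(z / L);
        bool admissible = false;
        for (int a = 0; a < adm.size(); ++a) {
          double d = zm - adm[a];
          d -= L * std::floor(d / L + 0.5);
          if (std::fabs(d) <= admw) { admissible = true; break; }
        }
        if (admissible) {
          acc = kw;
          if (u < acc) {
            trans_count(state, rigor)++;
            state = rigor;
            done = true;
          }
        }
      }
      double ptot = acc + (cum[state].empty() ? 0.0 : cum[state].back());
      if (!done && u < ptot) {
        for (size_t k = 0; k < cum[state].size(); ++k) {
          if (u < acc + cum[state][k]) {
            int to = dest[state][k];
            trans_count(state, to)++;
            state = to;
            if (state == closed && !ent) { ent = true; ze = z; }
            Fc = ls[state].eval(z, th);
            switched = true;
            break;
          }
        }
      }
      if (done) break;
      if (!switched) {
        // (ii)-(iv) lattice diffusion; the residual of u beyond the total
        // switching probability is itself uniform and drives the move choice
        double v = (u - ptot) / (1.0 - ptot);
        bool zmove = v < pz;
        double w = zmove ? v / pz : (v - pz) / (1.0 - pz);
        int dir = w < 0.5 ? -1 : 1;
        double zn = z, thn = th;
        if (zmove) zn += dir * dz; else thn += dir * dth;
        double Fn = ls[state].eval(zn, thn);
        if (!R_finite(Fn)) {
          rejected_missing[0] += 1.0;
        } else {
          double dF = Fn - Fc;
          if (dF <= 0 || rng.unif() < std::exp(-dF)) {
            z = zn; th = thn; Fc = Fn;
          }
        }
      }
      if (record && record_stride > 0 && s % record_stride == 0) {
        rec.push_back((double)s);
        rec.push_back((double)(state + 1));
        rec.push_back(z);
        rec.push_back(th);
      }
    }
    completed[tr] = done;
    entered[tr] = ent;
    steps[tr] = stepcount;
    z_entry[tr] = ze;
    z_final[tr] = z;
    D[tr] = (done && ent) ? (z - ze) : NA_REAL;
    if (record) {
      int nr = rec.size() / 4;
      NumericMatrix rm(nr, 4);
      for (int q = 0; q < nr; ++q)
        for (int c = 0; c < 4; ++c) rm(q, c) = rec[4 * q + c];
      recs[tr] = rm;
    }
  }
  return List::create(_["D"] = D, _["z_entry"] = z_entry,
                      _["z_final"] = z_final, _["steps"] = steps,
                      _["completed"] = completed, _["entered"] = entered,
                      _["transitions"] = trans_count,
                      _["rejected_missing"] = rejected_missing[0],
                      _["trajectories"] = recs);
}

// Landscape interpolation exposed for R-side use (vectorized).
// [[Rcpp::export]]
NumericVector landscape_eval_cpp(List lsc, NumericVector z, NumericVector th) {
  Lscape L;
  L.from_list(lsc);
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = L.eval(z[i], th[i]);
  return out;
}
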