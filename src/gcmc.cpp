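// Grand canonical Monte Carlo of rigid guests in a rigid orthorhombic
// periodic framework. Energies are Lennard-Jones 12-6 in Kelvin
// (epsilon/kB), Lorentz-Berthelot mixing, spherical cutoff with optional
// potential shift, optional damped-shifted-force electrostatics. Uses R's
// RNG throughout, so trajectories are fully determined by set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB_PA_A3 = 1.380649e7;   // Boltzmann, Pa A^3 / K
static const double COULOMB_K = 167100.9;    // e^2/(4 pi eps0 kB), K A

struct FrameCL {  // framework cell list
  double Lx, Ly, Lz;
  int ncx, ncy, ncz;
  std::vector<std::vector<int>> cells;
  const std::vector<double>* x; const std::vector<double>* y;
  const std::vector<double>* z;
  void build(const std::vector<double>& fx, const std::vector<double>& fy,
             const std::vector<double>& fz, double rc) {
    x = &fx; y = &fy; z = &fz;
    ncx = std::max(1, (int)std::floor(Lx / rc));
    ncy = std::max(1, (int)std::floor(Ly / rc));
    ncz = std::max(1, (int)std::floor(Lz / rc));
    cells.assign((size_t)ncx * ncy * ncz, {});
    for (size_t i = 0; i < fx.size(); ++i) {
      int ci = (int)(fx[i] / Lx * ncx) % ncx;
      int cj = (int)(fy[i] / Ly * ncy) % ncy;
      int ck = (int)(fz[i] / Lz * ncz) % ncz;
      if (ci < 0) ci += ncx; if (cj < 0) cj += ncy; if (ck < 0) ck += ncz;
      cells[(size_t)ck * ncx * ncy + (size_t)cj * ncx + ci].push_back((int)i);
    }
  }
};

struct Sim {
  // geometry
  double Lx, Ly, Lz, V;
  // framework
  std::vector<double> fx, fy, fz, fq;
  std::vector<int> ftype;
  FrameCL cl;
  // guest template (body frame)
  std::vector<double> gx, gy, gz, gq;
  std::vector<int> gtype;
  // LJ table
  std::vector<double> eps, sig;
  double rc, rc2;
  bool shifted, use_elec;
  double alpha;
  // state: per guest, site cartesian coords (ns sites each)
  std::vector<double> sx, sy, sz;  // flattened N * ns
  int N = 0;

  inline double mi(double d, double L) const {
    d -= L * std::round(d / L);
    return d;
  }
  inline double pair_e(int ti, int tj, double qi, double qj, double r2) const {
    if (r2 >= rc2) return 0.0;
    double s = 0.5 * (sig[ti] + sig[tj]);
    double e = std::sqrt(eps[ti] * eps[tj]);
    double u = 0.0;
    if (e > 0.0) {
      double sr2 = s * s / r2;
      double sr6 = sr2 * sr2 * sr2;
      u = 4.0 * e * sr6 * (sr6 - 1.0);
      if (shifted) {
        double src2 = s * s / rc2;
        double src6 = src2 * src2 * src2;
        u -= 4.0 * e * src6 * (src6 - 1.0);
      }
    }
    if (use_elec && qi != 0.0 && qj != 0.0) {
      double r = std::sqrt(r2), rcut = std::sqrt(rc2);
      double ec = std::erfc(alpha * r) / r - std::erfc(alpha * rcut) / rcut;
      u += COULOMB_K * qi * qj * ec;
    }
    return u;
  }

  // energy of a trial guest (site coords in trial arrays) with framework
  double frame_energy(const std::vector<double>& tx, const std::vector<double>& ty,
                      const std::vector<double>& tz) const {
    double u = 0.0;
    size_t ns = gtype.size();
    for (size_t a = 0; a < ns; ++a) {
      int ci = (int)(tx[a] / Lx * cl.ncx), cj = (int)(ty[a] / Ly * cl.ncy),
          ck = (int)(tz[a] / Lz * cl.ncz);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            ii = ((ii % cl.ncx) + cl.ncx) % cl.ncx;
            jj = ((jj % cl.ncy) + cl.ncy) % cl.ncy;
            kk = ((kk % cl.ncz) + cl.ncz) % cl.ncz;
            // avoid double visiting when ncell < 3 (wrapped duplicates)
            if (cl.ncx == 1 && di != 0) continue;
            if (cl.ncx == 2 && di == -1) continue;
            if (cl.ncy == 1 && dj != 0) continue;
            if (cl.ncy == 2 && dj == -1) continue;
            if (cl.ncz == 1 && dk != 0) continue;
            if (cl.ncz == 2 && dk == -1) continue;
            const std::vector<int>& bucket =
              cl.cells[(size_t)kk * cl.ncx * cl.ncy + (size_t)jj * cl.ncx + ii];
            for (int idx : bucket) {
              double dx = mi(tx[a] - fx[idx], Lx);
              double dy = mi(ty[a] - fy[idx], Ly);
              double dz = mi(tz[a] - fz[idx], Lz);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < 1e-12) return R_PosInf;
              u += pair_e(gtype[a], ftype[idx], gq[a], fq[idx], r2);
              if (!R_finite(u)) return R_PosInf;
            }
          }
    }
    return u;
  }

  // energy of trial guest with existing guests (skip index `skip`)
  double guest_energy(const std::vector<double>& tx, const std::vector<double>& ty,
                      const std::vector<double>& tz, int skip) const {
    double u = 0.0;
    size_t ns = gtype.size();
    for (int g = 0; g < N; ++g) {
      if (g == skip) continue;
      for (size_t a = 0; a < ns; ++a)
        for (size_t b = 0; b < ns; ++b) {
          double dx = mi(tx[a] - sx[(size_t)g * ns + b], Lx);
          double dy = mi(ty[a] - sy[(size_t)g * ns + b], Ly);
          double dz = mi(tz[a] - sz[(size_t)g * ns + b], Lz);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < 1e-12) return R_PosInf;
          u += pair_e(gtype[a], gtype[b], gq[a], gq[b], r2);
        }
    }
    return u;
  }

  double trial_energy(const std::vector<double>& tx, const std::vector<double>& ty,
                      const std::vector<double>& tz, int skip) const {
    double uf = frame_energy(tx, ty, tz);
    if (!R_finite(uf)) return R_PosInf;
    double ug = guest_energy(tx, ty, tz, skip);
    if (!R_finite(ug)) return R_PosInf;
    return uf + ug;
  }

  double total_energy() const {
    double u = 0.0;
    size_t ns = gtype.size();
    std::vector<double> tx(ns), ty(ns), tz(ns);
    for (int g = 0; g < N; ++g) {
      for (size_t a = 0; a < ns; ++a) {
        tx[a] = sx[(size_t)g * ns + a];
        ty[a] = sy[(size_t)g * ns + a];
        tz[a] = sz[(size_t)g * ns + a];
      }
      double uf = frame_energy(tx, ty, tz);
      if (!R_finite(uf)) return R_PosInf;
      u += uf;
      // guest-guest counted once: pairs with g' > g
      for (int h = g + 1; h < N; ++h)
        for (size_t a = 0; a < ns; ++a)
          for (size_t b = 0; b < ns; ++b) {
            double dx = mi(tx[a] - sx[(size_t)h * ns + b], Lx);
            double dy = mi(ty[a] - sy[(size_t)h * ns + b], Ly);
            double dz = mi(tz[a] - sz[(size_t)h * ns + b], Lz);
            u += pair_e(gtype[a], gtype[b], gq[a], gq[b],
                        dx * dx + dy * dy + dz * dz);
          }
    }
    return u;
  }

  void place(std::vector<double>& tx, std::vector<double>& ty,
             std::vector<double>& tz, double cx, double cy, double cz,
             const double q[4]) const {
    // rotation matrix from unit quaternion (w, x, y, z)
    double w = q[0], x = q[1], y = q[2], z = q[3];
    double R11 = 1 - 2 * (y * y + z * z), R12 = 2 * (x * y - w * z), R13 = 2 * (x * z + w * y);
    double R21 = 2 * (x * y + w * z), R22 = 1 - 2 * (x * x + z * z), R23 = 2 * (y * z - w * x);
    double R31 = 2 * (x * z - w * y), R32 = 2 * (y * z + w * x), R33 = 1 - 2 * (x * x + y * y);
    size_t ns = gtype.size();
    for (size_t a = 0; a < ns; ++a) {
      double bx = gx[a], by = gy[a], bz = gz[a];
      double px = cx + R11 * bx + R12 * by + R13 * bz;
      double py = cy + R21 * bx + R22 * by + R23 * bz;
      double pz = cz + R31 * bx + R32 * by + R33 * bz;
      px -= Lx * std::floor(px / Lx);
      py -= Ly * std::floor(py / Ly);
      pz -= Lz * std::floor(pz / Lz);
      tx[a] = px; ty[a] = py; tz[a] = pz;
    }
  }
};

static void rand_quat(double q[4]) {
  double n2;
  do {
    q[0] = norm_rand(); q[1] = norm_rand(); q[2] = norm_rand(); q[3] = norm_rand();
    n2 = q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  for (int i = 0; i < 4; ++i) q[i] *= inv;
}

static Sim make_sim(List sys) {
  Sim S;
  NumericVector box = sys["box"];
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.V = S.Lx * S.Ly * S.Lz;
  NumericMatrix fxyz = sys["frame_xyz"];
  IntegerVector ft = sys["frame_type"];
  NumericVector fq = sys["frame_charge"];
  for (int i = 0; i < fxyz.nrow(); ++i) {
    double X = fxyz(i, 0), Y = fxyz(i, 1), Z = fxyz(i, 2);
    X -= S.Lx * std::floor(X / S.Lx);
    Y -= S.Ly * std::floor(Y / S.Ly);
    Z -= S.Lz * std::floor(Z / S.Lz);
    S.fx.push_back(X); S.fy.push_back(Y); S.fz.push_back(Z);
    S.ftype.push_back(ft[i]); S.fq.push_back(fq[i]);
  }
  NumericMatrix gxyz = sys["guest_xyz"];
  IntegerVector gt = sys["guest_type"];
  NumericVector gq = sys["guest_charge"];
  for (int i = 0; i < gxyz.nrow(); ++i) {
    S.gx.push_back(gxyz(i, 0)); S.gy.push_back(gxyz(i, 1)); S.gz.push_back(gxyz(i, 2));
    S.gtype.push_back(gt[i]); S.gq.push_back(gq[i]);
  }
  NumericVector eps = sys["eps"], sig = sys["sig"];
  S.eps = std::vector<double>(eps.begin(), eps.end());
  S.sig = std::vector<double>(sig.begin(), sig.end());
  S.rc = as<double>(sys["cutoff"]);
  S.rc2 = S.rc * S.rc;
  S.shifted = as<bool>(sys["shifted"]);
  S.use_elec = as<bool>(sys["use_elec"]);
  S.alpha = as<double>(sys["alpha"]);
  S.cl.Lx = S.Lx; S.cl.Ly = S.Ly; S.cl.Lz = S.Lz;
  S.cl.build(S.fx, S.fy, S.fz, S.rc);
  return S;
}

// accessibility mask lookup (labels grid over the box, 1 = allowed)
static bool allowed_point(const IntegerVector& mask, const IntegerVector& mdims,
                          double x, double y, double z, double Lx, double Ly,
                          double Lz) {
  if (mask.size() == 0) return true;
  int nx = mdims[0], ny = mdims[1], nz = mdims[2];
  int i = (int)(x / Lx * nx) % nx; if (i < 0) i += nx;
  int j = (int)(y / Ly * ny) % ny; if (j < 0) j += ny;
  int k = (int)(z / Lz * nz) % nz; if (k < 0) k += nz;
  return mask[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] != 0;
}

// One GCMC run. sys: geometry/types (see make_sim). conf: T, fugacity,
// move probabilities, cycles, equilibration, max translation, tuning flag.
// Returns trajectory summaries for block averaging done in R.
// [[Rcpp::export]]
List run_gcmc_cpp(List sys, List conf) {
  Sim S = make_sim(sys);
  RNGScope scope;
  const double T = as<double>(conf["T"]);
  const double f = as<double>(conf["fugacity"]);
  const double beta = 1.0 / T;             // energies in K
  const double bfV = f * S.V / (KB_PA_A3 * T);  // beta f V, dimensionless
  NumericVector pm = conf["move_probs"];   // insert, delete, translate, rotate
  const int cycles = as<int>(conf["cycles"]);
  const int equil = as<int>(conf["equilibration"]);
  double dmax = as<double>(conf["max_translation"]);
  const bool tune = as<bool>(conf["tune"]);
  IntegerVector mask = conf["access_mask"];
  IntegerVector mdims = conf["access_dims"];
  const int drift_every = as<int>(conf["drift_check_every"]);  // 0 = off

  size_t ns = S.gtype.size();
  std::vector<double> tx(ns), ty(ns), tz(ns);
  std::vector<double> cxs, cys, czs;          // guest centroids
  std::vector<double> quats;                  // 4 per guest
  double U = 0.0;
  long acc[4] = {0, 0, 0, 0}, att[4] = {0, 0, 0, 0};
  bool ever_inserted = false;
  double max_drift = 0.0;

  std::vector<double> prod_N, prod_U;
  long step_count = 0;
  long tr_acc_win = 0, tr_att_win = 0;

  for (int cyc = 0; cyc < cycles; ++cyc) {
    int nmoves = std::max(20, S.N);
    for (int mv = 0; mv < nmoves; ++mv) {
      ++step_count;
      double u01 = unif_rand();
      int kind = (u01 < pm[0]) ? 0 : (u01 < pm[0] + pm[1]) ? 1
               : (u01 < pm[0] + pm[1] + pm[2]) ? 2 : 3;
      ++att[kind];
      if (kind == 0) {  // insertion
        double cx = unif_rand() * S.Lx, cy = unif_rand() * S.Ly,
               cz = unif_rand() * S.Lz;
        double q[4]; rand_quat(q);
        if (!allowed_point(mask, mdims, cx, cy, cz, S.Lx, S.Ly, S.Lz)) continue;
        S.place(tx, ty, tz, cx, cy, cz, q);
        double dU = S.trial_energy(tx, ty, tz, -1);
        if (R_finite(dU) &&
            unif_rand() < std::min(1.0, bfV / (S.N + 1) * std::exp(-beta * dU))) {
          for (size_t a = 0; a < ns; ++a) {
            S.sx.push_back(tx[a]); S.sy.push_back(ty[a]); S.sz.push_back(tz[a]);
          }
          cxs.push_back(cx); cys.push_back(cy); czs.push_back(cz);
          for (int i = 0; i < 4; ++i) quats.push_back(q[i]);
          ++S.N; U += dU; ++acc[0]; ever_inserted = true;
        }
      } else if (kind == 1) {  // deletion
        if (S.N == 0) continue;
        int g = (int)(unif_rand() * S.N); if (g == S.N) --g;
        for (size_t a = 0; a < ns; ++a) {
          tx[a] = S.sx[(size_t)g * ns + a]; ty[a] = S.sy[(size_t)g * ns + a];
          tz[a] = S.sz[(size_t)g * ns + a];
        }
        double dU = -S.trial_energy(tx, ty, tz, g);
        if (unif_rand() < std::min(1.0, S.N / bfV * std::exp(-beta * dU))) {
          // move last guest into slot g
          int last = S.N - 1;
          for (size_t a = 0; a < ns; ++a) {
            S.sx[(size_t)g * ns + a] = S.sx[(size_t)last * ns + a];
            S.sy[(size_t)g * ns + a] = S.sy[(size_t)last * ns + a];
            S.sz[(size_t)g * ns + a] = S.sz[(size_t)last * ns + a];
          }
          cxs[g] = cxs[last]; cys[g] = cys[last]; czs[g] = czs[last];
          for (int i = 0; i < 4; ++i) quats[4 * g + i] = quats[4 * last + i];
          S.sx.resize((size_t)last * ns); S.sy.resize((size_t)last * ns);
          S.sz.resize((size_t)last * ns);
          cxs.resize(last); cys.resize(last); czs.resize(last);
          quats.resize(4 * last);
          --S.N; U += dU; ++acc[1];
        }
      } else if (kind == 2) {  // translation
        ++tr_att_win;
        if (S.N == 0) continue;
        int g = (int)(unif_rand() * S.N); if (g == S.N) --g;
        for (size_t a = 0; a < ns; ++a) {
          tx[a] = S.sx[(size_t)g * ns + a]; ty[a] = S.sy[(size_t)g * ns + a];
          tz[a] = S.sz[(size_t)g * ns + a];
        }
        double uold = S.trial_energy(tx, ty, tz, g);
        double ddx = (unif_rand() - 0.5) * 2 * dmax;
        double ddy = (unif_rand() - 0.5) * 2 * dmax;
        double ddz = (unif_rand() - 0.5) * 2 * dmax;
        double ncx = cxs[g] + ddx, ncy = cys[g] + ddy, ncz = czs[g] + ddz;
        ncx -= S.Lx * std::floor(ncx / S.Lx);
        ncy -= S.Ly * std::floor(ncy / S.Ly);
        ncz -= S.Lz * std::floor(ncz / S.Lz);
        S.place(tx, ty, tz, ncx, ncy, ncz, &quats[4 * g]);
        double unew = S.trial_energy(tx, ty, tz, g);
        double dU = unew - uold;
        if (R_finite(unew) && unif_rand() < std::min(1.0, std::exp(-beta * dU))) {
          for (size_t a = 0; a < ns; ++a) {
            S.sx[(size_t)g * ns + a] = tx[a]; S.sy[(size_t)g * ns + a] = ty[a];
            S.sz[(size_t)g * ns + a] = tz[a];
          }
          cxs[g] = ncx; cys[g] = ncy; czs[g] = ncz;
          U += dU; ++acc[2]; ++tr_acc_win;
        }
      } else {  // rotation: fresh random orientation
        if (S.N == 0 || ns == 1) continue;
        int g = (int)(unif_rand() * S.N); if (g == S.N) --g;
        for (size_t a = 0; a < ns; ++a) {
          tx[a] = S.sx[(size_t)g * ns + a]; ty[a] = S.sy[(size_t)g * ns + a];
          tz[a] = S.sz[(size_t)g * ns + a];
        }
        double uold = S.trial_energy(tx, ty, tz, g);
        double q[4]; rand_quat(q);
        S.place(tx, ty, tz, cxs[g], cys[g], czs[g], q);
        double unew = S.trial_energy(tx, ty, tz, g);
        double dU = unew - uold;
        if (R_finite(unew) && unif_rand() < std::min(1.0, std::exp(-beta * dU))) {
          for (size_t a = 0; a < ns; ++a) {
            S.sx[(size_t)g * ns + a] = tx[a]; S.sy[(size_t)g * ns + a] = ty[a];
            S.sz[(size_t)g * ns + a] = tz[a];
          }
          for (int i = 0; i < 4; ++i) quats[4 * g + i] = q[i];
          U += dU; ++acc[3];
        }
      }
      if (drift_every > 0 && step_count % drift_every == 0) {
        double Ufull = S.total_energy();
        double denom = std::max(1.0, std::fabs(Ufull));
        double drift = std::fabs(Ufull - U) / denom;
        if (drift > max_drift) max_drift = drift;
        U = Ufull;  // resync so drift measures per-window accumulation
      }
    }
    // equilibration-phase step-size tuning toward ~40% translation acceptance
    if (tune && cyc < equil && tr_att_win >= 100) {
      double r = (double)tr_acc_win / tr_att_win;
      if (r > 0.45) dmax = std::min(dmax * 1.2, S.Lx / 2);
      else if (r < 0.35) dmax = std::max(dmax * 0.8, 0.01);
      tr_acc_win = tr_att_win = 0;
    }
    if (cyc >= equil) {
      prod_N.push_back((double)S.N);
      prod_U.push_back(U);
    }
  }

  return List::create(
    _["N_trace"] = wrap(prod_N), _["U_trace"] = wrap(prod_U),
    _["acc"] = NumericVector::create(acc[0], acc[1], acc[2], acc[3]),
    _["att"] = NumericVector::create(att[0], att[1], att[2], att[3]),
    _["ever_inserted"] = ever_inserted,
    _["final_max_translation"] = dmax,
    _["max_drift"] = max_drift,
    _["bfV"] = bfV);
}

// Widom test-particle insertion: mean Boltzmann factor of random trial
// insertions. Henry coefficient K_H = beta * <exp(-beta dU)> follows in R.
// [[Rcpp::export]]
List widom_cpp(List sys, double T, int n_insert) {
  Sim S = make_sim(sys);
  RNGScope scope;
  const double beta = 1.0 / T;
  size_t ns = S.gtype.size();
  std::vector<double> tx(ns), ty(ns), tz(ns);
  double sum = 0.0, sum2 = 0.0;
  for (int it = 0; it < n_insert; ++it) {
    double cx = unif_rand() * S.Lx, cy = unif_rand() * S.Ly,
           cz = unif_rand() * S.Lz;
    double q[4]; rand_quat(q);
    S.place(tx, ty, tz, cx, cy, cz, q);
    double dU = S.trial_energy(tx, ty, tz, -1);
    double w = R_finite(dU) ? std::exp(-beta * dU) : 0.0;
    sum += w; sum2 += w * w;
  }
  double mean = sum / n_insert;
  double var = std::max(0.0, sum2 / n_insert - mean * mean);
  return List::create(_["mean_boltzmann"] = mean,
                      _["se_boltzmann"] = std::sqrt(var / n_insert));
}

// Lattice-gas GCMC: M independent sites of energy eps_site (K), activity z.
// Exact isotherm <N> = M x/(1+x), x = z exp(-beta eps). Used as an
// analytically solvable oracle for the acceptance rules.
// [[Rcpp::export]]
List lattice_gcmc_cpp(int M, double eps_site, double z, double T,
                      int steps, int equil_steps) {
  RNGScope scope;
  const double x = z * std::exp(-eps_site / T);
  std::vector<char> occ(M, 0);
  int N = 0;
  double sum = 0.0, sum2 = 0.0;
  long nsamp = 0;
  std::vector<double> trace;
  for (int s = 0; s < steps; ++s) {
    int site = (int)(unif_rand() * M); if (site == M) --site;
    if (!occ[site]) {
      if (unif_rand() < std::min(1.0, x)) { occ[site] = 1; ++N; }
    } else {
      if (unif_rand() < std::min(1.0, 1.0 / x)) { occ[site] = 0; --N; }
    }
    if (s >= equil_steps) {
      sum += N; sum2 += (double)N * N; ++nsamp;
      if (s % std::max(1, M) == 0) trace.push_back((double)N);
    }
  }
  double mean = sum / nsamp;
  return List::create(_["mean_N"] = mean,
                      _["var_N"] = sum2 / nsamp - mean * mean,
                      _["trace"] = wrap(trace),
                      _["theta_exact"] = x / (1.0 + x));
}

// Energy difference oracle exposed for tests: total energy of an explicit
// configuration (list of guest site coordinate matrices).
// [[Rcpp::export]]
double total_energy_cpp(List sys, List guest_sites) {
  Sim S = make_sim(sys);
  size_t ns = S.gtype.size();
  S.N = guest_sites.size();
  S.sx.clear(); S.sy.clear(); S.sz.clear();
  for (int g = 0; g < S.N; ++g) {
    NumericMatrix m = guest_sites[g];
    for (size_t a = 0; a < ns; ++a) {
      double X = m(a, 0), Y = m(a, 1), Z = m(a, 2);
      X -= S.Lx * std::floor(X / S.Lx);
      Y -= S.Ly * std::floor(Y / S.Ly);
      Z -= S.Lz * std::floor(Z / S.Lz);
      S.sx.push_back(X); S.sy.push_back(Y); S.sz.push_back(Z);
    }
  }
  return S.total_energy();
}
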