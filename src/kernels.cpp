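// Compiled kernels: pairwise forces, RPY mobility, SAW initial conditions
// and the Ermak-McCammon Brownian-dynamics loop. All quantities are in the
// dimensionless simulation unit system (energies in kT, forces in f_c,
// lengths in x_c, time in t_c); pair forces are -(1/2) dU_kT/dr because
// f_c = 2 kT / x_c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct PairTables {
  // indexed by 4*ti + tj
  double b[16];      // contact distance
  double eps_pair[16];
  int zz[16];
  double rc2[16];    // squared interaction cutoff
  double eps_LJ, Q, L_D, ccf, ecf;
  double b_bond;     // contact distance for bonded pairs (B0)
  double rc2_bond;
  double eps_bond[16];
  int zz_bond[16];
  double L_max, L_max2;
};

PairTables make_tables(const NumericVector& B, const IntegerVector& charge,
                       const LogicalVector& cohesive, double eps,
                       double eps_LJ, double Q, double L_D, double B0,
                       double L_max, double ccf, double ecf) {
  PairTables t;
  t.eps_LJ = eps_LJ; t.Q = Q; t.L_D = L_D; t.ccf = ccf; t.ecf = ecf;
  t.b_bond = B0; t.L_max = L_max; t.L_max2 = L_max * L_max;
  double rc_elec = ecf * L_D;
  double rc2_bond_max = B0 * B0;
  for (int ti = 0; ti < 4; ++ti) {
    for (int tj = 0; tj < 4; ++tj) {
      int k = 4 * ti + tj;
      double b = 0.5 * (B[ti] + B[tj]);
      bool coh = cohesive[ti] && cohesive[tj];
      t.b[k] = b;
      t.eps_pair[k] = coh ? eps : 0.0;
      t.zz[k] = charge[ti] * charge[tj];
      double rc = b;
      if (coh && eps > 0) rc = ccf * b;
      if (t.zz[k] != 0 && rc_elec > rc) rc = rc_elec;
      t.rc2[k] = rc * rc;
      // bonded variants use b = B0 regardless of type
      t.eps_bond[k] = coh ? eps : 0.0;
      t.zz_bond[k] = t.zz[k];
      double rcb = B0;
      if (coh && eps > 0) rcb = ccf * B0;
      if (t.zz[k] != 0 && rc_elec > rcb) rcb = rc_elec;
      if (rcb * rcb > rc2_bond_max) rc2_bond_max = rcb * rcb;
    }
  }
  t.rc2_bond = rc2_bond_max;
  return t;
}

// radial force factor g = F_r / r for a nonbonded pair at squared
// separation r2 (force on i is g * (r_i - r_j))
inline double pair_force_factor(double r2, double b, double eps_pair,
                                int zz, const PairTables& t) {
  double g = 0.0;
  double b2 = b * b;
  if (r2 < b2) {
    double s2 = b2 / r2;
    double s6 = s2 * s2 * s2;
    double s8 = s6 * s2;
    g += 4.0 * t.eps_LJ * (s8 - s6) / r2;
  } else if (eps_pair > 0.0) {
    double rc = t.ccf * b;
    if (r2 < rc * rc) {
      double s2 = b2 / r2;
      double s6 = s2 * s2 * s2;
      double s8 = s6 * s2;
      g += 4.0 * eps_pair * (s8 - s6) / r2;
    }
  }
  if (eps_pair > 0.0 && r2 < b2) {
    // cohesive tail is zero inside contact; nothing to add
  }
  if (zz != 0) {
    double rc = t.ecf * t.L_D;
    if (r2 < rc * rc) {
      double r = std::sqrt(r2);
      double ex = std::exp(-r / t.L_D);
      g += 0.5 * t.Q * zz * ex * (1.0 / (r2 * t.L_D) + 1.0 / (r2 * r));
    }
  }
  return g;
}

void add_bonded_forces(const std::vector<double>& x,
                       const std::vector<double>& y,
                       const std::vector<double>& z,
                       const IntegerVector& codes,
                       const PairTables& t,
                       std::vector<double>& fx, std::vector<double>& fy,
                       std::vector<double>& fz) {
  int n = codes.size();
  for (int i = 0; i < n - 1; ++i) {
    int j = i + 1;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= t.L_max2) stop("bond overstretched during force evaluation");
    int k = 4 * codes[i] + codes[j];
    // FENE attraction: g = -1 / (1 - r^2/L_max^2)
    double g = -1.0 / (1.0 - r2 / t.L_max2);
    g += pair_force_factor(r2, t.b_bond, t.eps_bond[k], t.zz_bond[k], t);
    fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
    fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericMatrix pos, IntegerVector codes,
                               NumericVector typeB, IntegerVector typeCharge,
                               LogicalVector typeCohesive,
                               double eps, double eps_LJ, double Q,
                               double L_D, double B0, double L_max,
                               double ccf, double ecf) {
  int n = pos.nrow();
  if (codes.size() != n) stop("sequence/position length mismatch");
  PairTables t = make_tables(typeB, typeCharge, typeCohesive, eps, eps_LJ,
                             Q, L_D, B0, L_max, ccf, ecf);
  std::vector<double> x(n), y(n), z(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinates");
  }
  add_bonded_forces(x, y, z, codes, t, fx, fy, fz);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= 0.0) stop("coincident bead positions");
      int k = 4 * codes[i] + codes[j];
      if (r2 >= t.rc2[k]) continue;
      double g = pair_force_factor(r2, t.b[k], t.eps_pair[k], t.zz[k], t);
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_mobility_matrix(NumericMatrix pos, NumericVector A, double a0,
                              bool rpy) {
  int n = pos.nrow();
  arma::mat M(3 * n, 3 * n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double self = a0 / A[i];
    for (int d = 0; d < 3; ++d) M(3 * i + d, 3 * i + d) = self;
  }
  if (!rpy) return M;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r <= 0.0) stop("coincident bead positions in mobility matrix");
      double a = 0.5 * (A[i] + A[j]);
      double c1, c2; // block = c1 I + c2 rhat rhat^T
      if (r >= 2.0 * a) {
        double pref = 3.0 * a0 / (4.0 * r);
        c1 = pref * (1.0 + 2.0 * a * a / (3.0 * r2));
        c2 = pref * (1.0 - 2.0 * a * a / r2);
      } else {
        c1 = (a0 / a) * (1.0 - 9.0 * r / (32.0 * a));
        c2 = (a0 / a) * (3.0 * r / (32.0 * a));
      }
      double e[3] = {dx / r, dy / r, dz / r};
      for (int p = 0; p < 3; ++p) {
        for (int q = 0; q < 3; ++q) {
          double v = c2 * e[p] * e[q];
          if (p == q) v += c1;
          M(3 * i + p, 3 * j + q) = v;
          M(3 * j + q, 3 * i + p) = v;
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_init_saw(int n, double bond, double min_sep,
                           int max_restarts) {
  if (n < 2) stop("need at least 2 beads");
  std::vector<double> x(n), y(n), z(n);
  double ms2 = min_sep * min_sep;
  int restarts = 0;
  while (true) {
    bool ok = true;
    x[0] = 0.0; y[0] = 0.0; z[0] = 0.0;
    for (int i = 1; i < n && ok; ++i) {
      bool placed = false;
      for (int attempt = 0; attempt < 60; ++attempt) {
        double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
        double nr = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nr == 0.0) continue;
        double px = x[i - 1] + bond * ux / nr;
        double py = y[i - 1] + bond * uy / nr;
        double pz = z[i - 1] + bond * uz / nr;
        bool clash = false;
        for (int j = 0; j <= i - 2; ++j) {
          double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
          if (dx * dx + dy * dy + dz * dz < ms2) { clash = true; break; }
        }
        if (!clash) {
          x[i] = px; y[i] = py; z[i] = pz;
          placed = true;
          break;
        }
      }
      if (!placed) ok = false;
    }
    if (ok) break;
    if (++restarts > max_restarts) {
      stop("self-avoiding walk generation failed after %d restarts", max_restarts);
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return out;
}

namespace {

// Gaussian draws by polar Box-Muller over R's uniform stream: exact
// normals, deterministic under the R seed, several times faster than the
// default inversion sampler in this hot loop.
struct NormalSource {
  double spare = 0.0;
  bool has_spare = false;
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// Verlet neighbour list over nonbonded pairs with per-pair cutoffs
struct NeighbourList {
  std::vector<int> pi, pj;
  std::vector<double> xref, yref, zref;
  double skin;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const IntegerVector& codes,
             const PairTables& t) {
    int n = codes.size();
    pi.clear(); pj.clear();
    for (int i = 0; i < n; ++i) {
      for (int j = i + 2; j < n; ++j) {
        int k = 4 * codes[i] + codes[j];
        double rl = std::sqrt(t.rc2[k]) + skin;
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < rl * rl) {
          pi.push_back(i); pj.push_back(j);
        }
      }
    }
    xref.assign(x.begin(), x.end());
    yref.assign(y.begin(), y.end());
    zref.assign(z.begin(), z.end());
  }
  bool stale(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z) const {
    double m1 = 0.0, m2 = 0.0; // two largest squared displacements
    for (size_t i = 0; i < xref.size(); ++i) {
      double dx = x[i] - xref[i], dy = y[i] - yref[i], dz = z[i] - zref[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) { m2 = d2; }
    }
    return std::sqrt(m1) + std::sqrt(m2) > skin;
  }
};

void compute_forces_list(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         const IntegerVector& codes, const PairTables& t,
                         const NeighbourList& nl,
                         std::vector<double>& fx, std::vector<double>& fy,
                         std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  add_bonded_forces(x, y, z, codes, t, fx, fy, fz);
  size_t m = nl.pi.size();
  for (size_t p = 0; p < m; ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    int k = 4 * codes[i] + codes[j];
    if (r2 >= t.rc2[k]) continue;
    double g = pair_force_factor(r2, t.b[k], t.eps_pair[k], t.zz[k], t);
    fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
    fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
  }
}

} // namespace

// Brownian-dynamics run. Returns post-equilibration coordinate frames
// (every frame_stride steps), an observable series (every obs_stride
// steps: end-to-end vector and Rg^2), rejection statistics and the final
// configuration.
// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix pos0, IntegerVector codes,
                NumericVector typeB, IntegerVector typeCharge,
                LogicalVector typeCohesive, NumericVector beadA,
                double eps, double eps_LJ, double Q, double L_D,
                double B0, double L_max, double ccf, double ecf,
                double dt, double n_steps_d, double n_equil_d,
                int frame_stride, int obs_stride,
                bool rpy, int chol_stride, int max_reject,
                double verlet_skin) {
  long long n_steps = (long long) n_steps_d;
  long long n_equil = (long long) n_equil_d;
  int n = pos0.nrow();
  if (codes.size() != n) stop("sequence/position length mismatch");
  if (n_equil >= n_steps) stop("n_equil must be smaller than n_steps");
  PairTables t = make_tables(typeB, typeCharge, typeCohesive, eps, eps_LJ,
                             Q, L_D, B0, L_max, ccf, ecf);
  double a0 = B0 / 2.0;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> mob(n), sqmob(n);
  for (int i = 0; i < n; ++i) {
    mob[i] = a0 / beadA[i];
    sqmob[i] = std::sqrt(mob[i] * dt);
  }
  double sqdt = std::sqrt(dt);

  NeighbourList nl;
  nl.skin = verlet_skin;
  nl.build(x, y, z, codes, t);
  long long n_rebuild = 0, n_reject = 0;

  long long n_post = n_steps - n_equil;
  long long nf = (n_post + frame_stride - 1) / frame_stride;
  long long ns = (n_post + obs_stride - 1) / obs_stride;
  NumericVector frames((R_xlen_t)(nf * n * 3));
  NumericMatrix obs((R_xlen_t)ns, 5);
  long long fidx = 0, sidx = 0;

  arma::mat M, H;
  arma::vec F(3 * n), det(3 * n), xi(3 * n), dnoise(3 * n);
  NormalSource rng;
  NumericMatrix posmat(n, 3);

  for (long long step = 1; step <= n_steps; ++step) {
    if (nl.stale(x, y, z)) {
      nl.build(x, y, z, codes, t);
      ++n_rebuild;
    }
    compute_forces_list(x, y, z, codes, t, nl, fx, fy, fz);

    if (rpy) {
      if ((step - 1) % chol_stride == 0) {
        for (int i = 0; i < n; ++i) {
          posmat(i, 0) = x[i]; posmat(i, 1) = y[i]; posmat(i, 2) = z[i];
        }
        M = cpp_mobility_matrix(posmat, NumericVector(beadA), a0, true);
        if (!arma::chol(H, M, "lower")) {
          stop("mobility matrix not positive definite");
        }
      }
      for (int i = 0; i < n; ++i) {
        F[3 * i] = fx[i]; F[3 * i + 1] = fy[i]; F[3 * i + 2] = fz[i];
      }
      det = M * F * dt;
    }

    int tries = 0;
    while (true) {
      bool ok = true;
      if (rpy) {
        for (int i = 0; i < 3 * n; ++i) xi[i] = rng.next();
        dnoise = H * xi * sqdt;
        // trial bond check without committing
        for (int i = 0; i < n - 1 && ok; ++i) {
          double nx1 = x[i] + det[3 * i] + dnoise[3 * i];
          double ny1 = y[i] + det[3 * i + 1] + dnoise[3 * i + 1];
          double nz1 = z[i] + det[3 * i + 2] + dnoise[3 * i + 2];
          double nx2 = x[i + 1] + det[3 * (i + 1)] + dnoise[3 * (i + 1)];
          double ny2 = y[i + 1] + det[3 * (i + 1) + 1] + dnoise[3 * (i + 1) + 1];
          double nz2 = z[i + 1] + det[3 * (i + 1) + 2] + dnoise[3 * (i + 1) + 2];
          double dx = nx1 - nx2, dy = ny1 - ny2, dz = nz1 - nz2;
          if (dx * dx + dy * dy + dz * dz >= t.L_max2) ok = false;
        }
        if (ok) {
          for (int i = 0; i < n; ++i) {
            x[i] += det[3 * i] + dnoise[3 * i];
            y[i] += det[3 * i + 1] + dnoise[3 * i + 1];
            z[i] += det[3 * i + 2] + dnoise[3 * i + 2];
          }
          break;
        }
      } else {
        // free draining: per-bead mobility, diagonal noise
        static thread_local std::vector<double> nx, ny, nz;
        nx.resize(n); ny.resize(n); nz.resize(n);
        for (int i = 0; i < n; ++i) {
          nx[i] = x[i] + mob[i] * fx[i] * dt + sqmob[i] * rng.next();
          ny[i] = y[i] + mob[i] * fy[i] * dt + sqmob[i] * rng.next();
          nz[i] = z[i] + mob[i] * fz[i] * dt + sqmob[i] * rng.next();
        }
        for (int i = 0; i < n - 1; ++i) {
          double dx = nx[i] - nx[i + 1], dy = ny[i] - ny[i + 1],
                 dz = nz[i] - nz[i + 1];
          if (dx * dx + dy * dy + dz * dz >= t.L_max2) { ok = false; break; }
        }
        if (ok) {
          std::swap(x, nx); std::swap(y, ny); std::swap(z, nz);
          break;
        }
      }
      ++n_reject;
      if (++tries > max_reject) {
        stop("step rejected %d times (bond would exceed L_max); reduce dt",
             max_reject);
      }
    }

    if (step > n_equil) {
      long long post = step - n_equil; // 1-based
      if ((post - 1) % obs_stride == 0) {
        double cx = 0, cy = 0, cz = 0;
        for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
        cx /= n; cy /= n; cz /= n;
        double rg2 = 0;
        for (int i = 0; i < n; ++i) {
          double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
          rg2 += dx * dx + dy * dy + dz * dz;
        }
        rg2 /= n;
        obs((R_xlen_t)sidx, 0) = (double)step;
        obs((R_xlen_t)sidx, 1) = x[0] - x[n - 1];
        obs((R_xlen_t)sidx, 2) = y[0] - y[n - 1];
        obs((R_xlen_t)sidx, 3) = z[0] - z[n - 1];
        obs((R_xlen_t)sidx, 4) = rg2;
        ++sidx;
      }
      if ((post - 1) % frame_stride == 0) {
        double* fr = REAL(frames) + fidx * n * 3;
        for (int i = 0; i < n; ++i) {
          fr[i] = x[i];
          fr[n + i] = y[i];
          fr[2 * n + i] = z[i];
        }
        ++fidx;
      }
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  frames.attr("dim") = IntegerVector::create(n, 3, (int)nf);
  NumericMatrix finalpos(n, 3);
  for (int i = 0; i < n; ++i) {
    finalpos(i, 0) = x[i]; finalpos(i, 1) = y[i]; finalpos(i, 2) = z[i];
  }
  return List::create(
    _["frames"] = frames,
    _["obs"] = obs,
    _["final"] = finalpos,
    _["n_reject"] = (double)n_reject,
    _["n_rebuild"] = (double)n_rebuild);
}

// Total potential energy (kT) of a configuration: FENE bonds plus all
// pair terms, mirroring the force kernels (used by the Monte Carlo
// pre-equilibrator and available for diagnostics).
// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, IntegerVector codes,
                        NumericVector typeB, IntegerVector typeCharge,
                        LogicalVector typeCohesive,
                        double eps, double eps_LJ, double Q,
                        double L_D, double B0, double L_max,
                        double ccf, double ecf) {
  int n = pos.nrow();
  if (codes.size() != n) stop("sequence/position length mismatch");
  PairTables t = make_tables(typeB, typeCharge, typeCohesive, eps, eps_LJ,
                             Q, L_D, B0, L_max, ccf, ecf);
  double u = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= 0.0) stop("coincident bead positions");
      bool bonded = (j == i + 1);
      int k = 4 * codes[i] + codes[j];
      double b = bonded ? t.b_bond : t.b[k];
      double ep = bonded ? t.eps_bond[k] : t.eps_pair[k];
      int zz = bonded ? t.zz_bond[k] : t.zz[k];
      if (bonded) {
        if (r2 >= t.L_max2) return R_PosInf;
        u += -t.L_max2 * std::log(1.0 - r2 / t.L_max2);
      }
      double b2 = b * b;
      if (r2 < b2) {
        double s2 = b2 / r2, s6 = s2 * s2 * s2, s8 = s6 * s2;
        u += t.eps_LJ * (s8 - (4.0 / 3.0) * s6) + (t.eps_LJ - ep) / 3.0;
      } else if (ep > 0.0) {
        double rc = t.ccf * b;
        if (r2 < rc * rc) {
          double s2 = b2 / r2, s6 = s2 * s2 * s2, s8 = s6 * s2;
          u += ep * (s8 - (4.0 / 3.0) * s6);
        }
      }
      if (zz != 0) {
        double rc = t.ecf * t.L_D;
        if (r2 < rc * rc) {
          double r = std::sqrt(r2);
          u += t.Q * zz * std::exp(-r / t.L_D) / r;
        }
      }
    }
  }
  return u;
}
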