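// Coarse-grained charged-chain Monte Carlo with temperature replica exchange.
//
// One bead per residue; harmonic bonds; purely repulsive r^-12 excluded
// volume; Debye-Hueckel screened Coulomb between charged beads. Moves:
// single-bead displacement, crankshaft (rotation about the axis through the
// two bonded neighbours), and pivot (rigid rotation of the chain tail).
// Replica exchange between neighbouring temperature rungs at a fixed sweep
// stride. Uses R's RNG stream so set.seed() governs determinism.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double COULOMB_KCAL = 332.0637; // kcal*A/(mol*e^2)
static const double KB_KCAL = 0.0019872041;  // kcal/mol/K

struct Params {
  double bond_length, k_bond, sigma, eps_rep, kappa, dielectric;
  double rep_cut2; // squared cutoff for the repulsive term
};

struct Replica {
  std::vector<double> x, y, z;
  double energy;
};

static inline double pair_nonbonded(const Params& p, double dx, double dy,
                                    double dz, double qq) {
  double r2 = dx * dx + dy * dy + dz * dz;
  double e = 0.0;
  if (r2 < p.rep_cut2) {
    double s2 = (p.sigma * p.sigma) / r2;
    double s6 = s2 * s2 * s2;
    e += p.eps_rep * s6 * s6;
  }
  if (qq != 0.0) {
    double r = std::sqrt(r2);
    e += COULOMB_KCAL * qq * std::exp(-p.kappa * r) / (p.dielectric * r);
  }
  return e;
}

// Total energy of a configuration.
static double total_energy(const Params& p, const std::vector<double>& q,
                           const Replica& r) {
  int n = (int)r.x.size();
  double e = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = r.x[i + 1] - r.x[i], dy = r.y[i + 1] - r.y[i],
           dz = r.z[i + 1] - r.z[i];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - p.bond_length;
    e += p.k_bond * d * d;
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      e += pair_nonbonded(p, r.x[i] - r.x[j], r.y[i] - r.y[j],
                          r.z[i] - r.z[j], q[i] * q[j]);
  return e;
}

// Interaction energy of bead i with everything else (bonds + nonbonded).
static double bead_energy(const Params& p, const std::vector<double>& q,
                          const Replica& r, int i) {
  int n = (int)r.x.size();
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = r.x[i] - r.x[j], dy = r.y[i] - r.y[j], dz = r.z[i] - r.z[j];
    if (j == i - 1 || j == i + 1) {
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - p.bond_length;
      e += p.k_bond * d * d;
    } else {
      e += pair_nonbonded(p, dx, dy, dz, q[i] * q[j]);
    }
  }
  return e;
}

// Nonbonded energy between head [0..pivot] and tail [pivot+1..n-1].
static double cross_energy(const Params& p, const std::vector<double>& q,
                           const Replica& r, int pivot) {
  int n = (int)r.x.size();
  double e = 0.0;
  for (int i = 0; i <= pivot; ++i)
    for (int j = pivot + 1; j < n; ++j) {
      if (j == i + 1) continue; // bonded pair handled by bond term (unchanged)
      e += pair_nonbonded(p, r.x[i] - r.x[j], r.y[i] - r.y[j],
                          r.z[i] - r.z[j], q[i] * q[j]);
    }
  return e;
}

static inline void rotate_about_axis(double& px, double& py, double& pz,
                                     double ox, double oy, double oz,
                                     double ux, double uy, double uz,
                                     double angle) {
  // Rodrigues rotation of point p about unit axis u through origin o.
  double vx = px - ox, vy = py - oy, vz = pz - oz;
  double c = std::cos(angle), s = std::sin(angle);
  double dot = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  px = ox + vx * c + cx * s + ux * dot * (1 - c);
  py = oy + vy * c + cy * s + uy * dot * (1 - c);
  pz = oz + vz * c + cz * s + uz * dot * (1 - c);
}

// [[Rcpp::export(name = ".cg_remd_run")]]
List cg_remd_run(NumericMatrix coords0, NumericVector charges,
                 double bond_length, double k_bond, double sigma,
                 double eps_rep, double kappa, double dielectric,
                 NumericVector temperatures, int record_rung,
                 int n_sweeps, int sweeps_per_frame, int exchange_stride,
                 double max_disp) {
  int n = coords0.nrow();
  if (n < 3) stop("chain must have at least 3 beads");
  int n_rep = temperatures.size();
  if (record_rung < 0 || record_rung >= n_rep) stop("bad record rung");

  Params p;
  p.bond_length = bond_length; p.k_bond = k_bond; p.sigma = sigma;
  p.eps_rep = eps_rep; p.kappa = kappa; p.dielectric = dielectric;
  double rc = 2.5 * sigma;
  p.rep_cut2 = rc * rc;

  std::vector<double> q(charges.begin(), charges.end());
  std::vector<double> beta(n_rep);
  for (int t = 0; t < n_rep; ++t) beta[t] = 1.0 / (KB_KCAL * temperatures[t]);

  std::vector<Replica> reps(n_rep);
  for (int t = 0; t < n_rep; ++t) {
    reps[t].x.assign(n, 0.0); reps[t].y.assign(n, 0.0); reps[t].z.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      reps[t].x[i] = coords0(i, 0);
      reps[t].y[i] = coords0(i, 1);
      reps[t].z[i] = coords0(i, 2);
    }
    reps[t].energy = total_energy(p, q, reps[t]);
  }

  int n_frames = n_sweeps / sweeps_per_frame;
  NumericVector frames(Dimension(n, 3, n_frames));
  IntegerVector exch_attempts(n_rep - 1), exch_accepts(n_rep - 1);
  long moves_attempted = 0, moves_accepted = 0;
  int frame_k = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int t = 0; t < n_rep; ++t) {
      Replica& r = reps[t];
      for (int m = 0; m < n; ++m) {
        double u = unif_rand();
        ++moves_attempted;
        if (u < 0.80) {
          // single-bead displacement
          int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
          double ox = r.x[i], oy = r.y[i], oz = r.z[i];
          double e0 = bead_energy(p, q, r, i);
          r.x[i] += max_disp * (2 * unif_rand() - 1);
          r.y[i] += max_disp * (2 * unif_rand() - 1);
          r.z[i] += max_disp * (2 * unif_rand() - 1);
          double de = bead_energy(p, q, r, i) - e0;
          if (de <= 0 || unif_rand() < std::exp(-beta[t] * de)) {
            r.energy += de; ++moves_accepted;
          } else { r.x[i] = ox; r.y[i] = oy; r.z[i] = oz; }
        } else if (u < 0.95 && n >= 3) {
          // crankshaft: rotate interior bead about the neighbour axis
          int i = 1 + (int)(unif_rand() * (n - 2)); if (i >= n - 1) i = n - 2;
          double ax = r.x[i + 1] - r.x[i - 1], ay = r.y[i + 1] - r.y[i - 1],
                 az = r.z[i + 1] - r.z[i - 1];
          double norm = std::sqrt(ax * ax + ay * ay + az * az);
          if (norm < 1e-8) continue;
          ax /= norm; ay /= norm; az /= norm;
          double angle = M_PI * (2 * unif_rand() - 1);
          double ox = r.x[i], oy = r.y[i], oz = r.z[i];
          double e0 = bead_energy(p, q, r, i);
          rotate_about_axis(r.x[i], r.y[i], r.z[i],
                            r.x[i - 1], r.y[i - 1], r.z[i - 1],
                            ax, ay, az, angle);
          double de = bead_energy(p, q, r, i) - e0;
          if (de <= 0 || unif_rand() < std::exp(-beta[t] * de)) {
            r.energy += de; ++moves_accepted;
          } else { r.x[i] = ox; r.y[i] = oy; r.z[i] = oz; }
        } else {
          // pivot: rotate the tail about a random axis through bead ip
          int ip = 1 + (int)(unif_rand() * (n - 2)); if (ip >= n - 1) ip = n - 2;
          double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
          double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
          if (norm < 1e-8) continue;
          ux /= norm; uy /= norm; uz /= norm;
          double angle = 0.5 * M_PI * (2 * unif_rand() - 1);
          double e0 = cross_energy(p, q, r, ip);
          std::vector<double> sx(r.x.begin() + ip + 1, r.x.end()),
              sy(r.y.begin() + ip + 1, r.y.end()),
              sz(r.z.begin() + ip + 1, r.z.end());
          for (int j = ip + 1; j < n; ++j)
            rotate_about_axis(r.x[j], r.y[j], r.z[j],
                              r.x[ip], r.y[ip], r.z[ip], ux, uy, uz, angle);
          double de = cross_energy(p, q, r, ip) - e0;
          if (de <= 0 || unif_rand() < std::exp(-beta[t] * de)) {
            r.energy += de; ++moves_accepted;
          } else {
            std::copy(sx.begin(), sx.end(), r.x.begin() + ip + 1);
            std::copy(sy.begin(), sy.end(), r.y.begin() + ip + 1);
            std::copy(sz.begin(), sz.end(), r.z.begin() + ip + 1);
          }
        }
      }
    }

    if (n_rep > 1 && sweep % exchange_stride == 0) {
      int parity = (sweep / exchange_stride) % 2;
      for (int t = parity; t + 1 < n_rep; t += 2) {
        ++exch_attempts[t];
        double delta = (beta[t] - beta[t + 1]) *
                       (reps[t].energy - reps[t + 1].energy);
        if (delta >= 0 || unif_rand() < std::exp(delta)) {
          std::swap(reps[t].x, reps[t + 1].x);
          std::swap(reps[t].y, reps[t + 1].y);
          std::swap(reps[t].z, reps[t + 1].z);
          std::swap(reps[t].energy, reps[t + 1].energy);
          ++exch_accepts[t];
        }
      }
    }

    if (sweep % 1000 == 0) {
      // guard against incremental-energy drift
      for (int t = 0; t < n_rep; ++t)
        reps[t].energy = total_energy(p, q, reps[t]);
    }

    if (sweep % sweeps_per_frame == 0 && frame_k < n_frames) {
      const Replica& r = reps[record_rung];
      for (int i = 0; i < n; ++i) {
        frames[frame_k * 3 * n + 0 * n + i] = r.x[i];
        frames[frame_k * 3 * n + 1 * n + i] = r.y[i];
        frames[frame_k * 3 * n + 2 * n + i] = r.z[i];
      }
      ++frame_k;
    }
  }

  NumericVector final_energies(n_rep);
  for (int t = 0; t < n_rep; ++t) final_energies[t] = reps[t].energy;
  return List::create(
      _["frames"] = frames,
      _["exchange_attempts"] = exch_attempts,
      _["exchange_accepts"] = exch_accepts,
      _["move_acceptance"] = (double)moves_accepted / (double)moves_attempted,
      _["final_energies"] = final_energies);
}
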