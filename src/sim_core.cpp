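#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Overdamped Langevin dynamics of lipid headgroup beads in a 2D periodic
// box around fixed protein anchors.
//
//   dx = (D/kT) * F * dt + sqrt(2 D dt) * eta
//
// Forces: WCA excluded volume on all lipid-lipid and lipid-anchor pairs
// (cutoff 2^{1/6} sigma), plus Yukawa screened Coulomb on pairs of charged
// anchor x charged lipid (cutoff 6 lambda). Anchors are immobile. The
// caller seeds R's RNG; norm_rand() makes runs bit-reproducible.

static inline double wrap(double x, double box) {
  x -= box * std::floor(x / box);
  if (x >= box) x = 0.0;  // guard against floating-point edge at x == box
  return x;
}

// [[Rcpp::export]]
List sim_core(NumericMatrix pos0, NumericVector lipid_charge,
              NumericMatrix anchor_pos, NumericVector anchor_charge,
              double box, double dt, int n_equil, int n_steps, int stride,
              double D, double kT, double sigma, double eps_wca,
              double eps_elec, double lambda) {
  const int n = pos0.nrow();
  const int m = anchor_pos.nrow();
  if (n == 0) stop("no lipids to simulate");

  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }
  std::vector<double> ax(m), ay(m);
  for (int j = 0; j < m; ++j) { ax[j] = anchor_pos(j, 0); ay[j] = anchor_pos(j, 1); }

  const double sig2 = sigma * sigma;
  const double rc_wca2 = std::pow(2.0, 1.0 / 3.0) * sig2;  // (2^{1/6} sigma)^2
  const double rc_el = 6.0 * lambda;
  const double rc_el2 = rc_el * rc_el;
  const double mob_dt = D / kT * dt;
  const double noise = std::sqrt(2.0 * D * dt);
  const double max_disp = box / 2.0;

  const int n_frames = (stride > 0) ? n_steps / stride : 0;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * n * 2);

  std::vector<double> fx(n), fy(n);
  const int total_steps = n_equil + n_steps;
  int frame = 0;

  for (int step = 0; step < total_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // lipid-lipid WCA
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j];
        double dy = y[i] - y[j];
        dx -= box * std::nearbyint(dx / box);
        dy -= box * std::nearbyint(dy / box);
        double r2 = dx * dx + dy * dy;
        if (r2 < rc_wca2 && r2 > 1e-12) {
          double s2 = sig2 / r2;
          double s6 = s2 * s2 * s2;
          // F/r = 24 eps (2 s^12 - s^6) / r^2, repulsive along dx,dy
          double fr = 24.0 * eps_wca * (2.0 * s6 * s6 - s6) / r2;
          fx[i] += fr * dx; fy[i] += fr * dy;
          fx[j] -= fr * dx; fy[j] -= fr * dy;
        }
      }
    }

    // lipid-anchor WCA + screened Coulomb
    for (int i = 0; i < n; ++i) {
      const double qi = lipid_charge[i];
      for (int j = 0; j < m; ++j) {
        double dx = x[i] - ax[j];
        double dy = y[i] - ay[j];
        dx -= box * std::nearbyint(dx / box);
        dy -= box * std::nearbyint(dy / box);
        double r2 = dx * dx + dy * dy;
        if (r2 < rc_wca2 && r2 > 1e-12) {
          double s2 = sig2 / r2;
          double s6 = s2 * s2 * s2;
          double fr = 24.0 * eps_wca * (2.0 * s6 * s6 - s6) / r2;
          fx[i] += fr * dx; fy[i] += fr * dy;
        }
        double qq = qi * anchor_charge[j];
        if (qq != 0.0 && eps_elec != 0.0 && r2 < rc_el2 && r2 > 1e-12) {
          double r = std::sqrt(r2);
          // F_vec = eps * q_i q_j * exp(-r/lambda) * (1/(lambda r) + 1/r^2) * rhat
          double fr = eps_elec * qq * std::exp(-r / lambda) *
                      (1.0 / (lambda * r) + 1.0 / r2) / r;
          fx[i] += fr * dx; fy[i] += fr * dy;
        }
      }
    }

    // Euler-Maruyama update; the deterministic drift is capped at half a
    // bead radius per step (force capping) so the stiff WCA core cannot
    // amplify overshoot oscillations at strong electrostatic coupling
    const double drift_cap = 0.25 * sigma;
    for (int i = 0; i < n; ++i) {
      double dbx = mob_dt * fx[i];
      double dby = mob_dt * fy[i];
      double dn = std::sqrt(dbx * dbx + dby * dby);
      if (dn > drift_cap) { dbx *= drift_cap / dn; dby *= drift_cap / dn; }
      double ddx = dbx + noise * norm_rand();
      double ddy = dby + noise * norm_rand();
      if (std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp)
        stop("instability: bead displaced more than box_edge/2 in one step; "
             "use a smaller timestep");
      x[i] = wrap(x[i] + ddx, box);
      y[i] = wrap(y[i] + ddy, box);
    }

    int prod = step - n_equil + 1;  // production steps completed
    if (prod > 0 && stride > 0 && prod % stride == 0 && frame < n_frames) {
      // column-major layout for an R array dim c(n_frames, n, 2)
      for (int i = 0; i < n; ++i) {
        frames[frame + static_cast<R_xlen_t>(n_frames) * i] = x[i];
        frames[frame + static_cast<R_xlen_t>(n_frames) * (i + n)] = y[i];
      }
      ++frame;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(n, 2);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; }
  return List::create(_["frames"] = frames, _["final"] = fin,
                      _["n_frames"] = frame);
}
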