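#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exponent beyond which a Gaussian kernel contribution is dropped
// (exp(-30) ~ 9e-14, far below any tolerance used in the package).
static const double EXP_CUTOFF = 30.0;

// Integrate one CAPP droplet in a trail field that is Gaussian in y and
// uniform in x (the leader's straightened trail).  The cross-section has
// variance var(t) = var0 + 2*aging_D*t and amplitude
// amp(t) = C0 * sqrt(var0 / var(t)) so that the deposited mass is conserved
// while the profile spreads; aging_D = 0 freezes the profile ("static" mode).
//
// State: position (x, y), heading angle th.  Euler-Maruyama with the
// orientational update applied on the angle: dth = -omega*(g . n_perp)*dt.
// Integration stops when |y| > dmax (band exit), when the droplet has been
// slower than 0.05*V0 for longer than stall_time (trapped), or at max_steps.
//
// Returns a list: matrix (t, x, y, theta) sampled every save_every steps
// (the final state is always included) and an exit code
// 0 = exited band, 1 = max_steps reached, 2 = trapped in trail.
// [[Rcpp::export]]
List cpp_sim_gauss_trail(double x0, double y0, double th0,
                         double V0, double alpha, double omega,
                         double Dt, double Dr, double dt,
                         double C0, double var0, double aging_D,
                         double dmax, int max_steps, int save_every,
                         double stall_frac = 0.05, double stall_time = 60.0,
                         int beyond_steps = 0) {
  std::vector<double> ts, xs, ys, ths;
  ts.reserve(max_steps / save_every + 2);
  xs.reserve(max_steps / save_every + 2);
  ys.reserve(max_steps / save_every + 2);
  ths.reserve(max_steps / save_every + 2);

  double x = x0, y = y0, th = th0, t = 0.0;
  double stalled = 0.0;
  int exit_code = 1;
  int stop_step = max_steps;
  bool noisy = (Dt > 0.0) || (Dr > 0.0);
  double sq_t = std::sqrt(2.0 * Dt * dt), sq_r = std::sqrt(2.0 * Dr * dt);

  ts.push_back(t); xs.push_back(x); ys.push_back(y); ths.push_back(th);

  for (int k = 1; k <= max_steps; ++k) {
    double var = var0 + 2.0 * aging_D * t;
    double amp = C0 * std::sqrt(var0 / var);
    double arg = 0.5 * y * y / var;
    double gy = 0.0;
    if (arg < EXP_CUTOFF) {
      double c = amp * std::exp(-arg);
      gy = -c * y / var;            // d c / d y
    }
    double nx = std::cos(th), ny = std::sin(th);
    double vx = V0 * nx, vy = V0 * ny - alpha * gy;
    // n_perp = (-ny, nx); gradient has no x-component here
    double dth = -omega * (gy * nx) * dt;
    x += vx * dt;
    y += vy * dt;
    th += dth;
    if (noisy) {
      x += sq_t * norm_rand();
      y += sq_t * norm_rand();
      th += sq_r * norm_rand();
    }
    t = k * dt;

    double speed = std::sqrt(vx * vx + vy * vy);
    if (speed < stall_frac * V0) stalled += dt; else stalled = 0.0;

    bool save = (k % save_every == 0);
    bool out = std::fabs(y) > dmax;
    bool trapped = stalled > stall_time;
    // optionally keep integrating a short overshoot window past band exit
    bool stop_out = false;
    if (out && exit_code == 1) { exit_code = 0; stop_step = k + beyond_steps; }
    if (exit_code == 0 && k >= stop_step) stop_out = true;
    if (save || stop_out || trapped || k == max_steps) {
      ts.push_back(t); xs.push_back(x); ys.push_back(y); ths.push_back(th);
    }
    if (stop_out) break;
    if (trapped) { exit_code = 2; break; }
  }

  int n = ts.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = ts[i]; out(i, 1) = xs[i]; out(i, 2) = ys[i]; out(i, 3) = ths[i];
  }
  colnames(out) = CharacterVector::create("t", "x", "y", "theta");
  return List::create(_["path"] = out, _["exit_code"] = exit_code);
}

// Minimum-image displacement for a periodic box of side L (L <= 0: open).
static inline double min_image(double d, double L) {
  if (L > 0.0) {
    if (d > 0.5 * L) d -= L;
    else if (d < -0.5 * L) d += L;
  }
  return d;
}

// Concentration and gradient at (px, py[, pz]) from a set of trail segments.
// Each segment j contributes q*ds_j * G_d(|r - r_j|, 4*D*(t - t_j + t_off))
// with G_d the d-dimensional Gaussian diffusion kernel.  Segments older than
// T_mem, farther than R_max, or (when owner filtering is on) belonging to the
// querying droplet and younger than tau_self are skipped.
struct FieldEval {
  double c, gx, gy, gz;
};

static FieldEval eval_field(int dim, double px, double py, double pz,
                            double t, int self_id,
                            const std::vector<double>& sx,
                            const std::vector<double>& sy,
                            const std::vector<double>& sz,
                            const std::vector<double>& st,
                            const std::vector<double>& sds,
                            const std::vector<int>& sowner,
                            double q, double D, double t_off,
                            double T_mem, double R_max, double tau_self,
                            double L) {
  FieldEval f = {0.0, 0.0, 0.0, 0.0};
  double R2 = R_max * R_max;
  size_t n = sx.size();
  for (size_t j = 0; j < n; ++j) {
    double age = t - st[j];
    if (age <= 0.0 || age > T_mem) continue;
    if (self_id >= 0 && sowner[j] == self_id && age < tau_self) continue;
    double dx = min_image(px - sx[j], L);
    double dy = min_image(py - sy[j], L);
    double dz = (dim == 3) ? min_image(pz - sz[j], L) : 0.0;
    double s2 = dx * dx + dy * dy + dz * dz;
    if (s2 > R2) continue;
    double inv = 1.0 / (4.0 * D * (age + t_off));
    double arg = s2 * inv;
    if (arg > EXP_CUTOFF) continue;
    double pref = (dim == 3) ? std::pow(inv / M_PI, 1.5) : inv / M_PI;
    double w = q * sds[j] * pref * std::exp(-arg);
    f.c += w;
    double g = -2.0 * inv * w;
    f.gx += g * dx; f.gy += g * dy;
    if (dim == 3) f.gz += g * dz;
  }
  return f;
}

// Field at arbitrary query points given a segment table (midpoint rule):
// segments as columns x, y[, z], t, ds, owner.  Exposed for testing the
// collective field against the R-level superposition.
// [[Rcpp::export]]
NumericMatrix cpp_field_at(NumericMatrix points, double t,
                           NumericMatrix segments, int dim,
                           double q, double D, double t_off,
                           double T_mem, double R_max, double L) {
  int ns = segments.nrow();
  std::vector<double> sx(ns), sy(ns), sz(ns, 0.0), st(ns), sds(ns);
  std::vector<int> sowner(ns, -1);
  for (int j = 0; j < ns; ++j) {
    sx[j] = segments(j, 0);
    sy[j] = segments(j, 1);
    if (dim == 3) sz[j] = segments(j, 2);
    st[j] = segments(j, dim);
    sds[j] = segments(j, dim + 1);
  }
  int np = points.nrow();
  NumericMatrix out(np, dim + 1);
  for (int i = 0; i < np; ++i) {
    double pz = (dim == 3) ? points(i, 2) : 0.0;
    FieldEval f = eval_field(dim, points(i, 0), points(i, 1), pz, t, -1,
                             sx, sy, sz, st, sds, sowner,
                             q, D, t_off, T_mem, R_max, 0.0, L);
    out(i, 0) = f.c;
    out(i, 1) = f.gx; out(i, 2) = f.gy;
    if (dim == 3) out(i, 3) = f.gz;
  }
  return out;
}

// Collective Brownian dynamics of N trail-depositing CAPP droplets in a
// periodic box of side L.  Synchronous update: fields are evaluated for all
// droplets at the current positions, then all states advance one
// Euler-Maruyama step.  Every dt_dep a droplet appends a trail segment at the
// midpoint of its displacement since the previous deposit, weighted by the
// actual (unwrapped) path length, giving a midpoint-rule quadrature of the
// emission integral.  Droplets ignore their own segments younger than
// tau_self.  Positions are wrapped for field queries and trail storage;
// trajectories are returned unwrapped.
//
// pos0: N x dim start positions (inside the box); n0: N x dim unit
// orientations.  Saves every save_every steps.  Returns the trajectory array
// (t, x, y[, z], nx, ny[, nz]) per droplet and the trail segment table.
// [[Rcpp::export]]
List cpp_collective(NumericMatrix pos0, NumericMatrix n0, int dim,
                    double V0, double alpha, double omega,
                    double Dt, double Dr, double dt, int nsteps,
                    double L, double q, double D, double t_off,
                    double T_mem, double R_max,
                    double dt_dep, double tau_self, int save_every) {
  int N = pos0.nrow();
  std::vector<double> xu(N), yu(N), zu(N, 0.0);       // unwrapped
  std::vector<double> nxv(N), nyv(N), nzv(N, 0.0);
  std::vector<double> lastx(N), lasty(N), lastz(N, 0.0); // last deposit, unwrapped
  for (int i = 0; i < N; ++i) {
    xu[i] = pos0(i, 0); yu[i] = pos0(i, 1);
    nxv[i] = n0(i, 0); nyv[i] = n0(i, 1);
    if (dim == 3) { zu[i] = pos0(i, 2); nzv[i] = n0(i, 2); }
    lastx[i] = xu[i]; lasty[i] = yu[i]; lastz[i] = zu[i];
  }

  std::vector<double> sx, sy, sz, st, sds;
  std::vector<int> sowner;
  int dep_every = std::max(1, (int)std::lround(dt_dep / dt));

  int nsave = nsteps / save_every + 1;
  NumericMatrix traj(N * nsave, 2 * dim + 2);
  int save_row = 0;
  double sq_t = std::sqrt(2.0 * Dt * dt), sq_r = std::sqrt(2.0 * Dr * dt);

  std::vector<double> fgx(N), fgy(N), fgz(N, 0.0);

  auto wrap = [&](double v) {
    if (L > 0.0) { v -= L * std::floor(v / L); }
    return v;
  };
  auto save_state = [&](double t) {
    for (int i = 0; i < N; ++i) {
      traj(save_row, 0) = i + 1;
      traj(save_row, 1) = t;
      traj(save_row, 2) = xu[i]; traj(save_row, 3) = yu[i];
      if (dim == 3) {
        traj(save_row, 4) = zu[i];
        traj(save_row, 5) = nxv[i]; traj(save_row, 6) = nyv[i];
        traj(save_row, 7) = nzv[i];
      } else {
        traj(save_row, 4) = nxv[i]; traj(save_row, 5) = nyv[i];
      }
      ++save_row;
    }
  };
  save_state(0.0);

  for (int k = 1; k <= nsteps; ++k) {
    double t = (k - 1) * dt;   // fields evaluated at pre-step time
    for (int i = 0; i < N; ++i) {
      FieldEval f = eval_field(dim, wrap(xu[i]), wrap(yu[i]), wrap(zu[i]),
                               t, i, sx, sy, sz, st, sds, sowner,
                               q, D, t_off, T_mem, R_max, tau_self, L);
      fgx[i] = f.gx; fgy[i] = f.gy; fgz[i] = f.gz;
    }
    for (int i = 0; i < N; ++i) {
      xu[i] += (V0 * nxv[i] - alpha * fgx[i]) * dt;
      yu[i] += (V0 * nyv[i] - alpha * fgy[i]) * dt;
      if (Dt > 0.0) { xu[i] += sq_t * norm_rand(); yu[i] += sq_t * norm_rand(); }
      if (dim == 2) {
        double th = std::atan2(nyv[i], nxv[i]);
        th += -omega * (fgx[i] * (-nyv[i]) + fgy[i] * nxv[i]) * dt;
        if (Dr > 0.0) th += sq_r * norm_rand();
        nxv[i] = std::cos(th); nyv[i] = std::sin(th);
      } else {
        zu[i] += (V0 * nzv[i] - alpha * fgz[i]) * dt;
        if (Dt > 0.0) zu[i] += sq_t * norm_rand();
        double dotng = nxv[i] * fgx[i] + nyv[i] * fgy[i] + nzv[i] * fgz[i];
        double nx2 = nxv[i] + omega * dt * (dotng * nxv[i] - fgx[i]);
        double ny2 = nyv[i] + omega * dt * (dotng * nyv[i] - fgy[i]);
        double nz2 = nzv[i] + omega * dt * (dotng * nzv[i] - fgz[i]);
        if (Dr > 0.0) {
          // random kick in the tangent plane of n
          double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
          double pr = ax * nxv[i] + ay * nyv[i] + az * nzv[i];
          ax -= pr * nxv[i]; ay -= pr * nyv[i]; az -= pr * nzv[i];
          nx2 += sq_r * ax; ny2 += sq_r * ay; nz2 += sq_r * az;
        }
        double nn = std::sqrt(nx2 * nx2 + ny2 * ny2 + nz2 * nz2);
        nxv[i] = nx2 / nn; nyv[i] = ny2 / nn; nzv[i] = nz2 / nn;
      }
    }
    if (k % dep_every == 0) {
      double tnow = k * dt;
      for (int i = 0; i < N; ++i) {
        double dx = xu[i] - lastx[i], dy = yu[i] - lasty[i];
        double dz = (dim == 3) ? zu[i] - lastz[i] : 0.0;
        double ds = std::sqrt(dx * dx + dy * dy + dz * dz);
        sx.push_back(wrap(0.5 * (xu[i] + lastx[i])));
        sy.push_back(wrap(0.5 * (yu[i] + lasty[i])));
        sz.push_back(dim == 3 ? wrap(0.5 * (zu[i] + lastz[i])) : 0.0);
        st.push_back(tnow - 0.5 * dep_every * dt);
        sds.push_back(ds);
        sowner.push_back(i);
        lastx[i] = xu[i]; lasty[i] = yu[i]; lastz[i] = zu[i];
      }
    }
    if (k % save_every == 0) save_state(k * dt);
    if (k % 200 == 0) Rcpp::checkUserInterrupt();
  }

  int ns = sx.size();
  NumericMatrix segs(ns, dim + 3);
  for (int j = 0; j < ns; ++j) {
    segs(j, 0) = sx[j]; segs(j, 1) = sy[j];
    if (dim == 3) segs(j, 2) = sz[j];
    segs(j, dim) = st[j];
    segs(j, dim + 1) = sds[j];
    segs(j, dim + 2) = sowner[j] + 1;
  }
  return List::create(_["traj"] = traj, _["segments"] = segs);
}
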