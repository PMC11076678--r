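#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thalamocortical neural-mass right-hand side and fixed-step RK4 integrator.
// State layout: x[0]=x_ret1, x[1]=x_ret2, x[2]=x_tcr1, x[3]=x_tcr2,
//               x[4]=x_trn1, x[5]=x_trn2 (potentials in mV, rates in mV/s).
// Time constants arrive already converted to seconds.

struct Pars {
  double he, hi, taue, taui, nu, s0, e0, c1, c2, c3;
  bool trn_self;
};

static inline double sigmoid_rate(double v, const Pars &p) {
  return 2.0 * p.e0 / (1.0 + std::exp(-p.nu * (v - p.s0)));
}

static inline void rhs(const double *x, double drive, const Pars &p,
                       double *dx) {
  const double ie2 = 1.0 / (p.taue * p.taue);
  const double ii2 = 1.0 / (p.taui * p.taui);
  dx[0] = x[1];
  dx[1] = (p.he / p.taue) * drive - (2.0 / p.taue) * x[1] - ie2 * x[0];
  dx[2] = x[3];
  dx[3] = (p.he / p.taue) * sigmoid_rate(p.c3 * x[0] - p.c2 * x[4], p) -
          (2.0 / p.taue) * x[3] - ie2 * x[2];
  const double v_trn = p.c1 * (p.trn_self ? x[4] : x[2]);
  dx[4] = x[5];
  dx[5] = (p.hi / p.taui) * sigmoid_rate(v_trn, p) -
          (2.0 / p.taui) * x[5] - ii2 * x[4];
}

static Pars unpack(const List &params) {
  Pars p;
  p.he = as<double>(params["H_e"]);
  p.hi = as<double>(params["H_i"]);
  p.taue = as<double>(params["tau_e_s"]);
  p.taui = as<double>(params["tau_i_s"]);
  p.nu = as<double>(params["nu"]);
  p.s0 = as<double>(params["s0"]);
  p.e0 = as<double>(params["e0"]);
  p.c1 = as<double>(params["C1"]);
  p.c2 = as<double>(params["C2"]);
  p.c3 = as<double>(params["C3"]);
  p.trn_self = as<bool>(params["trn_self"]);
  return p;
}

// [[Rcpp::export(name = ".rhs_core")]]
NumericVector rhs_core(NumericVector state, double drive, List params) {
  Pars p = unpack(params);
  NumericVector out(6);
  rhs(REAL(state), drive, p, REAL(out));
  return out;
}

// Integrates every column of `drive` (one noise realization per column) with
// classical RK4 at step dt; the drive value of step k is held for all four
// stage evaluations (zero-order hold). Returns the model output
// V = C3*x_ret1 - C2*x_trn1 on the full grid, optionally the state
// trajectories, and divergence bookkeeping instead of throwing so the R side
// can build an informative error.
// [[Rcpp::export(name = ".rk4_core")]]
List rk4_core(NumericVector state0, NumericMatrix drive, double dt,
              List params, bool full_state, double blow_bound) {
  const Pars p = unpack(params);
  const int n_steps = drive.nrow();
  const int n_rep = drive.ncol();

  NumericMatrix V(n_steps + 1, n_rep);
  List states(full_state ? n_rep : 0);

  int diverged_rep = -1;
  double diverged_t = NA_REAL;

  double x[6], xs[6], k1[6], k2[6], k3[6], k4[6];

  for (int r = 0; r < n_rep && diverged_rep < 0; ++r) {
    for (int j = 0; j < 6; ++j) x[j] = state0[j];
    NumericMatrix traj;
    if (full_state) {
      traj = NumericMatrix(n_steps + 1, 6);
      for (int j = 0; j < 6; ++j) traj(0, j) = x[j];
    }
    V(0, r) = p.c3 * x[0] - p.c2 * x[4];

    for (int k = 0; k < n_steps; ++k) {
      const double u = drive(k, r);
      rhs(x, u, p, k1);
      for (int j = 0; j < 6; ++j) xs[j] = x[j] + 0.5 * dt * k1[j];
      rhs(xs, u, p, k2);
      for (int j = 0; j < 6; ++j) xs[j] = x[j] + 0.5 * dt * k2[j];
      rhs(xs, u, p, k3);
      for (int j = 0; j < 6; ++j) xs[j] = x[j] + dt * k3[j];
      rhs(xs, u, p, k4);
      bool bad = false;
      for (int j = 0; j < 6; ++j) {
        x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (!std::isfinite(x[j]) || std::fabs(x[j]) > blow_bound) bad = true;
      }
      if (bad) {
        diverged_rep = r;
        diverged_t = (k + 1) * dt;
        break;
      }
      V(k + 1, r) = p.c3 * x[0] - p.c2 * x[4];
      if (full_state)
        for (int j = 0; j < 6; ++j) traj(k + 1, j) = x[j];
    }
    if (full_state && diverged_rep < 0) states[r] = traj;
  }

  return List::create(_["v"] = V, _["states"] = states,
                      _["diverged_rep"] = diverged_rep + 1,
                      _["diverged_t"] = diverged_t);
}
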