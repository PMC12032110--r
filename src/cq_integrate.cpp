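#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand sides of the cubic-quadratic neuron model.
//
// variant 0 (autonomous):
//   dW/dt = -W^3 + 30 W - Z + E
//   dZ/dt = (5 (W + v)^2 - Z) / tau
// variant 1 (periodically forced, rescaled recovery variable):
//   dW/dt = -W^3 + 30 W - 10 Z + F sin(omega t) + e0
//   dZ/dt = 5 (W + 3)^2 - 10 Z - 70
// e0 = 0 reproduces the drive E(t) = F sin(omega t) + 70 with the resting
// level folded once into the -70 constant; e0 = 70 is the literally printed
// composition.
struct CQField {
  int variant;
  double E, v, tau, F, omega, e0;

  inline void eval(double t, double W, double Z,
                   double &dW, double &dZ) const {
    if (variant == 0) {
      dW = -W * W * W + 30.0 * W - Z + E;
      dZ = (5.0 * (W + v) * (W + v) - Z) / tau;
    } else {
      dW = -W * W * W + 30.0 * W - 10.0 * Z + F * std::sin(omega * t) + e0;
      dZ = 5.0 * (W + 3.0) * (W + 3.0) - 10.0 * Z - 70.0;
    }
  }
};

static CQField make_field(const List &pars) {
  CQField f;
  f.variant = as<int>(pars["variant"]);
  f.E = f.v = f.F = f.omega = f.e0 = 0.0;
  f.tau = 1.0;
  if (f.variant == 0) {
    f.E = as<double>(pars["E"]);
    f.v = as<double>(pars["v"]);
    f.tau = as<double>(pars["tau"]);
  } else {
    f.F = as<double>(pars["F"]);
    f.omega = as<double>(pars["omega"]);
    f.e0 = as<double>(pars["e0"]);
  }
  return f;
}

static inline void rk4_step(const CQField &f, double t, double dt,
                            double &W, double &Z) {
  double k1W, k1Z, k2W, k2Z, k3W, k3Z, k4W, k4Z;
  f.eval(t, W, Z, k1W, k1Z);
  f.eval(t + 0.5 * dt, W + 0.5 * dt * k1W, Z + 0.5 * dt * k1Z, k2W, k2Z);
  f.eval(t + 0.5 * dt, W + 0.5 * dt * k2W, Z + 0.5 * dt * k2Z, k3W, k3Z);
  f.eval(t + dt, W + dt * k3W, Z + dt * k3Z, k4W, k4Z);
  W += dt / 6.0 * (k1W + 2.0 * k2W + 2.0 * k3W + k4W);
  Z += dt / 6.0 * (k1Z + 2.0 * k2Z + 2.0 * k3Z + k4Z);
}

static inline bool bad(double W, double Z, double blowup) {
  return !std::isfinite(W) || !std::isfinite(Z) ||
         std::fabs(W) > blowup || std::fabs(Z) > 1e4 * blowup;
}

// Fixed-step RK4 integration with stride-based recording.
// [[Rcpp::export]]
List cq_rk4_cpp(List pars, NumericVector init, double t0, double t_end,
                double dt, int record_every, double blowup) {
  CQField f = make_field(pars);
  double W = init[0], Z = init[1];
  long n_steps = (long) std::llround((t_end - t0) / dt);
  if (n_steps < 0) stop("t_end must be >= t0");
  long n_rec = n_steps / record_every + 2;
  std::vector<double> tv, Wv, Zv;
  tv.reserve(n_rec); Wv.reserve(n_rec); Zv.reserve(n_rec);
  tv.push_back(t0); Wv.push_back(W); Zv.push_back(Z);
  bool diverged = false;
  double t = t0;
  for (long i = 0; i < n_steps; ++i) {
    double Wn = W, Zn = Z;
    rk4_step(f, t, dt, Wn, Zn);
    if (bad(Wn, Zn, blowup)) { diverged = true; break; }
    W = Wn; Z = Zn;
    t = t0 + (i + 1) * dt;
    if ((i + 1) % record_every == 0 || i + 1 == n_steps) {
      tv.push_back(t); Wv.push_back(W); Zv.push_back(Z);
    }
  }
  return List::create(_["t"] = wrap(tv), _["W"] = wrap(Wv),
                      _["Z"] = wrap(Zv), _["diverged"] = diverged,
                      _["last_t"] = t, _["last_W"] = W, _["last_Z"] = Z);
}

// Benettin two-trajectory largest-Lyapunov-exponent estimate.  The
// perturbation lives in the (W, Z) plane only; for the forced variant both
// copies share the same drive phase, so growth along time is excluded.
// [[Rcpp::export]]
List cq_lyapunov_cpp(List pars, NumericVector init, double transient,
                     double horizon, double dt, double renorm_interval,
                     double d0, double blowup) {
  CQField f = make_field(pars);
  double W = init[0], Z = init[1];
  long n_tr = (long) std::llround(transient / dt);
  double t = 0.0;
  for (long i = 0; i < n_tr; ++i) {
    rk4_step(f, t, dt, W, Z);
    t = (i + 1) * dt;
    if (bad(W, Z, blowup))
      return List::create(_["value"] = NA_REAL,
                          _["series"] = NumericVector(0),
                          _["diverged"] = true);
  }
  double s = 1.0 / std::sqrt(2.0);
  double W2 = W + d0 * s, Z2 = Z + d0 * s;
  long n_renorm = (long) std::llround(horizon / renorm_interval);
  long n_sub = (long) std::llround(renorm_interval / dt);
  NumericVector series(n_renorm);
  double acc = 0.0;
  for (long r = 0; r < n_renorm; ++r) {
    for (long i = 0; i < n_sub; ++i) {
      rk4_step(f, t, dt, W, Z);
      rk4_step(f, t, dt, W2, Z2);
      t += dt;
      if (bad(W, Z, blowup) || bad(W2, Z2, blowup))
        return List::create(_["value"] = NA_REAL,
                            _["series"] = NumericVector(0),
                            _["diverged"] = true);
    }
    double dW = W2 - W, dZ = Z2 - Z;
    double d = std::sqrt(dW * dW + dZ * dZ);
    if (d <= 0) d = 1e-300;
    acc += std::log(d / d0);
    series[r] = acc / ((r + 1) * renorm_interval);
    double shrink = d0 / d;
    W2 = W + dW * shrink;
    Z2 = Z + dZ * shrink;
  }
  return List::create(_["value"] = series[n_renorm - 1],
                      _["series"] = series, _["diverged"] = false);
}

// Stroboscopic samples of the forced system: W at t_k = k 2*pi/omega after a
// whole number of transient periods.  The step is adjusted so that an integer
// number of RK4 steps fits one forcing period exactly.
// [[Rcpp::export]]
List cq_strobe_cpp(List pars, NumericVector init, double transient,
                   int n_samples, double dt, double blowup) {
  CQField f = make_field(pars);
  if (f.variant != 1) stop("stroboscopic sampling needs the forced variant");
  double period = 2.0 * M_PI / f.omega;
  long m = (long) std::ceil(period / dt);
  if (m < 2) m = 2;
  double h = period / m;
  long n_tr_per = (long) std::ceil(transient / period);
  double W = init[0], Z = init[1];
  double t = 0.0;
  for (long p = 0; p < n_tr_per; ++p) {
    for (long i = 0; i < m; ++i) {
      rk4_step(f, t, h, W, Z);
      t = (p * m + i + 1) * h;
      if (bad(W, Z, blowup))
        return List::create(_["samples"] = NumericVector(0),
                            _["diverged"] = true,
                            _["last_W"] = W, _["last_Z"] = Z);
    }
  }
  NumericVector samples(n_samples);
  for (int k = 0; k < n_samples; ++k) {
    samples[k] = W;
    for (long i = 0; i < m; ++i) {
      rk4_step(f, t, h, W, Z);
      t += h;
      if (bad(W, Z, blowup)) {
        return List::create(_["samples"] = samples[Range(0, k)],
                            _["diverged"] = true,
                            _["last_W"] = W, _["last_Z"] = Z);
      }
    }
  }
  return List::create(_["samples"] = samples, _["diverged"] = false,
                      _["last_W"] = W, _["last_Z"] = Z);
}
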