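// Core integrators: classic RK4 Hodgkin-Huxley, the hybrid scheme coupling
// one Caputo (L1-discretized) gating variable to RK4 voltage dynamics, and
// the isolated-gate voltage-clamp integrator. All loops are O(N) per step in
// the full-memory case, so a run of N steps costs O(N^2) multiply-adds.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>

using namespace Rcpp;

// Rate functions. v is the voltage relative to the reference V0 (classic
// squid-axon convention, V0 = -65 mV). The 0/0 points of alpha_n (v = 10)
// and alpha_m (v = 25) are removable; within EPS_SING of them the analytic
// limit is returned.
static const double EPS_SING = 1e-6;

static inline double alpha_n_rel(double v) {
  double u = 10.0 - v;
  if (std::fabs(u) < EPS_SING * 10.0) return 0.1; // limit of 0.01*u/(exp(u/10)-1)
  return 0.01 * u / (std::exp(u / 10.0) - 1.0);
}
static inline double beta_n_rel(double v)  { return 0.125 * std::exp(-v / 80.0); }
static inline double alpha_m_rel(double v) {
  double u = 25.0 - v;
  if (std::fabs(u) < EPS_SING * 10.0) return 1.0;
  return 0.1 * u / (std::exp(u / 10.0) - 1.0);
}
static inline double beta_m_rel(double v)  { return 4.0 * std::exp(-v / 18.0); }
static inline double alpha_h_rel(double v) { return 0.07 * std::exp(-v / 20.0); }
static inline double beta_h_rel(double v)  { return 1.0 / (1.0 + std::exp(3.0 - 0.1 * v)); }

// gate: 0 = n, 1 = m, 2 = h; kind: 0 = alpha, 1 = beta
static inline double rate_of(int gate, int kind, double V, double V0) {
  double v = V - V0;
  switch (gate * 2 + kind) {
  case 0: return alpha_n_rel(v);
  case 1: return beta_n_rel(v);
  case 2: return alpha_m_rel(v);
  case 3: return beta_m_rel(v);
  case 4: return alpha_h_rel(v);
  default: return beta_h_rel(v);
  }
}

// [[Rcpp::export(name = ".rateCpp")]]
NumericVector rate_cpp(IntegerVector gate, IntegerVector kind, NumericVector V, double V0) {
  R_xlen_t n = V.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(V[i])) stop("rate(): V must be finite");
    out[i] = rate_of(gate[i % gate.size()], kind[i % kind.size()], V[i], V0);
  }
  return out;
}

struct HHP {
  double C, gNa, gK, gm, ENa, EK, EL, V0;
  explicit HHP(const NumericVector& p)
    : C(p["C"]), gNa(p["gNa_bar"]), gK(p["gK_bar"]), gm(p["gm"]),
      ENa(p["ENa"]), EK(p["EK"]), EL(p["EL"]), V0(p["V0"]) {}
};

static inline double dV_dt(const HHP& p, double V, double n, double m, double h, double I) {
  double INa = p.gNa * m * m * m * h * (p.ENa - V);
  double IK  = p.gK * n * n * n * n * (p.EK - V);
  double IL  = p.gm * (p.EL - V);
  return (INa + IK + IL + I) / p.C;
}
static inline double gate_dt(int gate, double V, double x, double V0) {
  double a = rate_of(gate, 0, V, V0), b = rate_of(gate, 1, V, V0);
  return a * (1.0 - x) - b * x;
}

static inline double step_current(double t, double amp, double onset, double dur) {
  return (t >= onset && t < onset + dur) ? amp : 0.0;
}

// sum_{j=1}^{jlim} dx[kmax-j] * c[j], with four independent accumulator
// chains so the FP reduction pipelines (gcc will not reassociate at -O2).
static inline double l1_convolve(const double* dx, const double* c,
                                 R_xlen_t kmax, R_xlen_t jlim) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  R_xlen_t j = 1;
  for (; j + 3 <= jlim; j += 4) {
    s0 += dx[kmax - j] * c[j];
    s1 += dx[kmax - j - 1] * c[j + 1];
    s2 += dx[kmax - j - 2] * c[j + 2];
    s3 += dx[kmax - j - 3] * c[j + 3];
  }
  for (; j <= jlim; ++j) s0 += dx[kmax - j] * c[j];
  return (s0 + s1) + (s2 + s3);
}

static void check_finite(double V, int stepno, double dt) {
  if (!R_finite(V)) {
    std::ostringstream msg;
    msg << "numerical divergence: non-finite voltage at step " << stepno
        << " (t = " << stepno * dt << " ms)";
    stop(msg.str());
  }
}

// Classic model: RK4 on (V, n, m, h).
// [[Rcpp::export(name = ".simulateClassicCpp")]]
NumericMatrix simulate_classic_cpp(NumericVector params,
                                   double amplitude, double onset, double duration,
                                   double total_time, double dt,
                                   double V_init, NumericVector gates_init) {
  HHP p(params);
  R_xlen_t nstep = (R_xlen_t) std::llround(total_time / dt);
  NumericMatrix out(nstep + 1, 5);
  double V = V_init, n = gates_init[0], m = gates_init[1], h = gates_init[2];
  out(0, 0) = 0.0; out(0, 1) = V; out(0, 2) = n; out(0, 3) = m; out(0, 4) = h;
  for (R_xlen_t i = 0; i < nstep; ++i) {
    double t = i * dt;
    double I1 = step_current(t, amplitude, onset, duration);
    double I2 = step_current(t + 0.5 * dt, amplitude, onset, duration);
    double I4 = step_current(t + dt, amplitude, onset, duration);

    double k1V = dV_dt(p, V, n, m, h, I1);
    double k1n = gate_dt(0, V, n, p.V0), k1m = gate_dt(1, V, m, p.V0), k1h = gate_dt(2, V, h, p.V0);

    double V2 = V + 0.5 * dt * k1V, n2 = n + 0.5 * dt * k1n, m2 = m + 0.5 * dt * k1m, h2 = h + 0.5 * dt * k1h;
    double k2V = dV_dt(p, V2, n2, m2, h2, I2);
    double k2n = gate_dt(0, V2, n2, p.V0), k2m = gate_dt(1, V2, m2, p.V0), k2h = gate_dt(2, V2, h2, p.V0);

    double V3 = V + 0.5 * dt * k2V, n3 = n + 0.5 * dt * k2n, m3 = m + 0.5 * dt * k2m, h3 = h + 0.5 * dt * k2h;
    double k3V = dV_dt(p, V3, n3, m3, h3, I2);
    double k3n = gate_dt(0, V3, n3, p.V0), k3m = gate_dt(1, V3, m3, p.V0), k3h = gate_dt(2, V3, h3, p.V0);

    double V4 = V + dt * k3V, n4 = n + dt * k3n, m4 = m + dt * k3m, h4 = h + dt * k3h;
    double k4V = dV_dt(p, V4, n4, m4, h4, I4);
    double k4n = gate_dt(0, V4, n4, p.V0), k4m = gate_dt(1, V4, m4, p.V0), k4h = gate_dt(2, V4, h4, p.V0);

    V += dt / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
    n += dt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n);
    m += dt / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
    h += dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
    check_finite(V, (int)(i + 1), dt);
    out(i + 1, 0) = (i + 1) * dt; out(i + 1, 1) = V;
    out(i + 1, 2) = n; out(i + 1, 3) = m; out(i + 1, 4) = h;
  }
  colnames(out) = CharacterVector::create("t_ms", "V_mV", "n", "m", "h");
  return out;
}

// Hybrid scheme. Per step: (1) the fractional gate is advanced with the L1
// update using the voltage and rates of the previous sample; (2) V and the
// two classic gates take one RK4 step with the fractional gate held at its
// freshly updated value. For eta = 1 all L1 weights vanish and the update is
// a forward-Euler step, so the memory loop is skipped entirely.
// fgate: 0 = n, 1 = m, 2 = h. window = 0 means full memory.
// [[Rcpp::export(name = ".simulateHybridCpp")]]
NumericMatrix simulate_hybrid_cpp(NumericVector params,
                                  int fgate, double eta,
                                  double amplitude, double onset, double duration,
                                  double total_time, double dt,
                                  double V_init, NumericVector gates_init,
                                  int window, double divergence_bound) {
  HHP p(params);
  R_xlen_t nstep = (R_xlen_t) std::llround(total_time / dt);
  NumericMatrix out(nstep + 1, 6);
  double V = V_init;
  double g[3] = { gates_init[0], gates_init[1], gates_init[2] };
  int c1 = (fgate == 0) ? 1 : 0;              // first classic gate index
  int c2 = (fgate == 2) ? 1 : 2;              // second classic gate index

  // L1 convolution weights c_j = (j+1)^(1-eta) - j^(1-eta), j = 1..nstep-1.
  // The weight applied to increment dx_k at step N is c_(N-1-k).
  std::vector<double> cj;
  bool frac = eta < 1.0;
  if (frac) {
    cj.resize((size_t) nstep, 0.0);
    double e = 1.0 - eta;
    for (R_xlen_t j = 1; j < nstep; ++j)
      cj[(size_t) j] = std::pow((double) j + 1.0, e) - std::pow((double) j, e);
  }
  std::vector<double> dx; // increments of the fractional gate
  dx.reserve((size_t) nstep);
  double dtg = std::pow(dt, eta) * std::tgamma(2.0 - eta);

  out(0, 0) = 0.0; out(0, 1) = V; out(0, 2) = g[0]; out(0, 3) = g[1]; out(0, 4) = g[2];
  out(0, 5) = 0.0;

  for (R_xlen_t i = 0; i < nstep; ++i) {
    double t = i * dt;
    // (1) L1 update of the fractional gate from state at t_i
    double x_prev = g[fgate];
    double kin = gate_dt(fgate, V, x_prev, p.V0);
    double mem = 0.0;
    if (frac && i >= 1) {
      R_xlen_t kmax = (R_xlen_t) dx.size();         // = i
      R_xlen_t jlim = (window > 0 && window < kmax) ? window : kmax;
      mem = -l1_convolve(dx.data(), cj.data(), kmax, jlim);
    }
    double x_new = dtg * kin + x_prev + mem;
    if (!R_finite(x_new) || std::fabs(x_new) > divergence_bound) {
      std::ostringstream msg;
      msg << "fractional gate divergence (gate=" << "nmh"[fgate]
          << ", eta=" << eta << ", dt=" << dt << ") at step " << (i + 1)
          << " (t = " << (i + 1) * dt << " ms): |x| exceeded bound "
          << divergence_bound;
      stop(msg.str());
    }
    dx.push_back(x_new - x_prev);

    // (2) RK4 on V and the two classic gates, fractional gate held at x_new
    double I1 = step_current(t, amplitude, onset, duration);
    double I2 = step_current(t + 0.5 * dt, amplitude, onset, duration);
    double I4 = step_current(t + dt, amplitude, onset, duration);
    double a1 = g[c1], a2 = g[c2];
    double gg[3];
    gg[fgate] = x_new;

    gg[c1] = a1; gg[c2] = a2;
    double k1V = dV_dt(p, V, gg[0], gg[1], gg[2], I1);
    double k1a = gate_dt(c1, V, a1, p.V0), k1b = gate_dt(c2, V, a2, p.V0);

    double Vm = V + 0.5 * dt * k1V, a1m = a1 + 0.5 * dt * k1a, a2m = a2 + 0.5 * dt * k1b;
    gg[c1] = a1m; gg[c2] = a2m;
    double k2V = dV_dt(p, Vm, gg[0], gg[1], gg[2], I2);
    double k2a = gate_dt(c1, Vm, a1m, p.V0), k2b = gate_dt(c2, Vm, a2m, p.V0);

    double Vn = V + 0.5 * dt * k2V, a1n = a1 + 0.5 * dt * k2a, a2n = a2 + 0.5 * dt * k2b;
    gg[c1] = a1n; gg[c2] = a2n;
    double k3V = dV_dt(p, Vn, gg[0], gg[1], gg[2], I2);
    double k3a = gate_dt(c1, Vn, a1n, p.V0), k3b = gate_dt(c2, Vn, a2n, p.V0);

    double Vq = V + dt * k3V, a1q = a1 + dt * k3a, a2q = a2 + dt * k3b;
    gg[c1] = a1q; gg[c2] = a2q;
    double k4V = dV_dt(p, Vq, gg[0], gg[1], gg[2], I4);
    double k4a = gate_dt(c1, Vq, a1q, p.V0), k4b = gate_dt(c2, Vq, a2q, p.V0);

    V += dt / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
    g[c1] = a1 + dt / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
    g[c2] = a2 + dt / 6.0 * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
    g[fgate] = x_new;
    check_finite(V, (int)(i + 1), dt);

    out(i + 1, 0) = (i + 1) * dt; out(i + 1, 1) = V;
    out(i + 1, 2) = g[0]; out(i + 1, 3) = g[1]; out(i + 1, 4) = g[2];
    out(i + 1, 5) = mem;
  }
  colnames(out) = CharacterVector::create("t_ms", "V_mV", "n", "m", "h", "memtrace");
  return out;
}

// Isolated gate under the L1 scheme at a fixed clamped voltage. Returns the
// gate values x(t_1)..x(t_nstep) (x(t_0) = x0 is not included). Throws on
// divergence, reporting the failing step; the caller may truncate there.
// [[Rcpp::export(name = ".gateClampL1Cpp")]]
NumericVector gate_clamp_l1_cpp(int gate, double eta, double x0, double V,
                                double V0, R_xlen_t nstep, double dt,
                                double divergence_bound) {
  double a = rate_of(gate, 0, V, V0), b = rate_of(gate, 1, V, V0);
  NumericVector out(nstep);
  bool frac = eta < 1.0;
  std::vector<double> cj;
  if (frac) {
    cj.resize((size_t) nstep, 0.0);
    double e = 1.0 - eta;
    for (R_xlen_t j = 1; j < nstep; ++j)
      cj[(size_t) j] = std::pow((double) j + 1.0, e) - std::pow((double) j, e);
  }
  std::vector<double> dx;
  dx.reserve((size_t) nstep);
  double dtg = std::pow(dt, eta) * std::tgamma(2.0 - eta);
  double x = x0;
  for (R_xlen_t i = 0; i < nstep; ++i) {
    double mem = 0.0;
    if (frac && i >= 1) {
      R_xlen_t kmax = (R_xlen_t) dx.size();
      mem = -l1_convolve(dx.data(), cj.data(), kmax, kmax);
    }
    double x_new = dtg * (a * (1.0 - x) - b * x) + x + mem;
    if (!R_finite(x_new) || std::fabs(x_new) > divergence_bound) {
      std::ostringstream msg;
      msg << "fractional gate divergence (gate=" << "nmh"[gate]
          << ", eta=" << eta << ", dt=" << dt << ") at step " << (i + 1)
          << " (t = " << (i + 1) * dt << " ms): |x| exceeded bound "
          << divergence_bound;
      stop(msg.str());
    }
    dx.push_back(x_new - x);
    x = x_new;
    out[i] = x;
  }
  return out;
}
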