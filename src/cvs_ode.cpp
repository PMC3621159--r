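// Six-chamber lumped-parameter circulation: right-hand side, septum root
// solve, and adaptive Dormand-Prince integration with dense sampling.
// All quantities in mmHg, mL, s.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Driver {
  int type;           // 0 = parametric Gaussian pulse, 1 = sampled curve
  double period;
  double t_peak;      // s (parametric)
  double width;       // s^-2 (parametric)
  std::vector<double> y;  // sampled values on uniform grid over [0, period)

  double value(double t) const {
    double tm = t - period * std::floor(t / period);
    if (type == 0) {
      double dt = tm - t_peak;
      // nearest periodic image keeps the pulse exactly periodic
      if (dt > 0.5 * period) dt -= period;
      if (dt < -0.5 * period) dt += period;
      return std::exp(-width * dt * dt);
    }
    const int n = (int)y.size();
    double u = tm / period * n;
    int i = (int)std::floor(u);
    double f = u - i;
    int j = (i + 1) % n;
    if (i >= n) i = n - 1;
    return (1.0 - f) * y[i] + f * y[j];
  }
};

struct Wall {  // one actively elastic wall: linear ESPVR + exponential EDPVR
  double E_es, V_d, P_0, lambda, V_0;
  double p(double V, double dri) const {
    return dri * E_es * (V - V_d) +
           (1.0 - dri) * P_0 * std::expm1(lambda * (V - V_0));
  }
  double dp(double V, double dri) const {
    return dri * E_es +
           (1.0 - dri) * P_0 * lambda * std::exp(lambda * (V - V_0));
  }
};

struct Params {
  Wall lvf, rvf, spt;
  double P_0_pcd, V_0_pcd, lambda_pcd, P_th;
  double E_ao, V_d_ao, E_vc, V_d_vc, E_pa, V_d_pa, E_pu, V_d_pu;
  double R_mt, R_av, R_sys, R_tc, R_pv, R_pul;
  double P_pu_src, P_vc_src;  // fixed source pressures for submodel modes
  Driver driL, driR;
};

Driver driver_from_list(List d) {
  Driver dr;
  std::string type = as<std::string>(d["type"]);
  dr.type = (type == "sampled") ? 1 : 0;
  dr.period = as<double>(d["period"]);
  if (dr.period <= 0) stop("driver period must be positive");
  if (dr.type == 0) {
    dr.t_peak = as<double>(d["t_peak"]);
    dr.width = as<double>(d["width"]);
  } else {
    dr.y = as<std::vector<double>>(d["values"]);
    if (dr.y.empty()) stop("sampled driver needs values");
  }
  return dr;
}

double num(List p, const char* k) { return as<double>(p[k]); }

Params params_from_list(List p) {
  Params q;
  q.lvf = {num(p, "E_es_lvf"), num(p, "V_d_lvf"), num(p, "P_0_lvf"),
           num(p, "lambda_lvf"), num(p, "V_0_lvf")};
  q.rvf = {num(p, "E_es_rvf"), num(p, "V_d_rvf"), num(p, "P_0_rvf"),
           num(p, "lambda_rvf"), num(p, "V_0_rvf")};
  q.spt = {num(p, "E_es_spt"), num(p, "V_d_spt"), num(p, "P_0_spt"),
           num(p, "lambda_spt"), num(p, "V_0_spt")};
  q.P_0_pcd = num(p, "P_0_pcd");
  q.V_0_pcd = num(p, "V_0_pcd");
  q.lambda_pcd = num(p, "lambda_pcd");
  q.P_th = num(p, "P_th");
  q.E_ao = num(p, "E_ao"); q.V_d_ao = num(p, "V_d_ao");
  q.E_vc = num(p, "E_vc"); q.V_d_vc = num(p, "V_d_vc");
  q.E_pa = num(p, "E_pa"); q.V_d_pa = num(p, "V_d_pa");
  q.E_pu = num(p, "E_pu"); q.V_d_pu = num(p, "V_d_pu");
  q.R_mt = num(p, "R_mt"); q.R_av = num(p, "R_av");
  q.R_sys = num(p, "R_sys"); q.R_tc = num(p, "R_tc");
  q.R_pv = num(p, "R_pv"); q.R_pul = num(p, "R_pul");
  q.P_pu_src = num(p, "P_pu"); q.P_vc_src = num(p, "P_vc");
  q.driL = driver_from_list(p["driL"]);
  q.driR = driver_from_list(p["driR"]);
  if (q.R_mt <= 0 || q.R_av <= 0 || q.R_sys <= 0 || q.R_tc <= 0 ||
      q.R_pv <= 0 || q.R_pul <= 0)
    stop("all resistances must be positive");
  return q;
}

// Root of P_spt(x) = P_lvf(V_lv - x) - P_rvf(V_rv + x); the residual is
// strictly increasing in x, so the root is unique.  Newton from a warm
// start, safeguarded by bisection on an expanding bracket.
double solve_septum(const Params& q, double V_lv, double V_rv, double dL,
                    double dR, double x0) {
  auto g = [&](double x) {
    return q.spt.p(x, dL) - q.lvf.p(V_lv - x, dL) + q.rvf.p(V_rv + x, dR);
  };
  auto dg = [&](double x) {
    return q.spt.dp(x, dL) + q.lvf.dp(V_lv - x, dL) + q.rvf.dp(V_rv + x, dR);
  };
  if (!std::isfinite(V_lv) || !std::isfinite(V_rv)) return NAN;
  double lo = -200.0, hi = 200.0;
  for (int k = 0; k < 60 && g(lo) > 0; ++k) lo *= 2.0;
  for (int k = 0; k < 60 && g(hi) < 0; ++k) hi *= 2.0;
  // a wild intermediate state (e.g. a Runge-Kutta trial stage about to
  // be rejected) can defeat the bracket; report NaN and let the step
  // controller reject the step rather than aborting the integration
  if (!(g(lo) <= 0 && g(hi) >= 0)) return NAN;
  double x = x0;
  if (!(x > lo && x < hi)) x = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    double f = g(x);
    if (std::fabs(f) < 1e-12) return x;
    if (f > 0) hi = x; else lo = x;
    double d = dg(x);
    double xn = (d > 0) ? x - f / d : x;
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);  // bisection fallback
    if (std::fabs(xn - x) < 1e-9) return xn;
    x = xn;
  }
  return x;
}

enum Mode { CLOSED = 0, SYSTEMIC = 1, PULMONARY = 2 };

// Full instantaneous record at (t, state).  State layout:
//   CLOSED:    V_lv V_ao V_vc V_rv V_pa V_pu
//   SYSTEMIC:  V_lv V_ao            (P_pu, P_vc fixed sources)
//   PULMONARY: V_rv V_pa            (P_vc, P_pu fixed sources)
struct Record {
  double P_lv, P_ao, P_vc, P_rv, P_pa, P_pu;
  double Q_mt, Q_av, Q_sys, Q_tc, Q_pv, Q_pul;
  double V_spt, P_pcd;
};

Record evaluate(const Params& q, int mode, double t, const double* v,
                double* vspt_cache) {
  Record r;
  double dL = q.driL.value(t), dR = q.driR.value(t);
  if (mode == CLOSED) {
    double V_lv = v[0], V_ao = v[1], V_vc = v[2], V_rv = v[3], V_pa = v[4],
           V_pu = v[5];
    double x = solve_septum(q, V_lv, V_rv, dL, dR, *vspt_cache);
    *vspt_cache = x;
    r.V_spt = x;
    double V_pcd = V_lv + V_rv;
    r.P_pcd = q.P_0_pcd * std::expm1(q.lambda_pcd * (V_pcd - q.V_0_pcd));
    r.P_lv = q.lvf.p(V_lv - x, dL) + r.P_pcd + q.P_th;
    r.P_rv = q.rvf.p(V_rv + x, dR) + r.P_pcd + q.P_th;
    r.P_ao = q.E_ao * (V_ao - q.V_d_ao);
    r.P_vc = q.E_vc * (V_vc - q.V_d_vc);
    r.P_pa = q.E_pa * (V_pa - q.V_d_pa);
    r.P_pu = q.E_pu * (V_pu - q.V_d_pu);
  } else if (mode == SYSTEMIC) {
    double V_lv = v[0], V_ao = v[1];
    r.V_spt = NA_REAL; r.P_pcd = 0.0;
    r.P_lv = q.lvf.p(V_lv, dL);
    r.P_ao = q.E_ao * (V_ao - q.V_d_ao);
    r.P_pu = q.P_pu_src;
    r.P_vc = q.P_vc_src;
    r.P_rv = NA_REAL; r.P_pa = NA_REAL;
  } else {
    double V_rv = v[0], V_pa = v[1];
    r.V_spt = NA_REAL; r.P_pcd = 0.0;
    r.P_rv = q.rvf.p(V_rv, dR);
    r.P_pa = q.E_pa * (V_pa - q.V_d_pa);
    r.P_vc = q.P_vc_src;
    r.P_pu = q.P_pu_src;
    r.P_lv = NA_REAL; r.P_ao = NA_REAL;
  }
  // pressure-gated valves (ideal diodes, inertances zero)
  r.Q_mt = (mode == PULMONARY) ? NA_REAL
           : std::max(0.0, (r.P_pu - r.P_lv) / q.R_mt);
  r.Q_av = (mode == PULMONARY) ? NA_REAL
           : std::max(0.0, (r.P_lv - r.P_ao) / q.R_av);
  r.Q_sys = (mode == PULMONARY) ? NA_REAL : (r.P_ao - r.P_vc) / q.R_sys;
  r.Q_tc = (mode == SYSTEMIC) ? NA_REAL
           : std::max(0.0, (r.P_vc - r.P_rv) / q.R_tc);
  r.Q_pv = (mode == SYSTEMIC) ? NA_REAL
           : std::max(0.0, (r.P_rv - r.P_pa) / q.R_pv);
  r.Q_pul = (mode == SYSTEMIC) ? NA_REAL : (r.P_pa - r.P_pu) / q.R_pul;
  return r;
}

void rhs(const Params& q, int mode, double t, const double* v, double* dv,
         double* vspt_cache) {
  Record r = evaluate(q, mode, t, v, vspt_cache);
  if (mode == CLOSED) {
    dv[0] = r.Q_mt - r.Q_av;
    dv[1] = r.Q_av - r.Q_sys;
    dv[2] = r.Q_sys - r.Q_tc;
    dv[3] = r.Q_tc - r.Q_pv;
    dv[4] = r.Q_pv - r.Q_pul;
    dv[5] = r.Q_pul - r.Q_mt;
  } else if (mode == SYSTEMIC) {
    dv[0] = r.Q_mt - r.Q_av;
    dv[1] = r.Q_av - r.Q_sys;
  } else {
    dv[0] = r.Q_tc - r.Q_pv;
    dv[1] = r.Q_pv - r.Q_pul;
  }
}

// Dormand-Prince 5(4) with standard step control.
struct Integrator {
  const Params& q;
  int mode, dim;
  double rtol, atol;
  double h;           // current step proposal
  double vspt_cache;  // warm start for the septum root
  long n_rhs = 0;

  Integrator(const Params& q_, int mode_, double rtol_, double atol_)
      : q(q_), mode(mode_), dim(mode_ == CLOSED ? 6 : 2), rtol(rtol_),
        atol(atol_), h(1e-3), vspt_cache(0.0) {}

  void f(double t, const double* v, double* dv) {
    rhs(q, mode, t, v, dv, &vspt_cache);
    ++n_rhs;
  }

  // advance state in place from t to t_end
  void advance(double& t, double* v, double t_end) {
    static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                        c5 = 8.0 / 9;
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                        a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                        a65 = -5103.0 / 18656;
    static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                        b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                        e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                        e6 = 22.0 / 525, e7 = -1.0 / 40;
    std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
        k7(dim), y(dim), yn(dim);
    int rejected_in_a_row = 0;
    while (t < t_end - 1e-12) {
      double hs = std::min(h, t_end - t);
      f(t, v, k1.data());
      for (int i = 0; i < dim; ++i) y[i] = v[i] + hs * a21 * k1[i];
      f(t + c2 * hs, y.data(), k2.data());
      for (int i = 0; i < dim; ++i)
        y[i] = v[i] + hs * (a31 * k1[i] + a32 * k2[i]);
      f(t + c3 * hs, y.data(), k3.data());
      for (int i = 0; i < dim; ++i)
        y[i] = v[i] + hs * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      f(t + c4 * hs, y.data(), k4.data());
      for (int i = 0; i < dim; ++i)
        y[i] = v[i] + hs * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
      f(t + c5 * hs, y.data(), k5.data());
      for (int i = 0; i < dim; ++i)
        y[i] = v[i] + hs * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
      f(t + hs, y.data(), k6.data());
      for (int i = 0; i < dim; ++i)
        yn[i] = v[i] + hs * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                             b5 * k5[i] + b6 * k6[i]);
      f(t + hs, yn.data(), k7.data());
      double err = 0.0;
      for (int i = 0; i < dim; ++i) {
        double e = hs * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(v[i]), std::fabs(yn[i]));
        double w = e / sc;
        err += w * w;
      }
      err = std::sqrt(err / dim);
      if (!std::isfinite(err)) err = 1e10;  // NaN stage: reject the step
      if (err <= 1.0) {
        t += hs;
        for (int i = 0; i < dim; ++i) v[i] = yn[i];
        double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
        h = hs * std::min(5.0, std::max(0.2, fac));
        rejected_in_a_row = 0;
      } else {
        h = hs * std::max(0.1, 0.9 * std::pow(err, -0.2));
        if (++rejected_in_a_row > 50)
          stop("integration failed at t = %g (repeated step rejection)", t);
      }
      if (h < 1e-10) stop("integration step underflow at t = %g", t);
    }
  }
};

List sample_run(Integrator& I, const Params& q, int mode, double t0,
                std::vector<double>& v, int n_beats, double fs) {
  double T = q.driL.period;
  int per_beat = (int)std::lround(T * fs);
  int n = per_beat * n_beats;
  NumericMatrix out(n, 21);
  CharacterVector nm = CharacterVector::create(
      "t", "V_lv", "V_ao", "V_vc", "V_rv", "V_pa", "V_pu", "V_spt", "P_lv",
      "P_ao", "P_vc", "P_rv", "P_pa", "P_pu", "Q_mt", "Q_av", "Q_sys",
      "Q_tc", "Q_pv", "Q_pul", "P_pcd");
  colnames(out) = nm;
  double t = t0;
  for (int s = 0; s < n; ++s) {
    double ts = t0 + (double)s / fs;
    if (ts > t) I.advance(t, v.data(), ts);
    double cache = I.vspt_cache;
    Record r = evaluate(q, mode, ts, v.data(), &cache);
    out(s, 0) = ts - t0;
    if (mode == CLOSED) {
      for (int i = 0; i < 6; ++i) out(s, 1 + i) = v[i];
    } else if (mode == SYSTEMIC) {
      out(s, 1) = v[0]; out(s, 2) = v[1];
      out(s, 3) = NA_REAL; out(s, 4) = NA_REAL; out(s, 5) = NA_REAL;
      out(s, 6) = NA_REAL;
    } else {
      out(s, 4) = v[0]; out(s, 5) = v[1];
      out(s, 1) = NA_REAL; out(s, 2) = NA_REAL; out(s, 3) = NA_REAL;
      out(s, 6) = NA_REAL;
    }
    out(s, 7) = r.V_spt;
    out(s, 8) = r.P_lv; out(s, 9) = r.P_ao; out(s, 10) = r.P_vc;
    out(s, 11) = r.P_rv; out(s, 12) = r.P_pa; out(s, 13) = r.P_pu;
    out(s, 14) = r.Q_mt; out(s, 15) = r.Q_av; out(s, 16) = r.Q_sys;
    out(s, 17) = r.Q_tc; out(s, 18) = r.Q_pv; out(s, 19) = r.Q_pul;
    out(s, 20) = r.P_pcd;
  }
  // advance to the exact end of the last beat so the final state closes it
  double t_end = t0 + (double)n_beats * T;
  if (t_end > t) I.advance(t, v.data(), t_end);
  return List::create(_["samples"] = out,
                      _["state"] = NumericVector(v.begin(), v.end()),
                      _["n_rhs"] = (double)I.n_rhs);
}

}  // namespace

// [[Rcpp::export]]
double cpp_driver_value(List driver, double t) {
  Driver d = driver_from_list(driver);
  return d.value(t);
}

// [[Rcpp::export]]
double cpp_septum_volume(List params, double V_lv, double V_rv, double driL,
                         double driR) {
  Params q = params_from_list(params);
  return solve_septum(q, V_lv, V_rv, driL, driR, 0.0);
}

// [[Rcpp::export]]
List cpp_simulate(List params, int mode, NumericVector state0, int n_beats,
                  double fs, double rtol, double atol) {
  Params q = params_from_list(params);
  Integrator I(q, mode, rtol, atol);
  if (state0.size() != I.dim) stop("state has wrong length for this mode");
  std::vector<double> v(state0.begin(), state0.end());
  return sample_run(I, q, mode, 0.0, v, n_beats, fs);
}

// Integrate beat by beat until the state at beat onset settles (max
// absolute change < tol_ml), then sample the final beat.
// [[Rcpp::export]]
List cpp_steady_state(List params, int mode, NumericVector state0, double fs,
                      double tol_ml, int max_beats, double rtol, double atol) {
  Params q = params_from_list(params);
  Integrator I(q, mode, rtol, atol);
  if (state0.size() != I.dim) stop("state has wrong length for this mode");
  std::vector<double> v(state0.begin(), state0.end()), prev(v);
  double T = q.driL.period, t = 0.0;
  bool converged = false;
  int beat = 0;
  for (; beat < max_beats; ++beat) {
    prev = v;
    I.advance(t, v.data(), (beat + 1) * T);
    double dmax = 0.0;
    for (int i = 0; i < I.dim; ++i)
      dmax = std::max(dmax, std::fabs(v[i] - prev[i]));
    if (dmax < tol_ml) { converged = true; ++beat; break; }
  }
  List run = sample_run(I, q, mode, t, v, 1, fs);
  run["converged"] = converged;
  run["beats_run"] = beat;
  return run;
}
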