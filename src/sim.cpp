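#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley gating rate functions (squid kinetics, 1/ms, v in mV).
// vtrap guards the removable singularities of the alpha functions.
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}
static inline double alpha_m(double v) { return 0.1 * vtrap(-(v + 40.0), 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) { return 0.01 * vtrap(-(v + 55.0), 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

static inline double exp_euler(double x, double a, double b, double dt) {
  double tau = 1.0 / (a + b), xi = a * tau;
  return xi + (x - xi) * std::exp(-dt / tau);
}

// Boltzmann gate for the NMDA conductance, depolarization-activated
// convention: scale = A2 + (A1 - A2) / (1 + exp((x0 - v)/dx)).
static inline double nmda_gate_c(double v, double A1, double A2, double x0, double dx) {
  double z = (x0 - v) / dx;
  if (z > 500.0) return A2;
  if (z < -500.0) return A1;
  return A2 + (A1 - A2) / (1.0 + std::exp(z));
}

// Single-compartment HH / passive simulation.
// events: columns onset_ms, gmax_nS, tau_ms, erev_mV, nmda_flag (sorted by onset)
// Units: conductances uS, capacitance nF, currents nA, voltage mV, time ms.
// [[Rcpp::export(name = ".hh_point_sim")]]
List hh_point_sim(List model, NumericMatrix events, List nmda,
                  double duration_ms, double dt_ms, double record_dt_ms,
                  double i_amp_nA, double i_onset_ms, double i_dur_ms,
                  bool record_currents, bool record_gates) {
  const double area = as<double>(model["area_cm2"]);
  const double C    = as<double>(model["cm_uf_cm2"]) * area * 1e3;   // nF
  const double gpas = as<double>(model["gpas_s_cm2"]) * area * 1e6;  // uS
  const double epas = as<double>(model["epas_mv"]);
  const bool active = as<bool>(model["active"]);
  const double gna  = active ? as<double>(model["gna_s_cm2"]) * area * 1e6 : 0.0;
  const double gk   = active ? as<double>(model["gk_s_cm2"]) * area * 1e6 : 0.0;
  const double gl   = active ? as<double>(model["gl_s_cm2"]) * area * 1e6 : 0.0;
  const double ena = as<double>(model["ena_mv"]), ek = as<double>(model["ek_mv"]),
               el = as<double>(model["el_mv"]);
  const double shift = as<double>(model["kdr_shift_mv"]);
  double v = as<double>(model["v0"]);
  double m = as<double>(model["m0"]), h = as<double>(model["h0"]), n = as<double>(model["n0"]);
  const double A1 = as<double>(nmda["A1"]), A2 = as<double>(nmda["A2"]),
               x0 = as<double>(nmda["x0"]), dx = as<double>(nmda["dx"]);

  const int n_steps = (int)std::llround(duration_ms / dt_ms);
  const int rec_every = (int)std::llround(record_dt_ms / dt_ms);
  const int n_rec = n_steps / rec_every + 1;
  NumericVector t_out(n_rec), v_out(n_rec);
  NumericVector ina_out(record_currents ? n_rec : 0), ik_out(record_currents ? n_rec : 0);
  NumericVector m_out(record_gates ? n_rec : 0), h_out(record_gates ? n_rec : 0),
                n_out(record_gates ? n_rec : 0);
  const int n_ev = events.nrow();

  int rec = 0, lo = 0;
  auto record = [&](double t) {
    t_out[rec] = t; v_out[rec] = v;
    if (record_currents) {
      ina_out[rec] = gna * m * m * m * h * (v - ena);
      ik_out[rec]  = gk * std::pow(n, 4.0) * (v - ek);
    }
    if (record_gates) { m_out[rec] = m; h_out[rec] = h; n_out[rec] = n; }
    ++rec;
  };
  record(0.0);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt_ms;
    // gate update (exponential Euler), KDR shift applied inside n kinetics
    if (active) {
      m = exp_euler(m, alpha_m(v), beta_m(v), dt_ms);
      h = exp_euler(h, alpha_h(v), beta_h(v), dt_ms);
      double vn = v - shift;
      n = exp_euler(n, alpha_n(vn), beta_n(vn), dt_ms);
    }
    // synaptic conductances
    double gsum = 0.0, gesum = 0.0;
    while (lo < n_ev && (t - events(lo, 0)) / events(lo, 2) > 16.0) ++lo;
    for (int e = lo; e < n_ev; ++e) {
      double on = events(e, 0);
      if (on > t) break;
      double x = (t - on) / events(e, 2);
      if (x > 16.0) continue;
      double g = events(e, 1) * 1e-3 * x * std::exp(1.0 - x);  // nS -> uS
      if (events(e, 4) != 0.0) g *= nmda_gate_c(v, A1, A2, x0, dx);
      gsum += g; gesum += g * events(e, 3);
    }
    double i_inj = (t >= i_onset_ms && t < i_onset_ms + i_dur_ms) ? i_amp_nA : 0.0;
    double gna_t = gna * m * m * m * h, gk_t = gk * std::pow(n, 4.0);
    double gtot = gna_t + gk_t + gl + gpas + gsum;
    double ge   = gna_t * ena + gk_t * ek + gl * el + gpas * epas + gesum;
    v = (C / dt_ms * v + ge + i_inj) / (C / dt_ms + gtot);  // backward Euler
    if (!std::isfinite(v)) stop("voltage integration diverged at t = %f ms", t);
    if ((s + 1) % rec_every == 0) record((s + 1) * dt_ms);
  }

  List out = List::create(_["t_ms"] = t_out, _["v_mv"] = v_out,
                          _["final"] = NumericVector::create(v, m, h, n));
  if (record_currents) { out["ina_na"] = ina_out; out["ik_na"] = ik_out; }
  if (record_gates) { out["m"] = m_out; out["h"] = h_out; out["n"] = n_out; }
  return out;
}

// Unbranched passive cable chain with an active (HH) somatic compartment.
// Each compartment is a cylinder (length_um, diam_um taken per compartment).
// events carry a compartment index column: onset, gmax, tau, erev, nmda, comp(1-based)
// [[Rcpp::export(name = ".hh_cable_sim")]]
List hh_cable_sim(List model, int n_comp, NumericVector length_um, NumericVector diam_um,
                  NumericMatrix events, List nmda,
                  double duration_ms, double dt_ms, double record_dt_ms,
                  bool soma_active, bool record_all, double epas_dend) {
  const double cm = as<double>(model["cm_uf_cm2"]);
  const double gpas_d = as<double>(model["gpas_s_cm2"]);
  const double epas = as<double>(model["epas_mv"]);
  const double ri = as<double>(model["ri_ohm_cm"]);
  const double gna_d = as<double>(model["gna_s_cm2"]), gk_d = as<double>(model["gk_s_cm2"]),
               gl_d = as<double>(model["gl_s_cm2"]);
  const double ena = as<double>(model["ena_mv"]), ek = as<double>(model["ek_mv"]),
               el = as<double>(model["el_mv"]);
  const double shift = as<double>(model["kdr_shift_mv"]);
  const double v0 = as<double>(model["v0"]);
  double m = as<double>(model["m0"]), h = as<double>(model["h0"]), n = as<double>(model["n0"]);
  const double A1 = as<double>(nmda["A1"]), A2 = as<double>(nmda["A2"]),
               x0 = as<double>(nmda["x0"]), dx = as<double>(nmda["dx"]);

  std::vector<double> area(n_comp), C(n_comp), gpas(n_comp), gax(n_comp > 1 ? n_comp - 1 : 0);
  for (int i = 0; i < n_comp; ++i) {
    area[i] = M_PI * (diam_um[i] * 1e-4) * (length_um[i] * 1e-4);  // cm2
    C[i] = cm * area[i] * 1e3;        // nF
    gpas[i] = gpas_d * area[i] * 1e6; // uS
  }
  for (int i = 0; i + 1 < n_comp; ++i) {
    // series of two half-cylinder axial resistances, in uS
    double r1 = ri * (length_um[i] * 1e-4 / 2.0) / (M_PI * std::pow(diam_um[i] * 1e-4 / 2.0, 2.0));
    double r2 = ri * (length_um[i + 1] * 1e-4 / 2.0) / (M_PI * std::pow(diam_um[i + 1] * 1e-4 / 2.0, 2.0));
    gax[i] = 1e6 / (r1 + r2);
  }
  const double gna = soma_active ? gna_d * area[0] * 1e6 : 0.0;
  const double gk  = soma_active ? gk_d * area[0] * 1e6 : 0.0;
  const double gl  = soma_active ? gl_d * area[0] * 1e6 : 0.0;

  std::vector<double> v(n_comp, v0);
  const int n_steps = (int)std::llround(duration_ms / dt_ms);
  const int rec_every = (int)std::llround(record_dt_ms / dt_ms);
  const int n_rec = n_steps / rec_every + 1;
  NumericVector t_out(n_rec), v_out(n_rec);
  NumericMatrix v_all(record_all ? n_rec : 0, record_all ? n_comp : 0);
  const int n_ev = events.nrow();
  std::vector<double> a(n_comp), bdiag(n_comp), cc(n_comp), dvec(n_comp);

  int rec = 0;
  auto record = [&](double t) {
    t_out[rec] = t; v_out[rec] = v[0];
    if (record_all) for (int i = 0; i < n_comp; ++i) v_all(rec, i) = v[i];
    ++rec;
  };
  record(0.0);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt_ms;
    if (soma_active) {
      m = exp_euler(m, alpha_m(v[0]), beta_m(v[0]), dt_ms);
      h = exp_euler(h, alpha_h(v[0]), beta_h(v[0]), dt_ms);
      double vn = v[0] - shift;
      n = exp_euler(n, alpha_n(vn), beta_n(vn), dt_ms);
    }
    // per-compartment membrane conductance and driving terms
    for (int i = 0; i < n_comp; ++i) {
      double e_i = (i == 0) ? epas : epas_dend;
      double gsum = gpas[i], gesum = gpas[i] * e_i;
      if (i == 0 && soma_active) {
        double gna_t = gna * m * m * m * h, gk_t = gk * std::pow(n, 4.0);
        gsum += gna_t + gk_t + gl;
        gesum += gna_t * ena + gk_t * ek + gl * el;
      }
      bdiag[i] = C[i] / dt_ms + gsum;
      dvec[i] = C[i] / dt_ms * v[i] + gesum;
      a[i] = cc[i] = 0.0;
    }
    for (int e = 0; e < n_ev; ++e) {
      double on = events(e, 0);
      if (on > t) break;
      double x = (t - on) / events(e, 2);
      if (x > 16.0) continue;
      int ci = (int)events(e, 5) - 1;
      double g = events(e, 1) * 1e-3 * x * std::exp(1.0 - x);
      if (events(e, 4) != 0.0) g *= nmda_gate_c(v[ci], A1, A2, x0, dx);
      bdiag[ci] += g; dvec[ci] += g * events(e, 3);
    }
    // axial coupling (implicit): tridiagonal system
    for (int i = 0; i + 1 < n_comp; ++i) {
      bdiag[i] += gax[i]; bdiag[i + 1] += gax[i];
      cc[i] = -gax[i]; a[i + 1] = -gax[i];
    }
    // Thomas algorithm
    for (int i = 1; i < n_comp; ++i) {
      double w = a[i] / bdiag[i - 1];
      bdiag[i] -= w * cc[i - 1];
      dvec[i] -= w * dvec[i - 1];
    }
    v[n_comp - 1] = dvec[n_comp - 1] / bdiag[n_comp - 1];
    for (int i = n_comp - 2; i >= 0; --i)
      v[i] = (dvec[i] - cc[i] * v[i + 1]) / bdiag[i];
    if (!std::isfinite(v[0])) stop("cable integration diverged at t = %f ms", t);
    if ((s + 1) % rec_every == 0) record((s + 1) * dt_ms);
  }

  List out = List::create(_["t_ms"] = t_out, _["v_mv"] = v_out);
  if (record_all) out["v_all"] = v_all;
  return out;
}

// Izhikevich two-variable spiking model, one explicit update per drive sample,
// step scaled by the free dt parameter. Spike cutoff fixed at +30.
// [[Rcpp::export(name = ".izh_sim")]]
List izh_sim(double a, double b, double c, double d, double dtp,
             NumericVector drive, double v0, double u0) {
  int nsteps = drive.size();
  NumericVector v_out(nsteps);
  std::vector<int> spikes;
  double v = v0, u = u0;
  for (int s = 0; s < nsteps; ++s) {
    double dv = 0.04 * v * v + 5.0 * v + 140.0 - u + drive[s];
    double du = a * (b * v - u);
    v += dtp * dv;
    u += dtp * du;
    if (v >= 30.0) {
      v_out[s] = 30.0;
      spikes.push_back(s + 1);
      v = c; u += d;
    } else {
      v_out[s] = v;
    }
    if (!std::isfinite(v) || std::fabs(v) > 1e6) { v = c; }  // overflow guard
  }
  return List::create(_["v"] = v_out, _["spike_idx"] = wrap(spikes),
                      _["final"] = NumericVector::create(v, u));
}
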