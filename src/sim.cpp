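#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment DRG neuron model.
// State: V (mV), m (Nav activation), h (Nav inactivation), n (Kdr activation),
// na (submembrane [Na+], mM). Conductances in nS, currents in pA, time in ms.
// dV/dt = (-(I_Nav + I_Kdr + I_KNa + I_leak) + I_inj) / C  [pA/pF = mV/ms]
// d[Na]/dt = -I_Nav / (F * shell_volume) - ([Na] - na_rest) / tau_ex
// with F*vol in pC/mM when volume is in pl: 96.48533 pC per (mM * pl).

struct Pars {
  double C;
  double gna, vhm, km, vhh, kh, taum, tauh, ena;
  double gk, vhn, kn, taun, ek;
  double gl, el;
  double gkna, ec50, hill, ekna;
  double navol, taux, narest;
};

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double hillact(double na, const Pars &p) {
  if (na <= 0.0) return 0.0;
  double r = std::pow(na / p.ec50, p.hill);
  return r / (1.0 + r);
}

static Pars unpack(const List &par) {
  Pars p;
  p.C = par["C"];
  p.gna = par["gna"]; p.vhm = par["vhm"]; p.km = par["km"];
  p.vhh = par["vhh"]; p.kh = par["kh"];
  p.taum = par["taum"]; p.tauh = par["tauh"]; p.ena = par["ena"];
  p.gk = par["gk"]; p.vhn = par["vhn"]; p.kn = par["kn"];
  p.taun = par["taun"]; p.ek = par["ek"];
  p.gl = par["gl"]; p.el = par["el"];
  p.gkna = par["gkna"]; p.ec50 = par["ec50"]; p.hill = par["hill"];
  p.ekna = par["ekna"];
  p.navol = par["navol"]; p.taux = par["taux"]; p.narest = par["narest"];
  return p;
}

struct State { double v, m, h, n, na; };

static inline State deriv_cc(const State &s, double iinj, const Pars &p) {
  State d;
  double ina = p.gna * s.m * s.h * (s.v - p.ena);
  double ik  = p.gk * s.n * (s.v - p.ek);
  double ikna = p.gkna * hillact(s.na, p) * (s.v - p.ekna);
  double il = p.gl * (s.v - p.el);
  d.v = (-(ina + ik + ikna + il) + iinj) / p.C;
  d.m = (boltz(s.v, p.vhm, p.km) - s.m) / p.taum;
  d.h = (boltz(-s.v, -p.vhh, p.kh) - s.h) / p.tauh;
  d.n = (boltz(s.v, p.vhn, p.kn) - s.n) / p.taun;
  d.na = -ina / (96485.33212 * p.navol) - (s.na - p.narest) / p.taux;
  return d;
}

static inline State axpy(const State &s, const State &d, double a) {
  State r;
  r.v = s.v + a * d.v; r.m = s.m + a * d.m; r.h = s.h + a * d.h;
  r.n = s.n + a * d.n; r.na = s.na + a * d.na;
  return r;
}

// [[Rcpp::export(name = ".cc_rk4")]]
List cc_rk4(List par, NumericVector i_inj, double dt,
            double v0, double m0, double h0, double n0, double na0) {
  Pars p = unpack(par);
  int nsamp = i_inj.size();
  NumericVector V(nsamp), NA_out(nsamp);
  State s; s.v = v0; s.m = m0; s.h = h0; s.n = n0; s.na = na0;
  for (int i = 0; i < nsamp; ++i) {
    V[i] = s.v; NA_out[i] = s.na;
    if (!std::isfinite(s.v))
      stop("integration failure: non-finite membrane potential at t = %f ms",
           i * dt);
    double ii = i_inj[i];
    double in = (i + 1 < nsamp) ? i_inj[i + 1] : ii;
    double im = 0.5 * (ii + in);
    State k1 = deriv_cc(s, ii, p);
    State k2 = deriv_cc(axpy(s, k1, dt / 2), im, p);
    State k3 = deriv_cc(axpy(s, k2, dt / 2), im, p);
    State k4 = deriv_cc(axpy(s, k3, dt), in, p);
    s.v  += dt / 6 * (k1.v + 2 * k2.v + 2 * k3.v + k4.v);
    s.m  += dt / 6 * (k1.m + 2 * k2.m + 2 * k3.m + k4.m);
    s.h  += dt / 6 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
    s.n  += dt / 6 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
    s.na += dt / 6 * (k1.na + 2 * k2.na + 2 * k3.na + k4.na);
    if (s.na < 0) s.na = 0;
  }
  return List::create(_["V"] = V, _["na"] = NA_out);
}

struct GState { double m, h, n, na; };

static inline GState deriv_vc(const GState &g, double v, const Pars &p) {
  GState d;
  double ina = p.gna * g.m * g.h * (v - p.ena);
  d.m = (boltz(v, p.vhm, p.km) - g.m) / p.taum;
  d.h = (boltz(-v, -p.vhh, p.kh) - g.h) / p.tauh;
  d.n = (boltz(v, p.vhn, p.kn) - g.n) / p.taun;
  d.na = -ina / (96485.33212 * p.navol) - (g.na - p.narest) / p.taux;
  return d;
}

static inline GState gaxpy(const GState &s, const GState &d, double a) {
  GState r;
  r.m = s.m + a * d.m; r.h = s.h + a * d.h;
  r.n = s.n + a * d.n; r.na = s.na + a * d.na;
  return r;
}

// Voltage-clamp run: membrane potential follows v_cmd exactly; gating and
// submembrane Na+ are integrated and the total ionic current returned.
// Extracellular Cs+ block (fraction f(V) = 1 - A/(1+exp(-(V-vh)/k))) scales
// the K+ currents (Kdr and KNa) by (1 - f(V)) when cs_on is true.
// [[Rcpp::export(name = ".vc_rk4")]]
NumericVector vc_rk4(List par, NumericVector v_cmd, double dt,
                     double m0, double h0, double n0, double na0,
                     bool cs_on, double cs_A, double cs_vh, double cs_k) {
  Pars p = unpack(par);
  int nsamp = v_cmd.size();
  NumericVector I(nsamp);
  GState s; s.m = m0; s.h = h0; s.n = n0; s.na = na0;
  for (int i = 0; i < nsamp; ++i) {
    double v = v_cmd[i];
    double ina = p.gna * s.m * s.h * (v - p.ena);
    double ik  = p.gk * s.n * (v - p.ek);
    double ikna = p.gkna * hillact(s.na, p) * (v - p.ekna);
    if (cs_on) {
      double f = 1.0 - cs_A / (1.0 + std::exp(-(v - cs_vh) / cs_k));
      double pass = 1.0 - f;
      ik *= pass; ikna *= pass;
    }
    double il = p.gl * (v - p.el);
    I[i] = ina + ik + ikna + il;
    double vn = (i + 1 < nsamp) ? v_cmd[i + 1] : v;
    double vm = 0.5 * (v + vn);
    GState k1 = deriv_vc(s, v, p);
    GState k2 = deriv_vc(gaxpy(s, k1, dt / 2), vm, p);
    GState k3 = deriv_vc(gaxpy(s, k2, dt / 2), vm, p);
    GState k4 = deriv_vc(gaxpy(s, k3, dt), vn, p);
    s.m  += dt / 6 * (k1.m + 2 * k2.m + 2 * k3.m + k4.m);
    s.h  += dt / 6 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
    s.n  += dt / 6 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
    s.na += dt / 6 * (k1.na + 2 * k2.na + 2 * k3.na + k4.na);
    if (s.na < 0) s.na = 0;
  }
  return I;
}
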