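// Implicit cable-equation core: Hines-ordered tree solve (theta method,
// backward Euler by default, Crank-Nicolson optional) with staggered
// exponential-Euler gate updates, backward-Euler Markov updates and
// implicit single-shell Ca dynamics.
//
// Units: mV, ms, nA, uS, nF, uM, cm2. Compartments are ordered so that every
// parent index is smaller than its child index; parent[root] == -1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212;

// ---- rate / gate helpers ----------------------------------------------------

struct RateFn {
  int type;            // 0 const, 1 exp, 2 linoid, 3 sigmoid
  double a, v0, k;
  double eval(double v) const {
    switch (type) {
    case 0: return a;
    case 1: return a * std::exp((v - v0) / k);
    case 2: {
      double x = (v - v0) / k;
      if (std::fabs(x) < 1e-7) return a * k;
      return a * k * x / (1.0 - std::exp(-x));
    }
    default: return a / (1.0 + std::exp(-(v - v0) / k));
    }
  }
};

static inline double ipow(double x, int n) {
  double r = 1.0;
  while (n > 0) { if (n & 1) r *= x; x *= x; n >>= 1; }
  return r;
}

struct GateSpec {
  int mode;            // 0 inftau, 1 alphabeta, 2 cahill
  int expo;
  double vhalf, k;
  double tau_amp, tau_mean, tau_sd, tau_base;
  RateFn alpha, beta;
  double kd, hill;
  bool inhib;
  double tauscale;     // q10^((T - tref)/10)
  // voltage lookup tables (built per run for fixed dt): xinf and
  // exp(-dt/tau) on a uniform grid; cahill gates use kdh + constant efact
  std::vector<double> tab_inf, tab_ef;
  double kdh, ef_const;

  double xinf(double v, double ca) const {
    if (mode == 0) return 1.0 / (1.0 + std::exp((vhalf - v) / k));
    if (mode == 1) {
      double a = alpha.eval(v), b = beta.eval(v);
      return a / (a + b);
    }
    double f = std::pow(ca, hill) / (std::pow(ca, hill) + std::pow(kd, hill));
    return inhib ? 1.0 - f : f;
  }
  double tau(double v) const {
    double t;
    if (mode == 1) t = 1.0 / (alpha.eval(v) + beta.eval(v));
    else t = tau_amp * std::exp(-((v - tau_mean) / tau_sd) *
                                ((v - tau_mean) / tau_sd)) + tau_base;
    return t / tauscale;
  }
};

static const double TAB_VMIN = -150.0, TAB_VMAX = 80.0, TAB_DV = 0.25;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

static void build_gate_tables(GateSpec& g, double dt) {
  if (g.mode == 2) {
    g.kdh = std::pow(g.kd, g.hill);
    g.ef_const = std::exp(-dt / (g.tau_base / g.tauscale));
    return;
  }
  g.tab_inf.resize(TAB_N);
  g.tab_ef.resize(TAB_N);
  for (int i = 0; i < TAB_N; ++i) {
    double v = TAB_VMIN + i * TAB_DV;
    g.tab_inf[i] = g.xinf(v, 0.0);
    g.tab_ef[i] = std::exp(-dt / g.tau(v));
  }
}

static inline void gate_lookup(const GateSpec& g, double v, double ca,
                               double& xi, double& ef) {
  if (g.mode == 2) {
    double ch = std::pow(ca, g.hill);
    double f = ch / (ch + g.kdh);
    xi = g.inhib ? 1.0 - f : f;
    ef = g.ef_const;
    return;
  }
  double u = (v - TAB_VMIN) / TAB_DV;
  if (u <= 0) { xi = g.tab_inf[0]; ef = g.tab_ef[0]; return; }
  if (u >= TAB_N - 1) { xi = g.tab_inf[TAB_N - 1]; ef = g.tab_ef[TAB_N - 1];
                        return; }
  int i = (int)u;
  double w = u - i;
  xi = g.tab_inf[i] + w * (g.tab_inf[i + 1] - g.tab_inf[i]);
  ef = g.tab_ef[i] + w * (g.tab_ef[i + 1] - g.tab_ef[i]);
}

struct MarkovSpec {
  int nstates;
  std::vector<int> from, to;
  std::vector<double> ca_power;
  std::vector<RateFn> rate;
  std::vector<int> open;
  double ratescale;
};

struct Channel {
  int kind;            // 0 passive, 1 instantaneous, 2 hh, 3 markov
  std::vector<int> comp;
  std::vector<double> gbar;   // uS
  double erev;
  bool is_ca;
  std::vector<GateSpec> gates;
  MarkovSpec mk;
  // state: gates -> [gate][instance]; markov -> [instance][state]
  std::vector< std::vector<double> > gstate;
  std::vector< std::vector<double> > mstate;

  double open_frac(size_t j, double v, double ca) const {
    if (kind == 0) return 1.0;
    if (kind == 1) {
      double o = 1.0, xi, ef;
      for (size_t g = 0; g < gates.size(); ++g) {
        gate_lookup(gates[g], v, ca, xi, ef);
        o *= ipow(xi, gates[g].expo);
      }
      return o;
    }
    if (kind == 2) {
      double o = 1.0;
      for (size_t g = 0; g < gates.size(); ++g)
        o *= ipow(gstate[g][j], gates[g].expo);
      return o;
    }
    double o = 0.0;
    for (size_t s = 0; s < mk.open.size(); ++s) o += mstate[j][mk.open[s]];
    return o;
  }
};

static RateFn parse_rate(const List& r) {
  RateFn f;
  f.type = as<int>(r["type"]);
  f.a = as<double>(r["a"]); f.v0 = as<double>(r["v0"]);
  f.k = as<double>(r["k"]);
  return f;
}

static GateSpec parse_gate(const List& g) {
  GateSpec s;
  s.mode = as<int>(g["mode"]);
  s.expo = as<int>(g["exponent"]);
  s.vhalf = as<double>(g["vhalf"]); s.k = as<double>(g["k"]);
  s.tau_amp = as<double>(g["tau_amp"]); s.tau_mean = as<double>(g["tau_mean"]);
  s.tau_sd = as<double>(g["tau_sd"]); s.tau_base = as<double>(g["tau_base"]);
  if (s.mode == 1) {
    s.alpha = parse_rate(g["alpha"]);
    s.beta = parse_rate(g["beta"]);
  }
  s.kd = as<double>(g["kd"]); s.hill = as<double>(g["hill"]);
  s.inhib = as<bool>(g["inhib"]);
  s.tauscale = as<double>(g["tauscale"]);
  return s;
}

// dense backward-Euler solve of the master equation: (I - dt Q^T) p' = p
static void markov_be(const MarkovSpec& mk, std::vector<double>& p,
                      double v, double ca, double dt) {
  int n = mk.nstates;
  std::vector<double> Q(n * n, 0.0);
  for (size_t t = 0; t < mk.from.size(); ++t) {
    double r = mk.rate[t].eval(v) * mk.ratescale;
    if (mk.ca_power[t] > 0) r *= std::pow(ca, mk.ca_power[t]);
    Q[mk.from[t] * n + mk.to[t]] += r;
  }
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) rs += Q[i * n + j];
    Q[i * n + i] = -rs;
  }
  // M = I - dt Q^T ; solve M x = p
  std::vector<double> M(n * n, 0.0), b(p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      M[i * n + j] = (i == j ? 1.0 : 0.0) - dt * Q[j * n + i];
  for (int c = 0; c < n; ++c) {          // partial pivoting
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(M[r * n + c]) > std::fabs(M[piv * n + c])) piv = r;
    if (piv != c) {
      for (int j = 0; j < n; ++j) std::swap(M[c * n + j], M[piv * n + j]);
      std::swap(b[c], b[piv]);
    }
    double d = M[c * n + c];
    if (d == 0.0) stop("singular implicit Markov system");
    for (int r = c + 1; r < n; ++r) {
      double f = M[r * n + c] / d;
      if (f == 0.0) continue;
      for (int j = c; j < n; ++j) M[r * n + j] -= f * M[c * n + j];
      b[r] -= f * b[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = b[c];
    for (int j = c + 1; j < n; ++j) s -= M[c * n + j] * p[j];
    p[c] = s / M[c * n + c];
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { if (p[i] < 0) p[i] = 0; tot += p[i]; }
  for (int i = 0; i < n; ++i) p[i] /= tot;
}

// ---- main entry -------------------------------------------------------------

// [[Rcpp::export]]
List sim_core(IntegerVector parent, NumericVector area_cm2,
              NumericVector c_nF, NumericVector g_ax,
              List channels, List cadyn, List synapses,
              List iclamp, List vclamp,
              NumericVector v0, double dt, int nsteps, double theta,
              IntegerVector record, bool record_ca, bool record_ielec,
              bool init_steady) {
  const int n = parent.size();
  std::vector<double> v(v0.begin(), v0.end());
  if ((int)v.size() != n) stop("v0 length mismatch");

  // parse channels
  std::vector<Channel> chs;
  for (int c = 0; c < channels.size(); ++c) {
    List cl = channels[c];
    Channel ch;
    ch.kind = as<int>(cl["kind"]);
    ch.comp = as< std::vector<int> >(cl["comp"]);
    ch.gbar = as< std::vector<double> >(cl["gbar"]);
    ch.erev = as<double>(cl["erev"]);
    ch.is_ca = as<bool>(cl["is_ca"]);
    List gl = cl["gates"];
    for (int g = 0; g < gl.size(); ++g) ch.gates.push_back(parse_gate(gl[g]));
    if (ch.kind == 3) {
      List ml = cl["markov"];
      ch.mk.nstates = as<int>(ml["nstates"]);
      ch.mk.from = as< std::vector<int> >(ml["from"]);
      ch.mk.to = as< std::vector<int> >(ml["to"]);
      ch.mk.ca_power = as< std::vector<double> >(ml["ca_power"]);
      ch.mk.open = as< std::vector<int> >(ml["open"]);
      ch.mk.ratescale = as<double>(ml["ratescale"]);
      List rl = ml["rates"];
      for (int t = 0; t < rl.size(); ++t)
        ch.mk.rate.push_back(parse_rate(rl[t]));
    }
    for (size_t g = 0; g < ch.gates.size(); ++g)
      build_gate_tables(ch.gates[g], dt);
    chs.push_back(ch);
  }

  const double ca_depth = as<double>(cadyn["shell_depth"]);
  const double ca_kappa = as<double>(cadyn["kappa"]);
  const double ca_tau = as<double>(cadyn["decay_tau"]);
  const double ca0 = as<double>(cadyn["resting_ca"]);
  std::vector<double> ca(n, ca0);

  // initialize states
  for (size_t c = 0; c < chs.size(); ++c) {
    Channel& ch = chs[c];
    size_t ni = ch.comp.size();
    if (ch.kind == 2) {
      ch.gstate.assign(ch.gates.size(), std::vector<double>(ni));
      for (size_t g = 0; g < ch.gates.size(); ++g)
        for (size_t j = 0; j < ni; ++j)
          ch.gstate[g][j] = init_steady ?
            ch.gates[g].xinf(v[ch.comp[j]], ca0) : 0.0;
    } else if (ch.kind == 3) {
      ch.mstate.assign(ni, std::vector<double>(ch.mk.nstates,
                                               1.0 / ch.mk.nstates));
      if (init_steady)
        for (size_t j = 0; j < ni; ++j)
          for (int it = 0; it < 12; ++it)
            markov_be(ch.mk, ch.mstate[j], v[ch.comp[j]], ca0, 1e7);
    }
  }

  // synapses: double-exponential state per synapse
  struct Syn { int comp; double tr, td, g, e, norm; std::vector<double> tt;
               double A, B; size_t next; };
  std::vector<Syn> syns;
  for (int s = 0; s < synapses.size(); ++s) {
    List sl = synapses[s];
    Syn sy;
    sy.comp = as<int>(sl["comp"]);
    sy.tr = as<double>(sl["tau_r"]); sy.td = as<double>(sl["tau_d"]);
    sy.g = as<double>(sl["gmax_uS"]); sy.e = as<double>(sl["erev"]);
    sy.tt = as< std::vector<double> >(sl["times"]);
    double tp = sy.tr * sy.td / (sy.td - sy.tr) * std::log(sy.td / sy.tr);
    sy.norm = 1.0 / (std::exp(-tp / sy.td) - std::exp(-tp / sy.tr));
    sy.A = 0.0; sy.B = 0.0; sy.next = 0;
    syns.push_back(sy);
  }

  // electrodes
  const int ic_comp = as<int>(iclamp["comp"]);
  NumericMatrix ic_steps = iclamp["steps"];
  const double ic_bias = as<double>(iclamp["bias"]);
  const bool vc_on = as<bool>(vclamp["enabled"]);
  const int vc_comp = as<int>(vclamp["comp"]);
  const double vc_g = as<double>(vclamp["gclamp_uS"]);
  NumericMatrix vc_steps = vclamp["steps"];
  const double vc_hold = as<double>(vclamp["holding"]);

  // recording
  const int nrec = record.size();
  NumericMatrix vout(nsteps + 1, nrec);
  NumericMatrix caout(record_ca ? nsteps + 1 : 1, record_ca ? nrec : 1);
  NumericVector iel(record_ielec ? nsteps + 1 : 1);
  NumericVector tout(nsteps + 1);
  for (int r = 0; r < nrec; ++r) vout(0, r) = v[record[r]];
  if (record_ca) for (int r = 0; r < nrec; ++r) caout(0, r) = ca[record[r]];

  std::vector<double> gtot(n), gE(n), iinj(n), diag(n), rhs(n);
  std::vector<double> ica(n);

  auto vc_cmd = [&](double t) {
    double cmd = vc_hold;
    for (int s = 0; s < vc_steps.nrow(); ++s)
      if (t >= vc_steps(s, 0) && t < vc_steps(s, 0) + vc_steps(s, 1))
        cmd = vc_steps(s, 2);
    return cmd;
  };
  if (record_ielec && vc_on) iel[0] = vc_g * (vc_cmd(0.0) - v[vc_comp]);

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double tm = t + 0.5 * dt;

    // 1. membrane conductances frozen at current states
    std::fill(gtot.begin(), gtot.end(), 0.0);
    std::fill(gE.begin(), gE.end(), 0.0);
    std::fill(iinj.begin(), iinj.end(), 0.0);
    for (size_t c = 0; c < chs.size(); ++c) {
      Channel& ch = chs[c];
      for (size_t j = 0; j < ch.comp.size(); ++j) {
        int i = ch.comp[j];
        double g = ch.gbar[j] * ch.open_frac(j, v[i], ca[i]);
        gtot[i] += g;
        gE[i] += g * ch.erev;
      }
    }

    // 2. synapses: advance to t+dt, deliver spikes in (t, t+dt]
    for (size_t s = 0; s < syns.size(); ++s) {
      Syn& sy = syns[s];
      sy.A *= std::exp(-dt / sy.tr);
      sy.B *= std::exp(-dt / sy.td);
      while (sy.next < sy.tt.size() && sy.tt[sy.next] <= t + dt) {
        double late = t + dt - sy.tt[sy.next];
        sy.A += sy.g * sy.norm * std::exp(-late / sy.tr);
        sy.B += sy.g * sy.norm * std::exp(-late / sy.td);
        sy.next++;
      }
      double g = sy.B - sy.A;
      if (g < 0) g = 0;
      gtot[sy.comp] += g;
      gE[sy.comp] += g * sy.e;
    }

    // 3. injected current
    if (ic_comp >= 0) {
      double amp = ic_bias;
      for (int s = 0; s < ic_steps.nrow(); ++s)
        if (tm >= ic_steps(s, 0) && tm < ic_steps(s, 0) + ic_steps(s, 1))
          amp += ic_steps(s, 2);
      iinj[ic_comp] += amp;
    }
    double cmd = 0.0;
    if (vc_on) {
      cmd = vc_cmd(tm);
      gtot[vc_comp] += vc_g;
      gE[vc_comp] += vc_g * cmd;
    }

    // 4. assemble theta-method system and Hines solve
    for (int i = 0; i < n; ++i) {
      diag[i] = c_nF[i] / dt + theta * gtot[i];
      rhs[i] = c_nF[i] / dt * v[i] + gE[i] + iinj[i]
             - (1.0 - theta) * gtot[i] * v[i];
      if (parent[i] >= 0) diag[i] += theta * g_ax[i];
    }
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      diag[p] += theta * g_ax[i];
      double ax = g_ax[i] * (v[i] - v[p]);
      rhs[i] += (1.0 - theta) * ax * -1.0;   // axial leaves i toward p
      rhs[p] += (1.0 - theta) * ax;
    }
    // elimination (children into parents; ordering guarantees parent < child)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double a = -theta * g_ax[i];
      double f = a / diag[i];
      diag[p] -= f * a;
      rhs[p] -= f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double a = -theta * g_ax[i];
      v[i] = (rhs[i] - a * v[parent[i]]) / diag[i];
    }
    if (!std::isfinite(v[0]))
      stop("simulation diverged at t = %f ms", t + dt);

    // 5. Ca-channel currents at new V, implicit shell update
    std::fill(ica.begin(), ica.end(), 0.0);
    bool any_ca = false;
    for (size_t c = 0; c < chs.size(); ++c) {
      Channel& ch = chs[c];
      if (!ch.is_ca) continue;
      any_ca = true;
      for (size_t j = 0; j < ch.comp.size(); ++j) {
        int i = ch.comp[j];
        ica[i] += ch.gbar[j] * ch.open_frac(j, v[i], ca[i]) *
                  (v[i] - ch.erev);
      }
    }
    if (any_ca) {
      for (int i = 0; i < n; ++i) {
        double vol = area_cm2[i] * 1e8 * ca_depth;   // um^3
        double infl = ica[i] < 0 ?
          (-ica[i]) * 1e9 / (2.0 * FARADAY * vol * ca_kappa) : 0.0;
        ca[i] = (ca[i] + dt * (infl + ca0 / ca_tau)) / (1.0 + dt / ca_tau);
        if (ca[i] < 0) ca[i] = 0;
      }
    }

    // 6. gate and Markov updates at new V / Ca (staggered)
    for (size_t c = 0; c < chs.size(); ++c) {
      Channel& ch = chs[c];
      if (ch.kind == 2) {
        for (size_t g = 0; g < ch.gates.size(); ++g) {
          const GateSpec& gs = ch.gates[g];
          double xi, ef;
          for (size_t j = 0; j < ch.comp.size(); ++j) {
            int i = ch.comp[j];
            gate_lookup(gs, v[i], ca[i], xi, ef);
            ch.gstate[g][j] = xi + (ch.gstate[g][j] - xi) * ef;
          }
        }
      } else if (ch.kind == 3) {
        for (size_t j = 0; j < ch.comp.size(); ++j)
          markov_be(ch.mk, ch.mstate[j], v[ch.comp[j]], ca[ch.comp[j]], dt);
      }
    }

    // 7. record
    tout[step + 1] = t + dt;
    for (int r = 0; r < nrec; ++r) vout(step + 1, r) = v[record[r]];
    if (record_ca)
      for (int r = 0; r < nrec; ++r) caout(step + 1, r) = ca[record[r]];
    if (record_ielec && vc_on)
      iel[step + 1] = vc_g * (vc_cmd(tm) - v[vc_comp]);
  }

  NumericVector vfin(v.begin(), v.end());
  NumericVector cafin(ca.begin(), ca.end());
  return List::create(_["t"] = tout, _["v"] = vout,
                      _["ca"] = record_ca ? (SEXP)caout : R_NilValue,
                      _["ielec"] = record_ielec ? (SEXP)iel : R_NilValue,
                      _["v_final"] = vfin, _["ca_final"] = cafin);
}
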