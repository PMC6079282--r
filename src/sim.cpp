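// Cable-equation integrator: implicit (backward-Euler) voltage update with
// channel conductances frozen within the step, solved on the compartment
// tree by Hines elimination; gating variables advanced by the exponential
// integrator; one single-exponential calcium pool per compartment.
//
// All units SI; calcium in mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GAS_R = 8.314462618;   // J/(mol K)
static const double FARADAY = 96485.33212; // C/mol

// (A + B*V)/(C + exp((V + D)/F)) with the removable-singularity guard
static inline double rate5(double A, double B, double C, double D, double F,
                           double V, bool guard = true) {
  double denom = C + std::exp((V + D) / F);
  if (guard && std::fabs(denom) < 1e-9) {
    return 0.5 * (rate5(A, B, C, D, F, V - 1e-5, false) +
                  rate5(A, B, C, D, F, V + 1e-5, false));
  }
  return (A + B * V) / denom;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(IntegerVector parent,        // 0-based, -1 for root
                 NumericVector Cm,            // F per compartment
                 NumericVector Gleak,         // S per compartment
                 double Eleak,
                 NumericVector Gax,           // S coupling to parent (root 0)
                 IntegerVector inst_comp,     // 0-based compartment of instance
                 NumericVector inst_gbar,     // S (density * area)
                 NumericVector inst_erev,     // V; NaN -> calcium Nernst
                 LogicalVector inst_ca,       // feeds the calcium pool?
                 IntegerVector ig_inst,       // instance index of each gate
                 IntegerVector ig_form,       // 0 alpha-beta, 1 tau-inf, 2 ca
                 IntegerVector ig_power,
                 NumericMatrix ig_fwd,        // columns A,B,C,D,F
                 NumericMatrix ig_bwd,
                 NumericVector ig_cahalf,
                 NumericVector ig_caslope,
                 NumericVector ig_taumin,
                 bool ca_enabled, double ca_tau, double ca_B,
                 double ca_base, double ca_out, double temperature,
                 double V_init, double dt, int rec_every, int n_steps,
                 int inj_comp, double inj_amp, double inj_on, double inj_off,
                 int rec_comp, bool record_all) {
  const int n = parent.size();
  const int ni = inst_comp.size();
  const int ng = ig_inst.size();

  std::vector<double> V(n, V_init), Ca(n, ca_base);
  std::vector<double> x(ng);

  // gate steady state / time constant
  auto gate_eq = [&](int g, double Vm, double ca, double &xinf, double &tau) {
    int f = ig_form[g];
    if (f == 0) {
      double a = rate5(ig_fwd(g, 0), ig_fwd(g, 1), ig_fwd(g, 2),
                       ig_fwd(g, 3), ig_fwd(g, 4), Vm);
      double b = rate5(ig_bwd(g, 0), ig_bwd(g, 1), ig_bwd(g, 2),
                       ig_bwd(g, 3), ig_bwd(g, 4), Vm);
      double s = a + b;
      if (s > 0) { xinf = a / s; tau = 1.0 / s; } else { xinf = 0.0; tau = 1e6; }
      if (tau < ig_taumin[g]) tau = ig_taumin[g];
    } else if (f == 1) {
      xinf = rate5(ig_fwd(g, 0), ig_fwd(g, 1), ig_fwd(g, 2),
                   ig_fwd(g, 3), ig_fwd(g, 4), Vm);
      tau = rate5(ig_bwd(g, 0), ig_bwd(g, 1), ig_bwd(g, 2),
                  ig_bwd(g, 3), ig_bwd(g, 4), Vm);
      if (tau < ig_taumin[g]) tau = ig_taumin[g];
    } else {
      double can = std::pow(ca, ig_caslope[g]);
      double hn = std::pow(ig_cahalf[g], ig_caslope[g]);
      xinf = can / (can + hn);
      tau = ig_taumin[g];
    }
  };

  for (int g = 0; g < ng; ++g) {
    double xinf, tau;
    gate_eq(g, V_init, ca_base, xinf, tau);
    x[g] = xinf;
  }

  // Voltage lookup tables for the voltage-dependent gates (forms 0 and 1):
  // steady state and per-step decay factor exp(-dt/tau) on a 0.1 mV grid
  // with linear interpolation, as in standard compartmental simulators.
  const double TAB_LO = -0.20, TAB_HI = 0.15, TAB_STEP = 1e-4;
  const int TAB_N = (int)std::lround((TAB_HI - TAB_LO) / TAB_STEP) + 1;
  std::vector<std::vector<double>> tab_xinf(ng), tab_decay(ng);
  for (int g = 0; g < ng; ++g) {
    if (ig_form[g] == 2) continue;
    tab_xinf[g].resize(TAB_N);
    tab_decay[g].resize(TAB_N);
    for (int j = 0; j < TAB_N; ++j) {
      double Vj = TAB_LO + j * TAB_STEP;
      double xinf, tau;
      gate_eq(g, Vj, ca_base, xinf, tau);
      tab_xinf[g][j] = xinf;
      tab_decay[g][j] = std::exp(-dt / tau);
    }
  }
  auto gate_lookup = [&](int g, double Vm, double &xinf, double &decay) {
    double u = (Vm - TAB_LO) / TAB_STEP;
    if (u <= 0) { xinf = tab_xinf[g][0]; decay = tab_decay[g][0]; return; }
    if (u >= TAB_N - 1) {
      xinf = tab_xinf[g][TAB_N - 1]; decay = tab_decay[g][TAB_N - 1]; return;
    }
    int j = (int)u;
    double w = u - j;
    xinf = tab_xinf[g][j] * (1 - w) + tab_xinf[g][j + 1] * w;
    decay = tab_decay[g][j] * (1 - w) + tab_decay[g][j + 1] * w;
  };

  // static diagonal contribution from the axial network
  std::vector<double> d_static(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (parent[i] >= 0) {
      d_static[i] += Gax[i];
      d_static[parent[i]] += Gax[i];
    }
  }

  // hot-loop copies of the input arrays (plain contiguous storage)
  std::vector<int> vparent(parent.begin(), parent.end());
  std::vector<double> vGleak(Gleak.begin(), Gleak.end());
  std::vector<double> vGax(Gax.begin(), Gax.end());
  std::vector<int> vinst_comp(inst_comp.begin(), inst_comp.end());
  std::vector<double> vinst_gbar(inst_gbar.begin(), inst_gbar.end());
  std::vector<double> vinst_erev(inst_erev.begin(), inst_erev.end());
  std::vector<int> vinst_ca(inst_ca.begin(), inst_ca.end());
  std::vector<int> vig_inst(ig_inst.begin(), ig_inst.end());
  std::vector<int> vig_form(ig_form.begin(), ig_form.end());
  std::vector<int> vig_power(ig_power.begin(), ig_power.end());
  std::vector<double> cmdt(n), gleakE(n);
  for (int i = 0; i < n; ++i) {
    cmdt[i] = Cm[i] / dt;
    gleakE[i] = vGleak[i] * Eleak;
  }

  const double rt2f = GAS_R * temperature / (2.0 * FARADAY);
  const int nrec = n_steps / rec_every + 1;
  NumericVector times(nrec), vm_out(nrec);
  NumericMatrix vm_all(record_all ? n : 1, record_all ? nrec : 1);
  NumericVector ca_out_v(nrec);
  int irec = 0;
  times[0] = 0.0; vm_out[0] = V[rec_comp]; ca_out_v[0] = Ca[rec_comp];
  if (record_all) for (int i = 0; i < n; ++i) vm_all(i, 0) = V[i];
  irec = 1;

  std::vector<double> G(n), GE(n), d(n), b(n);
  std::vector<double> inst_g(ni), inst_e(ni);
  const double cadecay = std::exp(-dt / ca_tau);
  const double eps_ca = 1e-12;

  const int inj_step0 = (int)std::ceil(inj_on / dt - 1e-9);
  const int inj_step1 = (int)std::ceil(inj_off / dt - 1e-9); // exclusive

  for (int step = 0; step < n_steps; ++step) {
    // channel conductances at current gate states
    for (int i = 0; i < n; ++i) { G[i] = vGleak[i]; GE[i] = gleakE[i]; }
    for (int k = 0; k < ni; ++k) inst_g[k] = vinst_gbar[k];
    for (int g = 0; g < ng; ++g) {
      int k = vig_inst[g];
      double xv = x[g];
      int p = vig_power[g];
      double xp = 1.0;
      for (int q = 0; q < p; ++q) xp *= xv;
      inst_g[k] *= xp;
    }
    for (int k = 0; k < ni; ++k) {
      int c = vinst_comp[k];
      double E = vinst_erev[k];
      if (ISNAN(E)) { // calcium Nernst
        double cai = Ca[c] > eps_ca ? Ca[c] : eps_ca;
        E = rt2f * std::log(ca_out / cai);
      }
      inst_e[k] = E;
      G[c] += inst_g[k];
      GE[c] += inst_g[k] * E;
    }
    // implicit voltage step on the tree
    for (int i = 0; i < n; ++i) {
      d[i] = cmdt[i] + G[i] + d_static[i];
      b[i] = cmdt[i] * V[i] + GE[i];
    }
    if (inj_amp != 0.0 && step >= inj_step0 && step < inj_step1)
      b[inj_comp] += inj_amp;
    for (int i = n - 1; i >= 1; --i) {
      double f = vGax[i] / d[i];
      d[vparent[i]] -= vGax[i] * f;
      b[vparent[i]] += b[i] * f;
    }
    V[0] = b[0] / d[0];
    for (int i = 1; i < n; ++i) V[i] = (b[i] + vGax[i] * V[vparent[i]]) / d[i];

    // gates: exponential update at the new voltage, previous-step calcium
    for (int g = 0; g < ng; ++g) {
      int c = vinst_comp[vig_inst[g]];
      double xinf, decay;
      if (vig_form[g] == 2) {
        double tau;
        gate_eq(g, V[c], Ca[c], xinf, tau);
        decay = std::exp(-dt / tau);
      } else {
        gate_lookup(g, V[c], xinf, decay);
      }
      x[g] = xinf + (x[g] - xinf) * decay;
      if (x[g] < 0.0) x[g] = 0.0;
      if (x[g] > 1.0) x[g] = 1.0;
    }
    // calcium pool: exact exponential update toward the current-dependent
    // fixed point; inward (negative) calcium current raises [Ca]
    if (ca_enabled) {
      for (int k = 0; k < ni; ++k) {
        if (!vinst_ca[k]) continue;
        int c = vinst_comp[k];
        double ica = inst_g[k] * (V[c] - inst_e[k]);
        double ca_inf = ca_base - ca_tau * ca_B * ica;
        Ca[c] = ca_inf + (Ca[c] - ca_inf) * cadecay;
        if (Ca[c] < 0.0) Ca[c] = 0.0;
      }
    }

    if ((step + 1) % rec_every == 0) {
      if (!R_finite(V[rec_comp]))
        stop("simulation diverged (non-finite voltage) at step %d", step + 1);
      times[irec] = (step + 1) * dt;
      vm_out[irec] = V[rec_comp];
      ca_out_v[irec] = Ca[rec_comp];
      if (record_all) for (int i = 0; i < n; ++i) vm_all(i, irec) = V[i];
      ++irec;
    }
    if ((step & 1023) == 0 && !R_finite(V[0]))
      stop("simulation diverged (non-finite voltage) at step %d", step + 1);
  }

  List out = List::create(_["times"] = times, _["Vm"] = vm_out,
                          _["Ca"] = ca_out_v);
  if (record_all) out["Vm_all"] = vm_all;
  return out;
}
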