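#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Fixed-step network integrator for the tripartite-synapse model.
//
// Update order within a step (cross-step ordering matters at O(dt)):
//   bath stimulus -> astrocytes (IP3, Ca, gliotransmitter release) ->
//   presynaptic modulation + transmitter pools -> receptor gating ->
//   currents -> membranes -> spike processing (TM jumps on efferents).
//
// Units: time s, voltage mV, conductance nS, current pA, concentration uM.
// Currents follow the inward-negative convention of the receptor equations
// and are negated when injected into the membrane equation.
//
// Structure exploited for speed (all exact, not approximations):
//  - r_gabab is driven by the global bath only -> one scalar ODE;
//  - Gamma and the extrasynaptic receptor pools are driven by the territory
//    astrocyte's G_A only -> per astrocyte, not per synapse;
//  - the TM variables u_S, x_S relax linearly between spikes -> evaluated
//    lazily at spike events from the elapsed time;
//  - every excitatory cleft pool shares one clearance factor -> per-astro
//    glutamate sums are updated incrementally (decay + jump), not re-summed;
//  - until the first gliotransmitter release G_A, Gamma and the
//    extrasynaptic open fractions are identically zero -> those loops are
//    skipped while no release has happened.

static inline double getd(const List& p, const char* name) {
  return as<double>(p[name]);
}
static inline double cube(double x) { return x * x * x; }

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(List cfg) {
  // --- scalars -------------------------------------------------------------
  const double dt = getd(cfg, "dt");                 // s
  const int n_steps = as<int>(cfg["n_steps"]);
  const int stride = as<int>(cfg["record_stride"]);
  const bool astro_on = as<bool>(cfg["astrocyte_enabled"]);
  const bool epsc_on = as<bool>(cfg["epsc_drive"]);
  const bool kinetic = as<bool>(cfg["kinetic_mode"]);

  // neuron parameters (converted to s where needed)
  const List np = cfg["neuron"];
  const double tau_m = getd(np, "tau_m") * 1e-3;
  const double v_rest = getd(np, "v_rest"), v_th = getd(np, "v_th");
  const double v_e = getd(np, "v_e"), v_i = getd(np, "v_i");
  const double g_leak = getd(np, "g_leak"), I_ex = getd(np, "I_ex");
  const double tau_ref = getd(np, "tau_ref") * 1e-3;
  const double f_ge = std::exp(-dt / (getd(np, "tau_e") * 1e-3));
  const double f_gi = std::exp(-dt / (getd(np, "tau_i") * 1e-3));

  // synapse parameters
  const List sp = cfg["synapse"];
  const double U0 = getd(sp, "U0"), xi = getd(sp, "xi");
  const double O_G = getd(sp, "O_G_uM");             // uM^-1 s^-1
  const double Omega_G = getd(sp, "Omega_G");
  const double a_gb = getd(sp, "alpha_gabab"), b_gb = getd(sp, "beta_gabab");
  const double tau_fac = getd(sp, "tau_fac"), tau_rec = getd(sp, "tau_rec");
  const double f_GS = std::exp(-getd(sp, "g_S_c") * dt);
  const double f_GABAS = std::exp(-getd(sp, "g_gaba_uptake") * dt);
  const double jumpY = getd(sp, "rho_c") * getd(sp, "Y_T") * 1000.0; // uM
  const double U_inh = getd(sp, "U_inh");

  // receptor parameters
  const List rp = cfg["receptor"];
  const double aA = getd(rp, "ampa_alpha"), bA = getd(rp, "ampa_beta");
  const double gA = getd(rp, "ampa_gmax"), eA = getd(rp, "ampa_erev");
  const double aN = getd(rp, "nmda_alpha"), bN = getd(rp, "nmda_beta");
  const double gN = getd(rp, "nmda_gmax"), eN = getd(rp, "nmda_erev");
  const double aG = getd(rp, "gabaa_alpha"), bG = getd(rp, "gabaa_beta");
  const double gG = getd(rp, "gabaa_gmax") * getd(rp, "gabaa_scale");
  const double eG = getd(rp, "gabaa_erev");
  const double Mg = getd(rp, "Mg_conc");

  // astrocyte parameters
  const List ap = cfg["astro"];
  const double ip3_star = getd(ap, "ip3_star"), tau_ip3 = getd(ap, "tau_ip3");
  const double v_gaba = getd(ap, "v_gaba"), v_glu = getd(ap, "v_glu");
  const double n1 = getd(ap, "n1"), n2 = getd(ap, "n2");
  const double k_gaba = getd(ap, "k_gaba"), k_glu = getd(ap, "k_glu");
  const double k_amp = getd(ap, "k_amp");
  const double ip3_thr = getd(ap, "ip3_thr"), F_ex = getd(ap, "F_ex");
  const double omega = getd(ap, "omega"), C_theta = getd(ap, "C_theta");
  const double f_xA = std::exp(-dt / getd(ap, "tau_G"));
  const double U_A = getd(ap, "U_A");
  const double glioY = getd(ap, "rho_e") * getd(ap, "G_T") * 1000.0; // uM
  const double f_GA = std::exp(-getd(ap, "g_A_c") * dt);
  const bool amp_ip3 = as<bool>(ap["amp_on_ip3"]);
  const bool amp_rel = as<bool>(ap["amp_on_release"]);
  const bool glu_mean = as<bool>(ap["glu_driver_mean"]);
  // Li-Rinzel constants
  const double c0 = getd(ap, "c0"), c1 = getd(ap, "c1");
  const double v1 = getd(ap, "v1"), v2 = getd(ap, "v2");
  const double v3 = getd(ap, "v3"), k3 = getd(ap, "k3");
  const double d1 = getd(ap, "d1"), d2 = getd(ap, "d2");
  const double d3 = getd(ap, "d3"), d5 = getd(ap, "d5");
  const double a2 = getd(ap, "a2");

  // bath protocol
  const List pr = cfg["protocol"];
  const double dose = getd(pr, "dose"), t_on = getd(pr, "t_on");
  const double t_off = t_on + getd(pr, "duration");
  const double clr = getd(pr, "clearance");

  // --- topology ------------------------------------------------------------
  const IntegerVector is_exc_neu = cfg["is_exc"];
  const int n_neu = is_exc_neu.size();
  const IntegerVector syn_pre = cfg["syn_pre"], syn_post = cfg["syn_post"];
  const IntegerVector syn_exc = cfg["syn_exc"], syn_astro = cfg["syn_astro"];
  const int n_syn = syn_pre.size();
  const IntegerVector eff_ptr = cfg["eff_ptr"], eff_idx = cfg["eff_idx"];
  const IntegerVector nb_ptr = cfg["astro_nb_ptr"],
    nb_idx = cfg["astro_nb_idx"];
  const int n_astro = nb_ptr.size() > 0 ? nb_ptr.size() - 1 : 0;
  const IntegerVector pool_astro = cfg["pool_astro"],
    pool_neuron = cfg["pool_neuron"];
  const int n_pool = pool_astro.size();
  const IntegerVector rec_neu = cfg["rec_neurons"],
    rec_syn = cfg["rec_synapses"], rec_ast = cfg["rec_astros"];

  std::vector<int> exc_idx, inh_idx;
  for (int s = 0; s < n_syn; ++s) {
    if (syn_exc[s]) exc_idx.push_back(s); else inh_idx.push_back(s);
  }
  const int n_exc_syn = exc_idx.size(), n_inh_syn = inh_idx.size();

  // --- state ---------------------------------------------------------------
  NumericVector v0 = cfg["v_init"];
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> g_e(n_neu, 0.0), g_i(n_neu, 0.0), refr(n_neu, 0.0);
  // TM variables stored at their last event time (lazy relaxation)
  std::vector<double> u_S(n_syn, 0.0), x_S(n_syn, 1.0);
  std::vector<double> tm_t(n_syn, 0.0);  // time of last TM evaluation
  std::vector<double> G_S(n_syn, 0.0);
  std::vector<double> r_ampa(n_syn, 0.0), r_nmda(n_syn, 0.0),
    r_gabaa(n_syn, 0.0);
  double r_gabab = 0.0;
  std::vector<double> ip3(n_astro, ip3_star), ca(n_astro, 0.1),
    h(n_astro, 0.0), x_A(n_astro, 1.0), G_A(n_astro, 0.0);
  std::vector<int> latch(n_astro, 0);
  std::vector<double> Gamma(n_astro, 0.0), U_a(n_astro, U0);
  std::vector<double> re_ampa(n_astro, 0.0), re_nmda(n_astro, 0.0);
  {
    const double Q2 = d2 * (ip3_star + d1) / (ip3_star + d3);
    for (int a = 0; a < n_astro; ++a) h[a] = Q2 / (Q2 + ca[a]);
  }
  std::vector<double> astro_syn_n(n_astro, 0.0);
  for (int s = 0; s < n_syn; ++s)
    if (syn_astro[s] >= 0) astro_syn_n[syn_astro[s]] += 1.0;
  std::vector<double> glu_sum(n_astro, 0.0);   // sum of G_S per territory
  double total_GS_exc = 0.0;

  double U_glob = U0;
  bool glio_seen = false;   // before the first release the glial pathway is 0

  // lazily relaxed TM values at time `now`
  auto tm_now = [&](int s, double now, double& u, double& x) {
    const double el = now - tm_t[s];
    u = u_S[s] * std::exp(-el / tau_fac);
    x = 1.0 - (1.0 - x_S[s]) * std::exp(-el / tau_rec);
  };

  // --- output buffers ------------------------------------------------------
  std::vector<int> spk_id; std::vector<double> spk_t;
  spk_id.reserve(1 << 16); spk_t.reserve(1 << 16);
  std::vector<double> rel_sum(n_syn, 0.0); std::vector<int> rel_n(n_syn, 0);
  std::vector<int> rev_syn; std::vector<double> rev_t, rev_r;
  std::vector<int> gev_ast; std::vector<double> gev_t, gev_r, gev_dG;
  std::vector<int> is_rec_syn(n_syn, 0);
  for (int k = 0; k < rec_syn.size(); ++k) is_rec_syn[rec_syn[k]] = 1;

  const int n_samp = n_steps / stride + 1;
  NumericVector tr_time(n_samp), tr_gaba(n_samp), tr_rgabab(n_samp);
  NumericVector m_ca(n_samp), m_ip3(n_samp), m_GA(n_samp), m_GS(n_samp),
    m_U(n_samp), m_sic(n_samp);
  NumericMatrix nv_tr(n_samp, rec_neu.size()),
    nsic_tr(n_samp, rec_neu.size()), nepsc_tr(n_samp, rec_neu.size());
  NumericMatrix a_ip3(n_samp, rec_ast.size()), a_ca(n_samp, rec_ast.size()),
    a_h(n_samp, rec_ast.size()), a_xA(n_samp, rec_ast.size()),
    a_GA(n_samp, rec_ast.size());
  NumericMatrix s_u(n_samp, rec_syn.size()), s_x(n_samp, rec_syn.size()),
    s_U(n_samp, rec_syn.size()), s_Gam(n_samp, rec_syn.size()),
    s_GS(n_samp, rec_syn.size());

  std::vector<double> I_in(n_neu, 0.0);   // depolarizing-positive injection
  std::vector<double> sic_neu(n_neu, 0.0), epsc_neu(n_neu, 0.0);
  std::vector<double> mg_neu(n_neu, 0.0);

  double gaba = 0.0;
  double mean_sic_now = 0.0;

  auto sample = [&](int k, double t) {
    tr_time[k] = t; tr_gaba[k] = gaba; tr_rgabab[k] = r_gabab;
    double sca = 0, sip = 0, sga = 0, sU = 0;
    for (int a = 0; a < n_astro; ++a) {
      sca += ca[a]; sip += ip3[a]; sga += G_A[a];
      sU += glio_seen ? U_a[a] : U_glob;
    }
    if (n_astro > 0) {
      m_ca[k] = sca / n_astro; m_ip3[k] = sip / n_astro;
      m_GA[k] = sga / n_astro; m_U[k] = sU / n_astro;
    }
    m_GS[k] = n_exc_syn > 0 ? total_GS_exc / n_exc_syn : 0.0;
    m_sic[k] = mean_sic_now;
    for (int j = 0; j < rec_neu.size(); ++j) {
      int i = rec_neu[j];
      nv_tr(k, j) = v[i]; nsic_tr(k, j) = sic_neu[i];
      nepsc_tr(k, j) = epsc_neu[i];
    }
    for (int j = 0; j < rec_ast.size(); ++j) {
      int a = rec_ast[j];
      a_ip3(k, j) = ip3[a]; a_ca(k, j) = ca[a]; a_h(k, j) = h[a];
      a_xA(k, j) = x_A[a]; a_GA(k, j) = G_A[a];
    }
    for (int j = 0; j < rec_syn.size(); ++j) {
      int s = rec_syn[j];
      double u, x; tm_now(s, t, u, x);
      s_u(k, j) = u; s_x(k, j) = x;
      int a = syn_astro[s];
      s_U(k, j) = (astro_on && glio_seen && a >= 0) ? U_a[a] : U_glob;
      s_Gam(k, j) = (astro_on && glio_seen && a >= 0) ? Gamma[a] : 0.0;
      s_GS(k, j) = G_S[s];
    }
  };
  {
    gaba = (t_on <= 0.0) ? dose : 0.0;
    sample(0, 0.0);
  }

  std::vector<double> ip3_prev(n_astro, 0.0);

  for (int n = 0; n < n_steps; ++n) {
    const double t = n * dt, t_next = (n + 1) * dt;

    // 1. bath stimulus
    if (t < t_on) gaba = 0.0;
    else if (t <= t_off) gaba = dose;
    else gaba = dose * std::exp(-clr * (t - t_off));
    const double amp_fac = 1.0 + k_amp * gaba;

    // 2. astrocytes
    if (astro_on && n_astro > 0) {
      std::copy(ip3.begin(), ip3.end(), ip3_prev.begin());
      const double J_gaba = (gaba > 0.0)
        ? v_gaba * std::pow(gaba, n1) /
          (std::pow(k_gaba, n1) + std::pow(gaba, n1))
        : 0.0;
      for (int a = 0; a < n_astro; ++a) {
        double glu = glu_sum[a];
        if (glu_mean && astro_syn_n[a] > 0) glu /= astro_syn_n[a];
        double J_glu = (glu > 0.0)
          ? v_glu * std::pow(glu, n2) /
            (std::pow(k_glu, n2) + std::pow(glu, n2))
          : 0.0;
        if (amp_ip3) J_glu *= amp_fac;
        double J_G = 0.0;
        for (int q = nb_ptr[a]; q < nb_ptr[a + 1]; ++q) {
          const double delta = ip3_prev[a] - ip3_prev[nb_idx[q]];
          if (delta != 0.0) {
            const double mag = (F_ex / 2.0) *
              (1.0 + std::tanh((std::fabs(delta) - ip3_thr) / omega));
            J_G -= (delta > 0 ? mag : -mag);
          }
        }
        ip3[a] += dt * ((ip3_star - ip3[a]) / tau_ip3 + J_gaba + J_glu + J_G);
        if (ip3[a] < 0) ip3[a] = 0;

        // Li-Rinzel (gating read at the pre-update IP3)
        const double m_inf = ip3_prev[a] / (ip3_prev[a] + d1);
        const double n_inf = ca[a] / (ca[a] + d5);
        const double gate = cube(m_inf * n_inf * h[a]);
        const double drive = c0 - (1.0 + c1) * ca[a];
        const double dca = v1 * gate * drive + v2 * drive -
          v3 * ca[a] * ca[a] / (k3 * k3 + ca[a] * ca[a]);
        const double Q2 = d2 * (ip3_prev[a] + d1) / (ip3_prev[a] + d3);
        const double dh = a2 * (Q2 * (1.0 - h[a]) - ca[a] * h[a]);
        ca[a] += dt * dca; if (ca[a] < 0) ca[a] = 0;
        h[a] += dt * dh;
        if (h[a] < 0) h[a] = 0; else if (h[a] > 1) h[a] = 1;

        // recovery / clearance, then the threshold-latch release rule
        x_A[a] = 1.0 - (1.0 - x_A[a]) * f_xA;
        G_A[a] *= f_GA;
        if (ca[a] >= C_theta) {
          if (!latch[a]) {
            latch[a] = 1;
            const double r_A = U_A * x_A[a];
            x_A[a] -= r_A;
            const double dG = r_A * glioY * (amp_rel ? amp_fac : 1.0);
            G_A[a] += dG;
            glio_seen = true;
            gev_ast.push_back(a); gev_t.push_back(t_next);
            gev_r.push_back(r_A); gev_dG.push_back(dG);
          }
        } else {
          latch[a] = 0;
        }
      }
    }

    // 3. presynaptic modulation (per astrocyte group + global GABA-B scalar)
    r_gabab += dt * (a_gb * gaba * (1.0 - r_gabab) - b_gb * r_gabab);
    if (r_gabab < 0) r_gabab = 0; else if (r_gabab > 1) r_gabab = 1;
    {
      double U = U0 - U0 * r_gabab;
      U_glob = U < 0 ? 0 : (U > 1 ? 1 : U);
    }
    if (astro_on && glio_seen) {
      for (int a = 0; a < n_astro; ++a) {
        Gamma[a] += dt * (O_G * G_A[a] * (1.0 - Gamma[a]) -
                          Omega_G * Gamma[a]);
        double U = U0 + (xi - U0) * Gamma[a] - U0 * r_gabab;
        U_a[a] = U < 0 ? 0 : (U > 1 ? 1 : U);
      }
      // extrasynaptic (G_A-driven) receptor pools
      for (int a = 0; a < n_astro; ++a) {
        re_ampa[a] += dt * (aA * G_A[a] * (1.0 - re_ampa[a]) -
                            bA * re_ampa[a]);
        re_nmda[a] += dt * (aN * G_A[a] * (1.0 - re_nmda[a]) -
                            bN * re_nmda[a]);
      }
    }

    // per-neuron magnesium factor; reset per-step current accumulators
    for (int i = 0; i < n_neu; ++i) {
      mg_neu[i] = 1.0 / (1.0 + std::exp(-0.062 * v[i]) * Mg / 3.57);
      I_in[i] = 0.0; sic_neu[i] = 0.0; epsc_neu[i] = 0.0;
    }

    // 4. transmitter decay + receptor gating (branch-free inner loops)
    for (int q = 0; q < n_exc_syn; ++q) {
      const int s = exc_idx[q];
      const double gs = G_S[s] * f_GS;
      G_S[s] = gs;
      r_ampa[s] += dt * (aA * gs * (1.0 - r_ampa[s]) - bA * r_ampa[s]);
      r_nmda[s] += dt * (aN * gs * (1.0 - r_nmda[s]) - bN * r_nmda[s]);
    }
    for (int a = 0; a < n_astro; ++a) glu_sum[a] *= f_GS;
    total_GS_exc *= f_GS;
    for (int q = 0; q < n_inh_syn; ++q) {
      const int s = inh_idx[q];
      const double gs = G_S[s] * f_GABAS;
      G_S[s] = gs;
      const double T = gs + gaba;
      r_gabaa[s] += dt * (aG * T * (1.0 - r_gabaa[s]) - bG * r_gabaa[s]);
    }

    // 5. currents
    if (kinetic) {
      for (int q = 0; q < n_exc_syn; ++q) {
        const int s = exc_idx[q];
        const int j = syn_post[s];
        const double I = gA * r_ampa[s] * (v[j] - eA) +
          gN * mg_neu[j] * r_nmda[s] * (v[j] - eN);
        if (epsc_on) I_in[j] -= I;   // recorded even when not delivered
        epsc_neu[j] += I;
      }
      for (int q = 0; q < n_inh_syn; ++q) {
        const int s = inh_idx[q];
        const int j = syn_post[s];
        I_in[j] -= gG * r_gabaa[s] * (v[j] - eG);
      }
    }
    if (astro_on && glio_seen) {    // slow inward currents, both modes
      for (int q = 0; q < n_pool; ++q) {
        const int a = pool_astro[q], j = pool_neuron[q];
        const double I = gA * re_ampa[a] * (v[j] - eA) +
          gN * mg_neu[j] * re_nmda[a] * (v[j] - eN);
        I_in[j] -= I;
        sic_neu[j] += I;
      }
      double s = 0;
      for (int i = 0; i < n_neu; ++i) s += sic_neu[i];
      mean_sic_now = n_neu > 0 ? s / n_neu : 0.0;
    } else {
      mean_sic_now = 0.0;
    }

    // 6. membranes
    for (int i = 0; i < n_neu; ++i) {
      if (refr[i] > 0.0) {
        v[i] = v_rest;
        refr[i] -= dt;
        // snap sub-half-step float residue so the refractory window always
        // spans the same whole number of steps (matches membrane_step)
        if (refr[i] < 0.5 * dt) refr[i] = 0;
      } else {
        const double drive = (v_rest - v[i]) +
          (g_e[i] * (v_e - v[i]) + g_i[i] * (v_i - v[i]) +
           I_ex + I_in[i]) / g_leak;
        v[i] += dt * drive / tau_m;
        if (!std::isfinite(v[i]))
          stop("membrane potential diverged (neuron %d, t = %g s)",
               i + 1, t_next);
      }
      g_e[i] *= f_ge;
      g_i[i] *= f_gi;
    }

    // 7. spikes + TM release on efferent synapses
    for (int i = 0; i < n_neu; ++i) {
      if (refr[i] > 0.0 || v[i] < v_th) continue;
      spk_id.push_back(i); spk_t.push_back(t_next);
      v[i] = v_rest; refr[i] = tau_ref;
      for (int q = eff_ptr[i]; q < eff_ptr[i + 1]; ++q) {
        const int s = eff_idx[q];
        const int a = syn_astro[s];
        const double U = syn_exc[s]
          ? ((astro_on && glio_seen && a >= 0) ? U_a[a] : U_glob) : U_inh;
        double u, x; tm_now(s, t_next, u, x);
        u += U * (1.0 - u);
        const double r_S = u * x;
        x -= r_S;
        u_S[s] = u; x_S[s] = x; tm_t[s] = t_next;
        G_S[s] += r_S * jumpY;
        if (a >= 0) glu_sum[a] += r_S * jumpY;
        if (syn_exc[s]) total_GS_exc += r_S * jumpY;
        rel_sum[s] += r_S; rel_n[s] += 1;
        if (is_rec_syn[s]) {
          rev_syn.push_back(s); rev_t.push_back(t_next); rev_r.push_back(r_S);
        }
        if (!kinetic) {
          const int j = syn_post[s];
          if (syn_exc[s]) {
            if (epsc_on) g_e[j] += gA * r_ampa[s] + gN * r_nmda[s];
          } else {
            g_i[j] += gG * r_gabaa[s];
          }
        }
      }
    }

    if ((n + 1) % stride == 0) sample((n + 1) / stride, t_next);
  }

  return List::create(
    _["spike_id"] = wrap(spk_id), _["spike_time"] = wrap(spk_t),
    _["trace_time"] = tr_time, _["gaba"] = tr_gaba,
    _["r_gabab"] = tr_rgabab,
    _["mean_ca"] = m_ca, _["mean_ip3"] = m_ip3, _["mean_GA"] = m_GA,
    _["mean_GS"] = m_GS, _["mean_U"] = m_U, _["mean_sic"] = m_sic,
    _["neuron_v"] = nv_tr, _["neuron_sic"] = nsic_tr,
    _["neuron_epsc"] = nepsc_tr,
    _["astro_ip3"] = a_ip3, _["astro_ca"] = a_ca, _["astro_h"] = a_h,
    _["astro_xA"] = a_xA, _["astro_GA"] = a_GA,
    _["syn_u"] = s_u, _["syn_x"] = s_x, _["syn_U"] = s_U,
    _["syn_Gamma"] = s_Gam, _["syn_GS"] = s_GS,
    _["rel_sum"] = wrap(rel_sum), _["rel_n"] = wrap(rel_n),
    _["release_syn"] = wrap(rev_syn), _["release_time"] = wrap(rev_t),
    _["release_rS"] = wrap(rev_r),
    _["glio_astro"] = wrap(gev_ast), _["glio_time"] = wrap(gev_t),
    _["glio_rA"] = wrap(gev_r), _["glio_dGA"] = wrap(gev_dG));
}
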