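// Fixed-step implicit compartmental integrator.
//
// Scheme: backward Euler on the branched cable for axial + ohmic membrane
// currents (Hines elimination over a parent-ordered tree), exponential Euler
// for gating variables and calcium shells, explicit treatment of GHK currents
// (CaT, AMPA, NMDA) evaluated at the previous voltage. Gating steady states
// and time constants arrive as voltage lookup tables built in R from the
// channel configuration; time constants are converted once per run into
// per-step decay factors exp(-dt/tau).
//
// Units: v mV, t ms, conductance densities mS/cm2, currents uA/cm2,
// Cm uF/cm2, permeabilities cm/s, concentrations mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double FARADAY = 96485.332;
const double GASCONST = 8.314462;
const double TEMP_K = 307.15;

struct Table {
  std::vector<double> inf, edt, tau;
  double vmin, dv;
  int n;
  inline double look(const std::vector<double>& y, double v) const {
    double u = (v - vmin) / dv;
    if (u <= 0.0) return y[0];
    if (u >= n - 1) return y[n - 1];
    int i = (int)u;
    double f = u - i;
    return y[i] * (1.0 - f) + y[i + 1] * f;
  }
  inline double get_inf(double v) const { return look(inf, v); }
  inline double get_edt(double v) const { return look(edt, v); }
  inline double get_tau(double v) const { return look(tau, v); }
  // advance a gate by one step with a single index computation
  inline double upd(double x, double v) const {
    double u = (v - vmin) / dv;
    if (u <= 0.0) u = 0.0;
    if (u >= n - 1) u = n - 1 - 1e-9;
    int i = (int)u;
    double f = u - i;
    double xi = inf[i] * (1.0 - f) + inf[i + 1] * f;
    double e = edt[i] * (1.0 - f) + edt[i + 1] * f;
    return xi + (x - xi) * e;
  }
};

Table make_table(List tl, double dt) {
  Table t;
  t.vmin = as<double>(tl["vmin"]);
  t.dv = as<double>(tl["dv"]);
  NumericVector inf = tl["inf"], tau = tl["tau"];
  t.n = inf.size();
  t.inf.assign(inf.begin(), inf.end());
  t.tau.assign(tau.begin(), tau.end());
  t.edt.resize(t.n);
  for (int i = 0; i < t.n; ++i) t.edt[i] = std::exp(-dt / t.tau[i]);
  return t;
}

// GHK constant-field current for unit permeability (1 cm/s), in uA/cm2.
inline double ghk_drive(double v, double z, double ci_mM, double co_mM) {
  double xi = z * v * 1e-3 * FARADAY / (GASCONST * TEMP_K);
  double ci = ci_mM * 1e-6, co = co_mM * 1e-6;  // mol/cm3
  double f;
  if (std::fabs(xi) < 1e-5) {
    f = (ci - co) + xi * (ci + co) / 2.0;
  } else {
    f = xi * (ci - co * std::exp(-xi)) / (1.0 - std::exp(-xi));
  }
  return z * FARADAY * f * 1e6;
}

inline double mgblock(double v, double mg_o) {
  return 1.0 / (1.0 + mg_o * std::exp(-0.062 * v) / 3.57);
}

}  // namespace

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(List model, List syn, List stim, List plast, List rec,
                List tables, List pars) {
  // ---- model geometry / densities ----
  IntegerVector parent = model["parent"];
  NumericVector area = model["area"];
  NumericVector cmv = model["cm"];
  NumericVector gpas = model["gpas"];
  NumericVector gax_self = model["gax_self"];
  NumericVector gax_par = model["gax_par"];
  NumericVector gna = model["gna"];
  NumericVector gkdr = model["gkdr"];
  NumericVector gka = model["gka"];
  IntegerVector kadist = model["ka_dist"];
  NumericVector gh = model["gh"];
  NumericVector hvhalf = model["hvhalf"];
  NumericVector pcat = model["pcat"];
  IntegerVector dend = model["dend"];
  const int n = parent.size();

  const double dt = as<double>(model["dt"]);
  const double duration = as<double>(model["duration"]);
  const double settle = as<double>(model["settle"]);
  const double v_init = as<double>(model["v_init"]);

  const double ena = as<double>(pars["e_na"]);
  const double ek = as<double>(pars["e_k"]);
  const double eh = as<double>(pars["e_h"]);
  const double na_o = as<double>(pars["na_o"]), na_i = as<double>(pars["na_i"]);
  const double k_o = as<double>(pars["k_o"]), k_i = as<double>(pars["k_i"]);
  const double ca_o = as<double>(pars["ca_o"]);
  const double mg_o = as<double>(pars["mg_o"]);
  const double ca_inf = as<double>(pars["ca_inf"]);
  const double tau_ca = as<double>(pars["tau_ca"]);
  const double ca_depth = as<double>(pars["ca_depth"]);
  // shell influx factor per Eq of the calcium model: -1e4 * i[mA/cm2]/(3.6*dpt*F)
  const double shell_fac = 1e4 / (3.6 * ca_depth * FARADAY);
  const double tau_r_ampa = as<double>(pars["tau_r_ampa"]);
  const double tau_d_ampa = as<double>(pars["tau_d_ampa"]);
  const double tau_r_nmda = as<double>(pars["tau_r_nmda"]);
  const double tau_d_nmda = as<double>(pars["tau_d_nmda"]);
  const double pca_ratio = as<double>(pars["nmda_pca"]);

  // double-exponential normalization so a single event peaks at 1
  auto norm_a = [](double tr, double td) {
    double tp = std::log(td / tr) * tr * td / (td - tr);
    return 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  };
  const double a_ampa = norm_a(tau_r_ampa, tau_d_ampa);
  const double a_nmda = norm_a(tau_r_nmda, tau_d_nmda);

  // GHK drive lookup for the fixed-concentration monovalent ions
  const double gv_min = -200.0, gv_dv = 0.05;
  const int gv_n = (int)((200.0 - gv_min) / gv_dv) + 1;
  std::vector<double> tab_dna(gv_n), tab_dk(gv_n);
  for (int i = 0; i < gv_n; ++i) {
    double vv = gv_min + i * gv_dv;
    tab_dna[i] = ghk_drive(vv, 1.0, na_i, na_o);
    tab_dk[i] = ghk_drive(vv, 1.0, k_i, k_o);
  }
  auto drive_nak = [&](double vv) {
    double u = (vv - gv_min) / gv_dv;
    if (u <= 0.0) u = 0.0;
    if (u >= gv_n - 1) u = gv_n - 1 - 1e-9;
    int i = (int)u;
    double f = u - i;
    return (tab_dna[i] * (1.0 - f) + tab_dna[i + 1] * f)
         + (tab_dk[i] * (1.0 - f) + tab_dk[i + 1] * f);
  };
  const double ed_ampa = std::exp(-dt / tau_d_ampa), er_ampa = std::exp(-dt / tau_r_ampa);
  const double ed_nmda = std::exp(-dt / tau_d_nmda), er_nmda = std::exp(-dt / tau_r_nmda);

  // ---- gating tables ----
  Table t_na_m = make_table(tables["na_m"], dt);
  Table t_na_h = make_table(tables["na_h"], dt);
  Table t_na_s = make_table(tables["na_s"], dt);
  Table t_kdr_n = make_table(tables["kdr_n"], dt);
  Table t_kap_n = make_table(tables["kap_n"], dt);
  Table t_kap_l = make_table(tables["kap_l"], dt);
  Table t_kad_n = make_table(tables["kad_n"], dt);
  Table t_kad_l = make_table(tables["kad_l"], dt);
  Table t_hd_l = make_table(tables["hd_l"], dt);   // inf over arg = v - vhalf
  Table t_hd_tau = make_table(tables["hd_tau"], dt);  // tau/edt over v
  Table t_cat_m = make_table(tables["cat_m"], dt);
  Table t_cat_h = make_table(tables["cat_h"], dt);

  // ---- synapses ----
  IntegerVector s_comp = syn["comp"];
  NumericVector s_pampa = syn["pampa"];
  NumericVector s_pnmda = syn["pnmda"];
  NumericVector s_w0 = syn["w"];
  IntegerVector s_plastic = syn["plastic"];
  NumericVector events = syn["events"];
  IntegerVector ev_off = syn["ev_offsets"];  // length nsyn+1
  const int nsyn = s_comp.size();
  std::vector<double> w(nsyn), ca(nsyn, ca_inf);
  std::vector<double> sAd(nsyn, 0.0), sAr(nsyn, 0.0), sNd(nsyn, 0.0), sNr(nsyn, 0.0);
  std::vector<int> ev_idx(nsyn);
  for (int j = 0; j < nsyn; ++j) { w[j] = s_w0[j]; ev_idx[j] = ev_off[j]; }

  // ---- stimulation ----
  IntegerVector st_comp = stim["step_comp"];
  NumericVector st_amp = stim["step_amp"], st_t0 = stim["step_t0"], st_t1 = stim["step_t1"];
  const int nstep_inj = st_comp.size();
  int wave_comp = as<int>(stim["wave_comp"]);
  NumericVector wave = stim["wave"];  // nA per main step (may be empty)

  // ---- plasticity ----
  const bool plast_on = as<bool>(plast["enabled"]);
  const bool couple_on = as<bool>(plast["couple"]);
  const double slope = as<double>(plast["slope"]);
  const bool dw_percent = as<bool>(plast["dw_percent"]);
  const double update_ms = as<double>(plast["update_ms"]);
  const double gh_scale_floor = as<double>(plast["gh_floor"]);
  // weight-update rule parameters
  const double om_a1 = as<double>(plast["alpha1"]), om_a2 = as<double>(plast["alpha2"]);
  const double om_b1 = as<double>(plast["beta1"]), om_b2 = as<double>(plast["beta2"]);
  const double tp1 = as<double>(plast["p1"]), tp2 = as<double>(plast["p2"]);
  const double tp3 = as<double>(plast["p3"]), tp4 = as<double>(plast["p4"]);
  double gh_scale = as<double>(plast["gh_scale0"]);

  auto omega_f = [&](double c) {
    return 0.25 + 1.0 / (1.0 + std::exp(-om_b2 * (c - om_a2)))
         - 0.25 / (1.0 + std::exp(-om_b1 * (c - om_a1)));
  };
  auto tau_w = [&](double c) { return tp1 + tp2 / (tp3 + std::pow(c, tp4)); };

  // ---- recording ----
  IntegerVector rec_comps = rec["comps"];
  const int rec_stride = as<int>(rec["stride"]);
  const int wstride = as<int>(rec["w_stride"]);
  const int nrec = rec_comps.size();

  const int nmain = (int)std::lround(duration / dt);
  const int nsett = (int)std::lround(settle / dt);
  const int ntot = nmain + nsett;
  const int upd_steps = std::max(1, (int)std::lround(update_ms / dt));

  NumericVector soma_v(nmain);
  const int nrt = nmain > 0 ? (nmain - 1) / rec_stride + 1 : 0;
  NumericMatrix vrec(nrec, nrec > 0 ? nrt : 0);
  const int nwt = (plast_on && nsyn > 0 && nmain > 0)
      ? (nmain - 1) / wstride + 1 : 0;
  NumericMatrix wtr(nsyn, nwt), catr(nsyn, nwt);
  std::vector<double> gh_tt, gh_vv;

  // ---- state ----
  std::vector<double> v(n, v_init);
  std::vector<double> m_na(n), h_na(n), s_na(n), n_kdr(n), n_ka(n), l_ka(n),
      l_hd(n), m_cat(n), h_cat(n);
  std::vector<double> comp_ca(n, ca_inf);  // shell per compartment (synapse-bearing)
  std::vector<int> has_shell(n, 0);
  std::vector<int> comp_syn(n, -1);
  for (int j = 0; j < nsyn; ++j) {
    comp_syn[s_comp[j]] = j;
    if (s_plastic[j]) has_shell[s_comp[j]] = 1;
  }

  for (int i = 0; i < n; ++i) {
    m_na[i] = t_na_m.get_inf(v_init);
    h_na[i] = t_na_h.get_inf(v_init);
    s_na[i] = dend[i] ? t_na_s.get_inf(v_init) : 1.0;
    n_kdr[i] = t_kdr_n.get_inf(v_init);
    n_ka[i] = kadist[i] ? t_kad_n.get_inf(v_init) : t_kap_n.get_inf(v_init);
    l_ka[i] = kadist[i] ? t_kad_l.get_inf(v_init) : t_kap_l.get_inf(v_init);
    l_hd[i] = t_hd_l.get_inf(v_init - hvhalf[i]);
    m_cat[i] = t_cat_m.get_inf(v_init);
    h_cat[i] = t_cat_h.get_inf(v_init);
  }

  // leak reversal balancing: pin the resting state at v_init
  NumericVector epas_in = model["epas"];
  std::vector<double> epas(n);
  const bool balance = as<bool>(model["balance"]);
  for (int i = 0; i < n; ++i) {
    if (balance) {
      double gion = gna[i] * m_na[i] * m_na[i] * m_na[i] * h_na[i] * s_na[i];
      double iion = gion * (v_init - ena)
          + gkdr[i] * n_kdr[i] * (v_init - ek)
          + gka[i] * n_ka[i] * l_ka[i] * (v_init - ek)
          + gh[i] * gh_scale * l_hd[i] * (v_init - eh)
          + pcat[i] * m_cat[i] * m_cat[i] * h_cat[i] * ghk_drive(v_init, 2.0, ca_inf, ca_o);
      epas[i] = v_init + iion / gpas[i];
    } else {
      epas[i] = epas_in[i];
    }
  }

  std::vector<double> diag(n), rhs(n), syn_i(n, 0.0), syn_g(n, 0.0),
      shell_i(n, 0.0);
  std::vector<double> child_g(n, 0.0);  // sum over children of gax_par
  for (int i = 1; i < n; ++i) child_g[parent[i]] += gax_par[i];

  double sumw_ref = 0.0;
  for (int j = 0; j < nsyn; ++j) if (s_plastic[j]) sumw_ref += w[j];
  const double dt_s = dt * 1e-3;

  int upd_count = 0;
  for (int istep = 0; istep < ntot; ++istep) {
    const double t0 = (istep - nsett) * dt;  // main-window time at step start
    const bool main_win = istep >= nsett;

    // -- gating update (exponential Euler at current v) --
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      if (gna[i] > 0) {
        m_na[i] = t_na_m.upd(m_na[i], vi);
        h_na[i] = t_na_h.upd(h_na[i], vi);
        if (dend[i]) s_na[i] = t_na_s.upd(s_na[i], vi);
      }
      if (gkdr[i] > 0) n_kdr[i] = t_kdr_n.upd(n_kdr[i], vi);
      if (gka[i] > 0) {
        const Table& tn = kadist[i] ? t_kad_n : t_kap_n;
        const Table& tl = kadist[i] ? t_kad_l : t_kap_l;
        n_ka[i] = tn.upd(n_ka[i], vi);
        l_ka[i] = tl.upd(l_ka[i], vi);
      }
      if (gh[i] > 0) {
        double linf = t_hd_l.get_inf(vi - hvhalf[i]);
        double e = t_hd_tau.get_edt(vi);
        l_hd[i] = linf + (l_hd[i] - linf) * e;
      }
      if (pcat[i] > 0) {
        m_cat[i] = t_cat_m.upd(m_cat[i], vi);
        h_cat[i] = t_cat_h.upd(h_cat[i], vi);
      }
    }

    // -- synapse states: decay + event onsets in (t0, t0+dt] --
    // GHK currents are linearized about the present voltage (their positive
    // chord conductance enters the implicit matrix) for stability at large
    // permeabilities.
    std::fill(syn_i.begin(), syn_i.end(), 0.0);
    std::fill(syn_g.begin(), syn_g.end(), 0.0);
    std::fill(shell_i.begin(), shell_i.end(), 0.0);
    for (int j = 0; j < nsyn; ++j) {
      sAd[j] *= ed_ampa; sAr[j] *= er_ampa;
      sNd[j] *= ed_nmda; sNr[j] *= er_nmda;
      while (ev_idx[j] < ev_off[j + 1] && events[ev_idx[j]] <= t0 + dt) {
        sAd[j] += 1.0; sAr[j] += 1.0;
        sNd[j] += 1.0; sNr[j] += 1.0;
        ++ev_idx[j];
      }
      const int ic = s_comp[j];
      const double vi = v[ic];
      double s_a = a_ampa * (sAd[j] - sAr[j]);
      if (s_a < 0) s_a = 0;
      double i_tot = 0.0, i_tot1 = 0.0;
      const double dnak0 = drive_nak(vi), dnak1 = drive_nak(vi + 1);
      if (s_pampa[j] > 0 && s_a > 0) {
        const double pa = s_pampa[j] * w[j] * s_a;
        i_tot += pa * dnak0;
        i_tot1 += pa * dnak1;
      }
      if (s_pnmda[j] > 0) {
        double s_n = a_nmda * (sNd[j] - sNr[j]);
        if (s_n > 0) {
          double mgb = mgblock(vi, mg_o);
          double pn = s_pnmda[j] * s_n * mgb;
          double dca = ghk_drive(vi, 2.0, comp_ca[ic], ca_o);
          double i_ca = pn * pca_ratio * dca;
          i_tot += pn * dnak0 + i_ca;
          i_tot1 += pn * dnak1
                  + pn * pca_ratio * ghk_drive(vi + 1, 2.0, comp_ca[ic], ca_o);
          shell_i[ic] += i_ca;  // uA/cm2
        }
      }
      syn_i[ic] += i_tot;
      double g_lin = i_tot1 - i_tot;   // chord conductance per mV
      if (g_lin > 0) syn_g[ic] += g_lin;
    }

    // -- assemble implicit system --
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      double gsum = gpas[i];
      double esum = gpas[i] * epas[i];
      if (gna[i] > 0) {
        double g = gna[i] * m_na[i] * m_na[i] * m_na[i] * h_na[i] * s_na[i];
        gsum += g; esum += g * ena;
      }
      if (gkdr[i] > 0) {
        double g = gkdr[i] * n_kdr[i];
        gsum += g; esum += g * ek;
      }
      if (gka[i] > 0) {
        double g = gka[i] * n_ka[i] * l_ka[i];
        gsum += g; esum += g * ek;
      }
      if (gh[i] > 0) {
        double g = gh[i] * gh_scale * l_hd[i];
        gsum += g; esum += g * eh;
      }
      double i_expl = syn_i[i];
      double g_expl = syn_g[i];
      if (pcat[i] > 0) {
        const double pm = pcat[i] * m_cat[i] * m_cat[i] * h_cat[i];
        double icat = pm * ghk_drive(vi, 2.0, comp_ca[i], ca_o);
        double gcat = pm * ghk_drive(vi + 1, 2.0, comp_ca[i], ca_o) - icat;
        i_expl += icat;
        if (gcat > 0) g_expl += gcat;
        if (has_shell[i]) shell_i[i] += icat;
      }
      double i_inj = 0.0;  // uA/cm2, depolarizing positive
      if (main_win) {
        for (int q = 0; q < nstep_inj; ++q) {
          if (st_comp[q] == i && t0 >= st_t0[q] && t0 < st_t1[q])
            i_inj += st_amp[q] * 1e-3 / area[i];
        }
        if (wave_comp == i && wave.size() > 0) {
          int iw = istep - nsett;
          if (iw < wave.size()) i_inj += wave[iw] * 1e-3 / area[i];
        }
      }
      const double cdt = cmv[i] / dt;
      diag[i] = cdt + gsum + g_expl
          + gax_self[i] * (parent[i] >= 0 ? 1.0 : 0.0) + child_g[i];
      rhs[i] = cdt * vi + esum - i_expl + g_expl * vi + i_inj;
    }

    // -- Hines elimination (parent-ordered tree) --
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = (-gax_par[i]) / diag[i];
      diag[p] -= f * (-gax_self[i]);
      rhs[p] -= f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      v[i] = (rhs[i] + gax_self[i] * v[parent[i]]) / diag[i];
    }
    if (!std::isfinite(v[0])) {
      stop("numerical divergence at t = %.3f ms (somatic voltage non-finite)", t0 + dt);
    }

    // -- calcium shells + weights --
    if (nsyn > 0) {
      const double e_ca = std::exp(-dt / tau_ca);
      for (int j = 0; j < nsyn; ++j) {
        if (!s_plastic[j]) continue;
        const int ic = s_comp[j];
        // influx: shell factor applied to current density in mA/cm2
        double influx = -shell_fac * (shell_i[ic] * 1e-3);  // mM/ms
        double ca_ss = ca_inf + tau_ca * influx;
        double c = ca_ss + (comp_ca[ic] - ca_ss) * e_ca;
        if (c < 0) c = 0;
        comp_ca[ic] = c;
        ca[j] = c;
        if (plast_on && main_win) {
          // the plasticity rule operates on the shell concentration in mM
          const double om = omega_f(c);
          const double tw = tau_w(c);
          w[j] = om + (w[j] - om) * std::exp(-dt_s / tw);
          if (w[j] < 0) w[j] = 0;
        }
      }
    }

    // -- HCN coupling update --
    if (plast_on && couple_on && main_win) {
      ++upd_count;
      if (upd_count >= upd_steps) {
        upd_count = 0;
        double sumw = 0.0;
        for (int j = 0; j < nsyn; ++j) if (s_plastic[j]) sumw += w[j];
        if (sumw_ref > 0) {
          double dW = (sumw - sumw_ref) / sumw_ref;
          if (dw_percent) dW *= 100.0;
          gh_scale *= (1.0 + dW * slope);
          if (gh_scale < gh_scale_floor) gh_scale = gh_scale_floor;
        }
        sumw_ref = sumw;
        gh_tt.push_back(t0 + dt);
        gh_vv.push_back(gh_scale);
      }
    }

    // -- recording (main window) --
    if (main_win) {
      const int im = istep - nsett;
      soma_v[im] = v[0];
      if (nrec > 0 && im % rec_stride == 0) {
        const int col = im / rec_stride;
        for (int r = 0; r < nrec; ++r) vrec(r, col) = v[rec_comps[r]];
      }
      if (nwt > 0 && im % wstride == 0) {
        const int col = im / wstride;
        for (int j = 0; j < nsyn; ++j) { wtr(j, col) = w[j]; catr(j, col) = ca[j]; }
      }
    }
  }

  NumericVector w_final(nsyn), ca_final(nsyn);
  for (int j = 0; j < nsyn; ++j) { w_final[j] = w[j]; ca_final[j] = ca[j]; }
  NumericVector v_final(n);
  for (int i = 0; i < n; ++i) v_final[i] = v[i];

  return List::create(
      _["soma_v"] = soma_v,
      _["dt"] = dt,
      _["vrec"] = vrec,
      _["rec_stride"] = rec_stride,
      _["w_trace"] = wtr,
      _["ca_trace"] = catr,
      _["w_stride"] = wstride,
      _["gh_t"] = NumericVector(gh_tt.begin(), gh_tt.end()),
      _["gh_scale_trace"] = NumericVector(gh_vv.begin(), gh_vv.end()),
      _["gh_scale_final"] = gh_scale,
      _["w_final"] = w_final,
      _["ca_final"] = ca_final,
      _["v_final"] = v_final);
}
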