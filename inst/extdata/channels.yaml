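# Voltage-gated channel kinetics: named closed-form rate functions + coefficients.
#
# Forms (v in mV, tau in ms at the reference temperature; qt = q10^((34 - t_ref)/10)
# divides tau):
#   trap      : rate(v) = a*(v - th)/(1 - exp(-(v - th)/q))   (linoid, guarded at v = th)
#   borg      : alp = exp(kT*zeta*(v - vhalf)); bet = exp(kT*zeta*gm*(v - vhalf))
#               inf = 1/(1 + alp); tau = max(bet/(a0*(1 + alp)), tau_min)/qt
#               with kT = 9.648e4/(8.315*T_kelvin)*1e-3 per mV
#   borg_pw   : borg with voltage-dependent zeta: zeta + pw/(1 + exp((v - tq)/qq))
#   sigmoid   : inf = 1/(1 + exp((v - vhalf)/k))
#   bell_tau  : tau = (base + 1/(exp((v + c1)/s1) + exp(-(v + c2)/s2)))/qt
#   lin_tau   : tau = max(slope*(v - v0), tau_min)/qt
constants:
  faraday: 96485.332
  gas: 8.314462
  temperature_K: 307.15
ions:
  na: {conc_out: 140.0, conc_in: 18.0, e_rev: 55.0}
  k: {conc_out: 5.0, conc_in: 140.0, e_rev: -90.0}
  ca: {conc_out: 2.0, conc_in: 1.0e-4}
  mg: {conc_out: 2.0}
channels:
  na:
    e_rev: 55.0
    q10: 2.0
    t_ref: 24.0
    m:
      power: 3
      alpha: {form: trap, th: -30.0, a: 0.4, q: 7.2}
      beta: {form: trap_neg, th: -30.0, a: 0.124, q: 7.2}
      tau_min: 0.02
    h:
      power: 1
      alpha: {form: trap, th: -45.0, a: 0.03, q: 1.5}
      beta: {form: trap_neg, th: -45.0, a: 0.01, q: 1.5}
      inf: {form: sigmoid, vhalf: -50.0, k: 4.0}
      tau_min: 0.5
    # Slow inactivation of dendritic Na channels (simplified two-parameter gate;
    # active in dendritic compartments only). ar2 is the non-inactivating fraction.
    s:
      power: 1
      inf: {form: sigmoid, vhalf: -58.0, k: 2.0}
      ar2_dend: 0.4
      tau: {base: 200.0, amp: 1000.0, vhalf: -45.0, k: 5.0}
  kdr:
    e_rev: -90.0
    q10: 1.0
    t_ref: 24.0
    "n":
      power: 1
      form: borg
      zeta: -3.0
      vhalf: 13.0
      gm: 0.7
      a0: 0.1
      tau_min: 2.0
  kap:
    e_rev: -90.0
    q10: 5.0
    t_ref: 24.0
    "n":
      power: 1
      form: borg_pw
      zeta: -1.5
      pw: -1.0
      tq: -40.0
      qq: 5.0
      vhalf: 11.0
      gm: 0.55
      a0: 0.05
      tau_min: 0.1
    l:
      power: 1
      inf: {form: sigmoid_borg, zeta: 3.0, vhalf: -56.0}
      tau: {form: lin_tau, slope: 0.26, v0: -50.0, tau_min: 2.0}
  kad:
    e_rev: -90.0
    q10: 5.0
    t_ref: 24.0
    "n":
      power: 1
      form: borg_pw
      zeta: -1.8
      pw: -1.0
      tq: -40.0
      qq: 5.0
      vhalf: -1.0
      gm: 0.39
      a0: 0.1
      tau_min: 0.2
    l:
      power: 1
      inf: {form: sigmoid_borg, zeta: 3.0, vhalf: -56.0}
      tau: {form: lin_tau, slope: 0.26, v0: -50.0, tau_min: 2.0}
  hd:
    e_rev: -30.0
    q10: 4.5
    t_ref: 33.0
    l:
      power: 1
      # vhalf varies with path distance (see hcn_half_activation); k = 8 mV
      inf: {form: sigmoid, vhalf: -82.0, k: 8.0}
      tau: {form: borg_tau, zeta: 2.2, vhalf: -75.0, gm: 0.4, a0: 0.011, tau_min: 1.0}
  cat:
    ghk: true
    q10: 2.5
    t_ref: 24.0
    m:
      power: 2
      inf: {form: sigmoid, vhalf: -50.0, k: -7.4}
      tau: {form: bell_tau, base: 3.0, c1: 25.0, s1: 20.0, c2: 100.0, s2: 15.0}
    h:
      power: 1
      inf: {form: sigmoid, vhalf: -85.0, k: 6.0}
      tau: {form: bell_tau, base: 85.0, c1: 46.0, s1: 4.0, c2: 405.0, s2: 50.0}
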