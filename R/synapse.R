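# GHK-based AMPA/NMDA receptor model, magnesium block, double-exponential
# gating, and the submembrane calcium shell each plastic synapse integrates.

#' Default receptor parameters
#'
#' Maximum permeabilities, the NMDA:AMPA permeability ratio (NAR), ionic
#' permeability ratios, and rise/decay time constants of the
#' double-exponential gating.
#'
#' @param p_ampa Maximum AMPA permeability (cm/s); the working value is set
#'   per synapse by dendritic-democracy tuning.
#' @param nar NMDA:AMPA maximum-permeability ratio.
#' @return Named list: `p_ampa`, `nar`, `pca_nmda` (Ca:Na:K = 10.6:1:1 for
#'   NMDA; Na:K = 1:1 for AMPA), `tau_r_ampa`/`tau_d_ampa` = 2/10 ms,
#'   `tau_r_nmda`/`tau_d_nmda` = 5/50 ms, `w_init` = 0.25.
#' @export
receptor_params <- function(p_ampa = 5e-8, nar = 1.5) {
  stopifnot(nar > 0, p_ampa >= 0)
  list(p_ampa = p_ampa, nar = nar, pca_nmda = 10.6,
       tau_r_ampa = 2, tau_d_ampa = 10,
       tau_r_nmda = 5, tau_d_nmda = 50,
       w_init = 0.25)
}

#' Magnesium block of the NMDA receptor
#'
#' `MgB(v) = 1/(1 + [Mg]o exp(-0.062 v)/3.57)`; monotone increasing in v,
#' in (0, 1].
#'
#' @param v Membrane potential (mV), vectorized.
#' @param mg_o Extracellular magnesium (mM).
#' @return Unblocked fraction.
#' @export
mg_block <- function(v, mg_o = 2) {
  stopifnot(mg_o >= 0)
  1 / (1 + mg_o * exp(-0.062 * v) / 3.57)
}

#' Double-exponential receptor gating
#'
#' `s(t) = a (exp(-t/tau_d) - exp(-t/tau_r))` per presynaptic event, with `a`
#' chosen so a single event peaks at exactly 1 at
#' `t* = ln(tau_d/tau_r) tau_r tau_d/(tau_d - tau_r)`. Multiple events
#' superpose linearly.
#'
#' @param t Time since each event onset (ms); values `< 0` contribute 0.
#'   Either a vector of lags for a single event, or — with `events` given —
#'   evaluation times.
#' @param tau_r,tau_d Rise and decay time constants (ms), `tau_r < tau_d`.
#' @param events Optional event-onset times (ms) to superpose.
#' @return Gating value(s).
#' @export
gating_s <- function(t, tau_r, tau_d, events = NULL) {
  stopifnot(tau_r < tau_d, tau_r > 0)
  tp <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  a <- 1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
  one <- function(lag) ifelse(lag < 0, 0, a * (exp(-lag / tau_d) - exp(-lag / tau_r)))
  if (is.null(events)) return(one(t))
  vapply(t, function(ti) sum(one(ti - events)), 0)
}

#' AMPA and NMDA receptor current components
#'
#' GHK ionic components of the co-localized AMPA/NMDA synapse: NMDA carries
#' Na, K and Ca (permeability ratio 10.6:1:1 for Ca:Na:K) gated by the
#' magnesium block; AMPA carries Na and K (1:1) scaled by the synaptic
#' weight `w`.
#'
#' @param v Membrane potential (mV).
#' @param s_ampa,s_nmda Gating values from [gating_s()].
#' @param w Synaptic weight (dimensionless).
#' @param p_ampa,p_nmda Maximum permeabilities (cm/s).
#' @param ca_i Shell calcium (mM) seen by the NMDA Ca component.
#' @param params Receptor parameters, see [receptor_params()].
#' @param constants See [physical_constants()].
#' @return Named list of current densities (mA/cm2): `i_nmda_na`, `i_nmda_k`,
#'   `i_nmda_ca`, `i_ampa_na`, `i_ampa_k`.
#' @export
receptor_currents <- function(v, s_ampa, s_nmda, w, p_ampa,
                              p_nmda = 1.5 * p_ampa, ca_i = 1e-4,
                              params = receptor_params(),
                              constants = physical_constants()) {
  mgb <- mg_block(v, constants$mg_o)
  list(
    i_nmda_na = p_nmda * s_nmda * mgb *
      ghk_flux(v, 1, constants$na_i, constants$na_o, 1, constants),
    i_nmda_k = p_nmda * s_nmda * mgb *
      ghk_flux(v, 1, constants$k_i, constants$k_o, 1, constants),
    i_nmda_ca = p_nmda * params$pca_nmda * s_nmda * mgb *
      ghk_flux(v, 2, ca_i, constants$ca_o, 1, constants),
    i_ampa_na = p_ampa * w * s_ampa *
      ghk_flux(v, 1, constants$na_i, constants$na_o, 1, constants),
    i_ampa_k = p_ampa * w * s_ampa *
      ghk_flux(v, 1, constants$k_i, constants$k_o, 1, constants)
  )
}

#' Default calcium-shell parameters
#'
#' @return Named list: decay time constant `tau_ca` = 30 ms, shell depth
#'   `depth` = 0.1 um, resting concentration `ca_inf` = 1e-4 mM.
#' @export
calcium_params <- function() list(tau_ca = 30, depth = 0.1, ca_inf = 1e-4)

#' Advance the submembrane calcium shell
#'
#' `d[Ca]i/dt = -1e4 (I_NMDA_Ca + I_CaT)/(3.6 dpt F) + ([Ca]inf - [Ca]i)/tau`
#' with currents in mA/cm2, depth in um, time in ms; advanced analytically
#' over `dt` holding the influx constant. The printed shell constant (3.6) is
#' kept verbatim; see the package vignette for a unit-consistency note.
#'
#' @param ca Shell calcium (mM).
#' @param i_nmda_ca,i_cat_ca Calcium current densities (mA/cm2, inward
#'   negative).
#' @param dt Time step (ms).
#' @param params See [calcium_params()].
#' @return Updated shell calcium (mM), clamped at 0 with a warning if the
#'   update would go negative.
#' @export
step_calcium <- function(ca, i_nmda_ca, i_cat_ca = 0, dt,
                         params = calcium_params()) {
  stopifnot(dt > 0, ca >= 0)
  influx <- -1e4 * (i_nmda_ca + i_cat_ca) / (3.6 * params$depth * .const$faraday)
  ca_ss <- params$ca_inf + params$tau_ca * influx
  out <- ca_ss + (ca - ca_ss) * exp(-dt / params$tau_ca)
  if (any(out < 0)) {
    warning("calcium shell clamped at 0")
    out <- pmax(out, 0)
  }
  out
}
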