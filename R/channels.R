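# Voltage-gated channel kinetics, conductance gradients, and GHK
# electrochemistry. Rate functions are named closed forms whose coefficients
# live in inst/extdata/channels.yaml so they are inspectable and testable.

#' Load the channel kinetics configuration
#'
#' Reads the structured channel parameter file shipped with the package (or a
#' user-supplied one with the same schema): per channel, gating variables are
#' defined by named closed-form rate functions plus coefficients, together
#' with reversal potentials and q10 temperature factors.
#'
#' @param path Path to a YAML channel definition; defaults to the packaged
#'   file.
#' @return Nested list with elements `constants`, `ions`, `channels`.
#' @export
channel_config <- function(path = system.file("extdata", "channels.yaml",
                                              package = "hplast")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$channels), !is.null(cfg$ions))
  cfg
}

# linoid rate, guarded at the singular point
.trap <- function(v, th, a, q) {
  x <- v - th
  out <- a * x / (1 - exp(-x / q))
  small <- abs(x) < 1e-6
  out[small] <- a * q
  out
}

.sigmoid <- function(v, vhalf, k) 1 / (1 + exp((v - vhalf) / k))

# thermodynamic factor per mV: F/(R*T) * 1e-3
.kT <- function() .const$faraday / (.const$gas * .const$temp_K) * 1e-3

.qt <- function(ch) ch$q10^((34 - ch$t_ref) / 10)

#' Gating variable steady state and time constant
#'
#' Evaluates the steady-state activation/inactivation curve and the
#' voltage-dependent time constant of one gating variable of one channel at
#' the model temperature (34 degrees C; q10-corrected).
#'
#' @param channel One of `"na"`, `"kdr"`, `"kap"`, `"kad"`, `"hd"`, `"cat"`.
#' @param gate Gate name within the channel (e.g. `"m"`, `"h"`, `"n"`, `"l"`,
#'   `"s"`).
#' @param v Membrane potential (mV), vectorized.
#' @param cfg Channel configuration from [channel_config()].
#' @param dendritic For the Na slow-inactivation gate `s`: evaluate the
#'   dendritic variant (partial inactivation); otherwise the gate is inert.
#' @param hd_vhalf Half-activation voltage override for the HCN `l` gate
#'   (its half-activation varies with path distance).
#' @return List with numeric vectors `inf` (dimensionless) and `tau` (ms).
#' @export
gate_kinetics <- function(channel, gate, v, cfg = channel_config(),
                          dendritic = TRUE, hd_vhalf = NULL) {
  ch <- cfg$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  g <- ch[[gate]]
  if (is.null(g)) stop("channel ", channel, " has no gate ", gate)
  qt <- .qt(ch)
  kT <- .kT()
  if (channel == "na" && gate %in% c("m", "h")) {
    al <- .trap(v, g$alpha$th, g$alpha$a, g$alpha$q)
    be <- .trap(-v, -g$beta$th, g$beta$a, g$beta$q)
    tau <- pmax(1 / (al + be) / qt, g$tau_min)
    inf <- if (!is.null(g$inf)) .sigmoid(v, g$inf$vhalf, g$inf$k) else al / (al + be)
    return(list(inf = inf, tau = tau))
  }
  if (channel == "na" && gate == "s") {
    base <- .sigmoid(v, g$inf$vhalf, g$inf$k)
    ar2 <- if (dendritic) g$ar2_dend else 1
    inf <- ar2 + (1 - ar2) * base
    # slow gate: recovery slow at rest, inactivation moderate when depolarized
    tau <- g$tau$base + g$tau$amp / (1 + exp((v - g$tau$vhalf) / g$tau$k))
    return(list(inf = inf, tau = tau))
  }
  if (channel %in% c("kdr", "kap", "kad") && gate == "n") {
    zeta <- g$zeta
    if (identical(g$form, "borg_pw")) {
      zeta <- zeta + g$pw / (1 + exp((v - g$tq) / g$qq))
    }
    alp <- exp(kT * zeta * (v - g$vhalf))
    bet <- exp(kT * zeta * g$gm * (v - g$vhalf))
    inf <- 1 / (1 + alp)
    tau <- pmax(bet / (g$a0 * qt * (1 + alp)), g$tau_min)
    return(list(inf = inf, tau = tau))
  }
  if (channel %in% c("kap", "kad") && gate == "l") {
    alp <- exp(kT * g$inf$zeta * (v - g$inf$vhalf))
    inf <- 1 / (1 + alp)
    tau <- pmax(g$tau$slope * (v - g$tau$v0), g$tau$tau_min)
    return(list(inf = inf, tau = tau))
  }
  if (channel == "hd" && gate == "l") {
    vh <- if (is.null(hd_vhalf)) g$inf$vhalf else hd_vhalf
    inf <- .sigmoid(v, vh, g$inf$k)
    a <- exp(0.0378 * g$tau$zeta * (v - g$tau$vhalf))
    bet <- exp(0.0378 * g$tau$zeta * g$tau$gm * (v - g$tau$vhalf))
    tau <- pmax(bet / (g$tau$a0 * qt * (1 + a)), g$tau$tau_min)
    return(list(inf = inf, tau = tau))
  }
  if (channel == "cat") {
    inf <- .sigmoid(v, g$inf$vhalf, g$inf$k)
    tt <- g$tau
    tau <- (tt$base + 1 / (exp((v + tt$c1) / tt$s1) + exp(-(v + tt$c2) / tt$s2))) / qt
    return(list(inf = inf, tau = tau))
  }
  stop("no kinetics defined for ", channel, "/", gate)
}

#' Conductance-density gradients along the apical trunk
#'
#' A-type K density rises linearly with path distance from the soma; HCN and
#' T-type Ca densities rise sigmoidally. Basal and axonal compartments take
#' somatic (x = 0) values, which callers enforce by passing x = 0.
#'
#' @param channel `"KA"`, `"HCN"` or `"CaT"`.
#' @param x Path distance from the soma (um), vectorized, `>= 0`.
#' @param params Gradient parameters from [gradient_params()].
#' @return Conductance density: mS/cm2 for KA, uS/cm2 for HCN and CaT.
#' @export
gradient_density <- function(channel, x, params = gradient_params()) {
  stopifnot(all(x >= 0))
  p <- params
  switch(channel,
    KA = p$A_gB * (1 + p$A_F * x / 100),
    HCN = p$h_gB * (1 + p$h_F / (1 + exp((p$h_d - x) / p$h_k))),
    CaT = p$T_gB * (1 + p$T_F / (1 + exp((p$T_d - x) / p$T_k))),
    stop("unknown channel: ", channel)
  )
}

#' Default channel gradient parameters
#'
#' Somatic baseline densities, fold increases and sigmoid midpoints/slopes of
#' the apical channel gradients, plus the uniform Na/KDR densities and the
#' axon-initial-segment Na multiplier.
#'
#' @param theta If `TRUE`, use the Na/KDR densities of the theta-modulated
#'   (place-field) model variant (15.4 and 2 mS/cm2) instead of the
#'   Poisson-input variant (16 and 10 mS/cm2).
#' @return Named list. `A_gB` (mS/cm2) and `A_F` set the linear KA gradient;
#'   `h_gB` (uS/cm2), `h_F`, `h_d`, `h_k` (um) the HCN sigmoid; `T_gB`
#'   (uS/cm2), `T_F`, `T_d`, `T_k` (um) the CaT sigmoid; `gNa`, `gKDR`
#'   (mS/cm2) the uniform densities; `ais_na_mult` the AIS Na multiplier.
#' @export
gradient_params <- function(theta = FALSE) {
  list(A_gB = 3.1, A_F = 8,
       h_gB = 25, h_F = 12, h_d = 320, h_k = 50,
       T_gB = 80, T_F = 30, T_d = 350, T_k = 50,
       gNa = if (theta) 15.4 else 16,
       gKDR = if (theta) 2 else 10,
       ais_na_mult = 5)
}

#' HCN half-maximal activation voltage along the apical trunk
#'
#' -82 mV within 100 um of the soma, linearly shifting to -90 mV at 300 um,
#' and -90 mV beyond.
#'
#' @param x Path distance from the soma (um), vectorized.
#' @return Half-activation voltage (mV).
#' @export
hcn_half_activation <- function(x) {
  stopifnot(all(x >= 0))
  ifelse(x <= 100, -82,
         ifelse(x >= 300, -90, -82 - 8 * (x - 100) / 200))
}

#' A-type K channel model selector
#'
#' Proximal kinetics within 100 um of the soma, distal kinetics at and beyond
#' 100 um.
#'
#' @param x Path distance from the soma (um), vectorized.
#' @return Character vector, `"proximal"` or `"distal"`.
#' @export
ka_model_select <- function(x) {
  stopifnot(all(x >= 0))
  ifelse(x < 100, "proximal", "distal")
}

#' Goldman-Hodgkin-Katz constant-field current
#'
#' GHK current density for an ion of valence `z` at permeability `P`. The
#' expression is continuous at v = 0 via its series limit, where the current
#' equals `P * z * F * (Ci - Co)` (concentrations in mol/cm3).
#'
#' @param v Membrane potential (mV), vectorized.
#' @param z Ion valence.
#' @param ci,co Internal and external concentrations (mM).
#' @param P Permeability (cm/s).
#' @param constants Physical constants, see [physical_constants()].
#' @return Current density (mA/cm2); negative is inward.
#' @export
ghk_flux <- function(v, z, ci, co, P = 1, constants = physical_constants()) {
  stopifnot(P >= 0)
  xi <- z * v * 1e-3 * constants$faraday / (constants$gas * constants$temp_K)
  ci3 <- ci * 1e-6   # mol/cm3
  co3 <- co * 1e-6
  f <- ifelse(abs(xi) < 1e-5,
              (ci3 - co3) + xi * (ci3 + co3) / 2,
              xi * (ci3 - co3 * exp(-xi)) / (1 - exp(-xi)))
  P * z * constants$faraday * f * 1e3
}

# Voltage lookup tables handed to the compiled integrator. The HCN activation
# curve is tabulated over the shifted argument (v - vhalf) so per-compartment
# half-activation voltages reuse one table.
.gate_tables <- function(cfg = channel_config()) {
  v <- seq(-150, 70, by = 0.05)
  arg <- seq(-200, 200, by = 0.05)
  tab <- function(k) list(vmin = v[1], dv = 0.05, inf = k$inf, tau = k$tau)
  hd0 <- gate_kinetics("hd", "l", arg, cfg, hd_vhalf = 0)
  hdt <- gate_kinetics("hd", "l", v, cfg)
  list(
    na_m = tab(gate_kinetics("na", "m", v, cfg)),
    na_h = tab(gate_kinetics("na", "h", v, cfg)),
    na_s = tab(gate_kinetics("na", "s", v, cfg, dendritic = TRUE)),
    kdr_n = tab(gate_kinetics("kdr", "n", v, cfg)),
    kap_n = tab(gate_kinetics("kap", "n", v, cfg)),
    kap_l = tab(gate_kinetics("kap", "l", v, cfg)),
    kad_n = tab(gate_kinetics("kad", "n", v, cfg)),
    kad_l = tab(gate_kinetics("kad", "l", v, cfg)),
    hd_l = list(vmin = arg[1], dv = 0.05, inf = hd0$inf, tau = hd0$tau),
    hd_tau = tab(hdt),
    cat_m = tab(gate_kinetics("cat", "m", v, cfg)),
    cat_h = tab(gate_kinetics("cat", "h", v, cfg))
  )
}
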