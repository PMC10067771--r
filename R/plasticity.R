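# Calcium-control synaptic weight dynamics and the linear coupling between
# total synaptic weight change and somatic HCN conductance.

#' Default plasticity parameters
#'
#' Constants of the calcium-dependent learning time constant
#' `tau(Ca) = P1 + P2/(P3 + Ca^P4)` and of the double-sigmoid target function
#' Omega. Calcium enters these expressions in mM.
#'
#' @return Named list: `p1` = 1 s, `p2` = 0.1 s, `p3` = `p2 * 1e-4`,
#'   `p4` = 3; `alpha1` = 0.35, `alpha2` = 0.55, `beta1` = `beta2` = 80;
#'   `w_init` = 0.25.
#' @export
plasticity_params <- function() {
  list(p1 = 1, p2 = 0.1, p3 = 0.1 * 1e-4, p4 = 3,
       alpha1 = 0.35, alpha2 = 0.55, beta1 = 80, beta2 = 80,
       w_init = 0.25)
}

#' Calcium-dependent target weight (Omega function)
#'
#' Double sigmoid with an LTD trough between `alpha1` and `alpha2` and an LTP
#' plateau (-> 1) above `alpha2`:
#' `Omega(Ca) = 0.25 + 1/(1 + exp(-beta2 (Ca - alpha2)))
#'            - 0.25/(1 + exp(-beta1 (Ca - alpha1)))`.
#'
#' @param ca Calcium (mM), `>= 0`, vectorized.
#' @param params See [plasticity_params()].
#' @return Target weight.
#' @export
omega <- function(ca, params = plasticity_params()) {
  stopifnot(all(ca >= 0))
  0.25 + 1 / (1 + exp(-params$beta2 * (ca - params$alpha2))) -
    0.25 / (1 + exp(-params$beta1 * (ca - params$alpha1)))
}

#' Calcium-dependent learning time constant
#'
#' `tau(Ca) = P1 + P2/(P3 + Ca^P4)` (seconds); strictly decreasing in
#' calcium, about 3 h at Ca = 0 and bounded below by `P1` = 1 s.
#'
#' @param ca Calcium (mM), `>= 0`, vectorized.
#' @param params See [plasticity_params()].
#' @return Time constant (s).
#' @export
learning_tau <- function(ca, params = plasticity_params()) {
  stopifnot(all(ca >= 0))
  params$p1 + params$p2 / (params$p3 + ca^params$p4)
}

#' Advance a synaptic weight by one step
#'
#' Exponential pursuit of the calcium-dependent target:
#' `dw/dt = (Omega(Ca) - w)/tau(Ca)`, advanced analytically over `dt` at
#' fixed calcium. The result always lies between `w` and `Omega(Ca)`.
#'
#' @param w Current weight.
#' @param ca Calcium (mM).
#' @param dt Time step (s).
#' @param params See [plasticity_params()].
#' @return Updated weight.
#' @export
step_weight <- function(w, ca, dt, params = plasticity_params()) {
  stopifnot(dt > 0)
  om <- omega(ca, params)
  om + (w - om) * exp(-dt / learning_tau(ca, params))
}

#' HCN coupling rule parameters
#'
#' @param slope Slope of the linear relationship between the fractional
#'   change in total synaptic weight and the fractional change in somatic HCN
#'   conductance.
#' @param update_ms Update cadence (ms) at which the coupling is applied
#'   during induction.
#' @param dw_percent If `TRUE`, the weight change enters the update as a
#'   percentage instead of a fraction (a 100x rescaling of the slope).
#' @param gh_floor Lower clamp for the cumulative conductance scale.
#' @return Named list of class `hcn_coupling`.
#' @export
hcn_coupling <- function(slope, update_ms = 100, dw_percent = FALSE,
                         gh_floor = 1e-3) {
  stopifnot(slope >= 0, update_ms > 0)
  structure(list(slope = slope, update_ms = update_ms,
                 dw_percent = dw_percent, gh_floor = gh_floor),
            class = c("hcn_coupling", "list"))
}

#' Apply the HCN conductance update rule
#'
#' `g' = g (1 + DeltaW * slope)` with
#' `DeltaW = (sum(w_now) - sum(w_ref))/sum(w_ref)` the fractional change of
#' the summed synaptic weights over the update interval. The somatic value
#' rescales the entire spatial HCN gradient (widespread conductance change).
#'
#' @param g_soma Somatic maximal HCN conductance (any density unit).
#' @param weights_now,weights_ref Weight vectors at the end and start of the
#'   interval; `sum(weights_ref) > 0`.
#' @param coupling An [hcn_coupling()].
#' @return Updated somatic conductance (clamped at
#'   `coupling$gh_floor * g_soma` with a warning if the update would cross 0).
#' @export
update_hcn <- function(g_soma, weights_now, weights_ref, coupling) {
  stopifnot(inherits(coupling, "hcn_coupling"),
            length(weights_now) == length(weights_ref),
            sum(weights_ref) > 0)
  dW <- (sum(weights_now) - sum(weights_ref)) / sum(weights_ref)
  if (coupling$dw_percent) dW <- dW * 100
  g <- g_soma * (1 + dW * coupling$slope)
  if (g <= 0) {
    warning("HCN conductance update clamped at floor")
    g <- coupling$gh_floor * g_soma
  }
  g
}
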