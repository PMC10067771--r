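# Measurement battery: EPSP amplitude, dendritic-democracy tuning, input
# resistance, input/output response profiles, RMSE.

#' Somatic EPSP amplitude of one synapse
#'
#' Activates a single synapse once (AMPA only) and returns the difference
#' between the somatic baseline potential and the peak response.
#'
#' @param model A `neuron_model` with synapses.
#' @param syn_id Synapse id (row of `model$syn`).
#' @param weights,gh_scale Optional state overrides (see [simulate()]).
#' @param duration Simulated window after the event (ms).
#' @return EPSP amplitude (mV). Errors if the event evokes a spike.
#' @export
epsp_amplitude <- function(model, syn_id, weights = NULL, gh_scale = NULL,
                           duration = 120) {
  stopifnot(!is.null(model$syn), syn_id %in% model$syn$syn)
  nsyn <- nrow(model$syn)
  events <- vector("list", nsyn)
  onset <- 10
  events[[which(model$syn$syn == syn_id)]] <- onset
  sim <- simulate(model, duration = duration, events = events,
                  ampa_only = TRUE, weights = weights, gh_scale = gh_scale,
                  settle = 50)
  i0 <- round(onset / model$dt)
  base <- sim$soma_v[i0]
  peak <- max(sim$soma_v[i0:length(sim$soma_v)])
  if (length(sim$spikes) > 0) stop("EPSP measurement evoked a spike")
  peak - base
}

#' Tune synaptic permeabilities for dendritic democracy
#'
#' Iteratively rescales each synapse's maximum AMPA permeability until all
#' somatic EPSP amplitudes match their targets, so synapses at all dendritic
#' distances contribute equally at the soma. The converged permeabilities
#' increase with distance from the soma.
#'
#' @param model A `neuron_model` with synapses.
#' @param target Target somatic EPSP amplitude (mV); a scalar, or one value
#'   per synapse (e.g. different targets for different synapse populations).
#' @param tol Convergence tolerance (mV); scalar or per synapse.
#' @param max_iter Maximum sweeps over the synapse set.
#' @return The model with tuned `syn$p_ampa`.
#' @export
democracy_tune <- function(model, target = 0.2, tol = 0.01, max_iter = 25) {
  stopifnot(!is.null(model$syn), all(target > 0))
  nsyn <- nrow(model$syn)
  target <- rep_len(target, nsyn)
  tol <- rep_len(tol, nsyn)
  for (iter in seq_len(max_iter)) {
    amps <- vapply(model$syn$syn, function(s) {
      tryCatch(epsp_amplitude(model, s), error = function(e) NA_real_)
    }, 0)
    if (!anyNA(amps) && all(abs(amps - target) <= tol)) {
      attr(model, "democracy") <- list(iter = iter, amps = amps)
      return(model)
    }
    fac <- ifelse(is.na(amps), 0.5, ifelse(amps > 0, target / amps, 2))
    model$syn$p_ampa <- model$syn$p_ampa * pmin(pmax(fac, 0.2), 5)
  }
  stop("democracy tuning did not converge in ", max_iter, " iterations")
}

#' Local input resistance
#'
#' Injects current pulses of various amplitudes (default -50 to +50 pA in
#' steps of 10 pA) at a compartment and fits the steady-state V-I relation;
#' the slope is the input resistance.
#'
#' @param model A `neuron_model`.
#' @param comp Compartment id (default: soma).
#' @param amps_pA Pulse amplitudes (pA). The -50..+50 pA default suits the
#'   full-scale model; reduced models need smaller pulses to stay
#'   subthreshold.
#' @param pulse_ms Pulse length (ms); the last fifth is averaged as steady
#'   state, against a 100 ms pre-pulse baseline.
#' @param gh_scale Optional HCN scale override.
#' @return List: `rin` (MOhm), `r2` of the linear fit, the V-I table.
#' @export
input_resistance <- function(model, comp = 1, amps_pA = seq(-50, 50, 10),
                             pulse_ms = 500, gh_scale = NULL) {
  delay <- 100
  dv <- vapply(amps_pA, function(a) {
    inj <- data.frame(comp = comp, amp = a / 1000, t0 = delay,
                      t1 = delay + pulse_ms)
    sim <- simulate(model, duration = delay + pulse_ms, inj = inj,
                    settle = 200, record = comp, gh_scale = gh_scale)
    if (length(sim$spikes) > 0) stop("input resistance pulse evoked spikes")
    tr <- sim$vrec[1, ]
    tt <- (seq_along(tr) - 1) * model$dt * sim$rec_stride
    mean(tr[tt >= delay + 0.8 * pulse_ms]) - mean(tr[tt < delay])
  }, 0)
  fit <- lm(dv ~ I(amps_pA / 1000))
  list(rin = unname(coef(fit)[2]), r2 = summary(fit)$r.squared,
       vi = data.frame(amp_pA = amps_pA, dv_mV = dv))
}

# deterministic per-(freq, trial, synapse) substream below 2^31
.trial_seed <- function(seed, freq, trial, synapse) {
  as.integer((as.double(seed) * 10007 + round(freq * 977) * 131 +
                trial * 8191 + synapse * 17) %% 2147483647)
}

#' Synaptically driven input/output response profile
#'
#' Stimulates all synapses simultaneously with independent Poisson trains at
#' each stimulus frequency (AMPA receptors only), repeating each frequency
#' over several trials; the somatic spike count in the 1 s window is the
#' response frequency. Trial substreams are derived deterministically from
#' the master seed, so baseline and post-plasticity profiles see identical
#' stimulation patterns trial by trial.
#'
#' @param model A `neuron_model` with synapses.
#' @param freqs Stimulus frequencies (Hz).
#' @param trials Trials per frequency.
#' @param seed Master seed.
#' @param weights,gh_scale Optional state overrides.
#' @param duration_s Trial window (s).
#' @return Object of class `response_profile`: `freqs`, `trials`, matrix
#'   `rf` (frequencies x trials, spikes/s).
#' @export
io_profile <- function(model, freqs = 1:50, trials = 10, seed = 1,
                       weights = NULL, gh_scale = NULL, duration_s = 1) {
  stopifnot(!is.null(model$syn))
  nsyn <- nrow(model$syn)
  rf <- matrix(0, length(freqs), trials)
  for (fi in seq_along(freqs)) {
    for (k in seq_len(trials)) {
      events <- lapply(seq_len(nsyn), function(s) {
        poisson_train(freqs[fi], duration_s,
                      seed = .trial_seed(seed, freqs[fi], k, s))
      })
      sim <- simulate(model, duration = duration_s * 1000, events = events,
                      ampa_only = TRUE, weights = weights,
                      gh_scale = gh_scale, settle = 50)
      rf[fi, k] <- length(sim$spikes) / duration_s
    }
  }
  structure(list(freqs = freqs, trials = trials, rf = rf, seed = seed),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat("response profile:", length(x$freqs), "stimulus frequencies x",
      x$trials, "trials; mean rate",
      sprintf("%.2f Hz\n", mean(x$rf)))
  invisible(x)
}

#' Root mean squared error between response profiles
#'
#' `sqrt(mean((new - base)^2))` over all (stimulus frequency, trial) cells;
#' trials are matched by index, so with shared stimulation substreams the
#' RMSE measures the profile shift rather than trial noise.
#'
#' @param new,base `response_profile`s (or bare matrices) of equal dimension.
#' @return RMSE (Hz).
#' @export
rmse <- function(new, base) {
  a <- if (inherits(new, "response_profile")) new$rf else as.matrix(new)
  b <- if (inherits(base, "response_profile")) base$rf else as.matrix(base)
  if (!all(dim(a) == dim(b))) stop("profile dimensions differ")
  sqrt(mean((a - b)^2))
}

#' Write a response profile as CSV
#'
#' Rows are stimulus frequencies, columns trials.
#'
#' @param profile A `response_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  m <- as.data.frame(profile$rf)
  names(m) <- paste0("trial", seq_len(ncol(m)))
  write.csv(cbind(freq_Hz = profile$freqs, m), path, row.names = FALSE)
  invisible(path)
}
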