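# Experiment orchestration: baseline construction, plasticity induction,
# iterated stimulation with permeability updates, slope optimization,
# sensitivity sweeps, and the theta-driven place-field study.

#' Reduced-scale study preset
#'
#' Desk-scale study conditions: a synthetic morphology with the full 425 um
#' apical extent, a proportionally reduced synapse count, a coarser stimulus
#' grid and fewer trials than the full-scale model. All biophysical
#' constants, the integration step and the plasticity rule are unchanged
#' from the full-scale conditions; only problem sizes shrink.
#'
#' @return Named list of protocol parameters.
#' @export
reduced_preset <- function() {
  list(name = "reduced",
       morph_spec = morphology_spec(n_oblique = 5, oblique_length = 80),
       morph_seed = 42,
       n_syn = 24, syn_range = c(12.5, 286.7),
       epsp_total = 100, epsp_tol_frac = 0.02,
       freqs = seq(2, 20, by = 2), trials = 3,
       induction_s = 25, induction_range = c(4, 12),
       slope_grid = seq(0, 20, by = 2.5),
       iterations = 7,
       mi_bins = 1:100, mi_range = NULL,
       update_ms = 100,
       base_n = 12, place_n = 5,
       theta_base_epsp = 0.6, theta_place_epsp = 6, theta_gkdr = 10,
       place_window = c(3, 8), place_duration = 10,
       ramp_target = 4, theta_A = 1, smoothing_sd = 300)
}

#' Full-scale study preset
#'
#' The conditions of the full-scale model: a 3D-reconstructed CA1 morphology
#' (SWC path must be supplied), 303 synapses over 12.5-286.7 um, stimulus
#' frequencies 1-50 Hz with 10 trials, 151/61 base/place theta synapses.
#' Running at this scale takes hours and is opt-in.
#'
#' @param swc_path Path to the CA1 reconstruction SWC file.
#' @return Named list of protocol parameters.
#' @export
full_preset <- function(swc_path) {
  p <- reduced_preset()
  p$name <- "full"
  p$swc_path <- swc_path
  p$n_syn <- 303
  p$freqs <- 1:50
  p$trials <- 10
  p$slope_grid <- seq(0, 10, by = 0.5)
  p$base_n <- 151
  p$place_n <- 61
  p$theta_base_epsp <- 0.2
  p$theta_place_epsp <- 0.2
  p$theta_gkdr <- 2
  p
}

#' Build the baseline study model
#'
#' Morphology (synthetic or from SWC), compartmentalization, channel
#' gradients, synapse placement, and dendritic-democracy tuning.
#'
#' @param preset A [reduced_preset()] or [full_preset()].
#' @param theta Build the theta-protocol variant (place-field Na/KDR
#'   densities, -66 mV holding); otherwise the Poisson-protocol variant
#'   (-65 mV).
#' @param synapses Place and tune the Poisson-protocol synapse set (skipped
#'   for the place-field study, which places its own populations).
#' @return A tuned `neuron_model`.
#' @export
build_study <- function(preset = reduced_preset(), theta = FALSE,
                        synapses = TRUE) {
  m <- if (!is.null(preset$swc_path)) load_swc(preset$swc_path)
       else make_morphology(preset$morph_spec, seed = preset$morph_seed)
  tree <- compartmentalize(m)
  model <- build_model(tree, gradients = gradient_params(theta = theta),
                       v_init = if (theta) -66 else -65)
  if (synapses) {
    model <- place_synapses(model, preset$n_syn, range = preset$syn_range)
    target <- preset$epsp_total / nrow(model$syn)
    model <- democracy_tune(model, target = target,
                            tol = target * preset$epsp_tol_frac)
  }
  model
}

#' Assign induction stimuli
#'
#' Each synapse receives a stimulus frequency drawn uniformly from the
#' induction range (4-12 Hz) and an independent Poisson event train at that
#' frequency. The pattern is a pure function of the seed, so it can be held
#' fixed across iterations and slope conditions.
#'
#' @param model A `neuron_model` with synapses.
#' @param duration_s Induction duration (s).
#' @param seed Integer seed.
#' @param range Frequency range (Hz).
#' @return List: `freqs` per synapse, `events` list of event-time vectors
#'   (ms).
#' @export
assign_induction_stimuli <- function(model, duration_s, seed,
                                     range = c(4, 12)) {
  nsyn <- nrow(model$syn)
  set.seed(seed)
  freqs <- runif(nsyn, range[1], range[2])
  events <- lapply(seq_len(nsyn), function(s) {
    poisson_train(freqs[s], duration_s, seed = .trial_seed(seed, 0, 0, s))
  })
  list(freqs = freqs, events = events)
}

#' Induce synaptic plasticity (optionally with HCN coupling)
#'
#' Runs the induction protocol with AMPA+NMDA synapses and calcium-dependent
#' weight updates; if a coupling is given, somatic HCN conductance co-evolves
#' with the total synaptic weight.
#'
#' @param model A `neuron_model` with synapses.
#' @param stimuli From [assign_induction_stimuli()].
#' @param coupling An [hcn_coupling()] or `NULL`.
#' @param duration_s Induction duration (s).
#' @return The [simulate()] result (final weights in `w_final`, HCN scale in
#'   `gh_scale_final`, decimated weight/calcium/HCN traces).
#' @export
induce_plasticity <- function(model, stimuli, coupling = NULL,
                              duration_s = 25) {
  simulate(model, duration = duration_s * 1000, events = stimuli$events,
           plasticity = TRUE, coupling = coupling, settle = 50)
}

#' Fold expressed plasticity into the model
#'
#' Updates AMPA permeabilities according to the final synaptic weights
#' (`p_ampa * w_final/w_init`), resets weights to `w_init`, keeps the
#' NMDA:AMPA ratio (NMDA permeabilities follow automatically), and makes the
#' evolved HCN conductance scale the new baseline.
#'
#' @param model A `neuron_model`.
#' @param sim An [induce_plasticity()] result.
#' @return The updated model.
#' @export
apply_plasticity <- function(model, sim) {
  w_init <- model$syn$w
  model$syn$p_ampa <- model$syn$p_ampa * sim$w_final / w_init
  model$gh_scale <- sim$gh_scale_final
  model
}

#' Iterated induction with fixed stimulation pattern
#'
#' Repeats induction -> permeability update -> I/O profile for a number of
#' iterations, reusing the same spatio-temporal stimulation pattern and the
#' same profile trial substreams throughout. With `coupling = NULL` the model
#' is expected to lose firing at high stimulus frequencies over iterations
#' (depolarization-induced sodium channel block); with coupling at a suitable
#' slope the profile stays near baseline.
#'
#' @param model A baseline `neuron_model`.
#' @param iterations Number of induction iterations.
#' @param stimuli From [assign_induction_stimuli()].
#' @param coupling An [hcn_coupling()] applied at every iteration, `NULL`
#'   for synaptic plasticity only, or `"optimal"` to re-optimize the slope
#'   by RMSE minimization before every iteration (the optimal slope
#'   decreases as conductances grow across iterations; the search grid
#'   adapts around the previous optimum).
#' @param preset Study preset (profile grid, trials, induction duration).
#' @param seed Master seed for profile trials.
#' @param base_profile Optional precomputed baseline profile.
#' @return List: `base_profile`, per-iteration `profiles`, `rmse`, `mi`,
#'   `H`, `H_noise` (bits), `weights` (final weights per iteration),
#'   `gh_scale` trace.
#' @export
iterate <- function(model, iterations, stimuli, coupling = NULL,
                    preset = reduced_preset(), seed = 1,
                    base_profile = NULL) {
  if (is.null(base_profile)) {
    base_profile <- io_profile(model, preset$freqs, preset$trials, seed = seed)
  }
  profiles <- vector("list", iterations)
  rmses <- mis <- ghs <- h_resp <- h_noise <- numeric(iterations)
  weights <- matrix(NA_real_, nrow = max(1, nrow(model$syn)),
                    ncol = iterations)
  mi_range <- preset$mi_range
  resweep <- identical(coupling, "optimal")
  slopes <- rep(NA_real_, iterations)
  for (it in seq_len(iterations)) {
    if (resweep) {
      grid <- if (it == 1) preset$slope_grid
              else sort(unique(pmax(0, slopes[it - 1] * c(0.25, 0.5, 0.75, 1, 1.25))))
      opt <- optimize_slope(model, stimuli, "rmse_min", grid = grid,
                            preset = preset, seed = seed,
                            base_profile = base_profile, widen_retries = 1)
      slopes[it] <- opt$optimal_slope
      coupling_it <- hcn_coupling(opt$optimal_slope)
    } else {
      coupling_it <- coupling
      if (inherits(coupling, "hcn_coupling")) slopes[it] <- coupling$slope
    }
    sim <- induce_plasticity(model, stimuli, coupling = coupling_it,
                             duration_s = preset$induction_s)
    model <- apply_plasticity(model, sim)
    prof <- io_profile(model, preset$freqs, preset$trials, seed = seed)
    profiles[[it]] <- prof
    rmses[it] <- rmse(prof, base_profile)
    info <- profile_information(prof, preset$mi_bins, mi_range)
    mis[it] <- info$I_m
    h_resp[it] <- info$H
    h_noise[it] <- info$H_noise
    weights[, it] <- sim$w_final
    ghs[it] <- model$gh_scale
  }
  list(base_profile = base_profile, profiles = profiles, rmse = rmses,
       mi = mis, H = h_resp, H_noise = h_noise, weights = weights,
       gh_scale = ghs, slopes = slopes, model = model)
}

#' Optimize the coupling slope
#'
#' Sweeps the slope of the linear synaptic-to-HCN coupling over a grid,
#' running one induction + profile per slope, and returns the full objective
#' curve with its optimum (RMSE minimization against the baseline profile,
#' or mutual-information maximization). Ties break toward the smaller slope;
#' if the optimum lands on the grid boundary the grid is widened upward and
#' re-swept (bounded retries), and a boundary optimum after retries is
#' flagged.
#'
#' @param model A baseline `neuron_model`.
#' @param stimuli From [assign_induction_stimuli()].
#' @param objective `"rmse_min"` or `"mi_max"`.
#' @param grid Slope grid (non-negative, ascending).
#' @param preset Study preset.
#' @param seed Master seed for profile trials.
#' @param base_profile Optional precomputed baseline profile.
#' @param widen_retries Automatic grid-widening attempts on boundary optima.
#' @return List: `slopes`, `objective` values (RMSE in Hz, or MI in bits),
#'   `optimal_slope`, `boundary` flag, `base_profile`.
#' @export
optimize_slope <- function(model, stimuli, objective = c("rmse_min", "mi_max"),
                           grid = NULL, preset = reduced_preset(), seed = 1,
                           base_profile = NULL, widen_retries = 2) {
  objective <- match.arg(objective)
  if (is.null(grid)) grid <- preset$slope_grid
  stopifnot(length(grid) >= 1, all(grid >= 0), !is.unsorted(grid))
  if (is.null(base_profile)) {
    base_profile <- io_profile(model, preset$freqs, preset$trials, seed = seed)
  }
  mi_range <- preset$mi_range
  eval_slope <- function(s) {
    sim <- induce_plasticity(model, stimuli, coupling = hcn_coupling(s),
                             duration_s = preset$induction_s)
    prof <- io_profile(model, preset$freqs, preset$trials, seed = seed,
                       weights = sim$w_final, gh_scale = sim$gh_scale_final)
    if (objective == "rmse_min") rmse(prof, base_profile)
    else profile_information(prof, preset$mi_bins, mi_range)$I_m
  }
  vals <- vapply(grid, eval_slope, 0)
  for (r in seq_len(widen_retries)) {
    best <- if (objective == "rmse_min") which.min(vals) else which.max(vals)
    if (best < length(grid) || length(grid) == 1) break
    step <- if (length(grid) > 1) diff(tail(grid, 2)) else 1
    ext <- tail(grid, 1) + step * seq_len(max(2, length(grid) %/% 2))
    vals <- c(vals, vapply(ext, eval_slope, 0))
    grid <- c(grid, ext)
  }
  best <- if (objective == "rmse_min") which.min(vals) else which.max(vals)
  boundary <- best == length(grid) || (best == 1 && length(grid) > 1 &&
                                         grid[1] > 0)
  list(slopes = grid, objective = vals, optimal_slope = grid[best],
       boundary = boundary, base_profile = base_profile)
}

#' Sensitivity of the optimal slope to baseline conditions
#'
#' Rebuilds the baseline along one axis (uniform synaptic permeability
#' scaling, or baseline HCN conductance scaling), recomputes the baseline
#' profile, and re-optimizes the coupling slope at every axis value.
#'
#' @param model A baseline `neuron_model`.
#' @param axis `"synaptic_scale"` or `"h_baseline"`.
#' @param values Positive scale factors.
#' @param stimuli From [assign_induction_stimuli()].
#' @param preset Study preset.
#' @param seed Master seed.
#' @param grid Slope grid passed to [optimize_slope()].
#' @return List: `values`, `optimal_slopes`, per-value sweep results.
#' @export
sensitivity_sweep <- function(model, axis = c("synaptic_scale", "h_baseline"),
                              values, stimuli, preset = reduced_preset(),
                              seed = 1, grid = NULL) {
  axis <- match.arg(axis)
  stopifnot(all(values > 0))
  sweeps <- lapply(values, function(v) {
    m2 <- model
    if (axis == "synaptic_scale") {
      m2$syn$p_ampa <- m2$syn$p_ampa * v
    } else {
      m2$vec$gh <- m2$vec$gh * v
    }
    optimize_slope(m2, stimuli, "rmse_min", grid = grid, preset = preset,
                   seed = seed)
  })
  list(values = values,
       optimal_slopes = vapply(sweeps, `[[`, 0, "optimal_slope"),
       sweeps = sweeps)
}

#' Smoothed firing-rate profile from spike times
#'
#' Convolves spike times with a normalized Gaussian window; the profile
#' integrates to the spike count.
#'
#' @param spikes Spike times (ms).
#' @param duration_s Trace duration (s).
#' @param bin_ms Output grid spacing (ms).
#' @param sd_ms Gaussian SD (ms).
#' @return Data frame with `t` (s) and `rate` (Hz).
#' @export
rate_profile <- function(spikes, duration_s, bin_ms = 10, sd_ms = 300) {
  tt <- seq(bin_ms / 2, duration_s * 1000 - bin_ms / 2, by = bin_ms)
  rate <- numeric(length(tt))
  for (s in spikes) rate <- rate + dnorm(tt, s, sd_ms)
  data.frame(t = tt / 1000, rate = rate * 1000)
}

#' Build the place-field study model
#'
#' Theta-variant biophysics with two synapse populations on the apical
#' arbor: base theta synapses (AMPA only, non-plastic) driving the baseline
#' theta oscillation, and place theta synapses (AMPA+NMDA, plastic) driving
#' place-field activity, distributed over the same distance range.
#'
#' @param preset Study preset.
#' @return A tuned `neuron_model`; the place synapses are the rows of
#'   `model$syn` with `plastic = TRUE`.
#' @export
build_place_study <- function(preset = reduced_preset()) {
  model <- build_study(preset, theta = TRUE, synapses = FALSE)
  if (!is.null(preset$theta_gkdr)) {
    # the reduced model needs the stronger delayed rectifier to sustain
    # in-field firing without baseline depolarization block
    model$vec$gkdr <- ifelse(model$vec$gkdr > 0, preset$theta_gkdr, 0)
  }
  model <- place_synapses(model, preset$base_n, range = preset$syn_range,
                          nar = 0, plastic = FALSE)
  occupied <- model$syn$comp
  model <- place_synapses(model, preset$place_n, range = preset$syn_range,
                          nar = 1.5, plastic = TRUE, exclude = occupied)
  target <- ifelse(model$syn$plastic, preset$theta_place_epsp,
                   preset$theta_base_epsp)
  democracy_tune(model, target = target,
                 tol = target * max(0.05, preset$epsp_tol_frac))
}

#' Run the place-field protocol
#'
#' 10 s theta-driven run: base synapses active throughout, place synapses
#' and a calibrated asymmetric somatic ramp current active in the place
#' window (3-8 s). Only place synapses undergo plasticity (when enabled).
#' The smoothed rate profile is the place-field readout.
#'
#' @param model From [build_place_study()].
#' @param seed Integer seed for the theta event draws.
#' @param plasticity Enable weight updates on place synapses.
#' @param coupling An [hcn_coupling()] or `NULL`.
#' @param preset Study preset.
#' @param ramp Precomputed [ramp_current()] result (calibrated once and
#'   reused across conditions).
#' @return List of class `place_field_result`: `sim`, `spikes`, `profile`
#'   (smoothed rate), `peak_rate` (Hz), `w_final` of place synapses,
#'   `gh_scale_final`, `ramp`.
#' @export
place_field <- function(model, seed = 1, plasticity = FALSE, coupling = NULL,
                        preset = reduced_preset(), ramp = NULL) {
  stopifnot(!is.null(model$syn))
  dur <- preset$place_duration
  if (is.null(ramp)) {
    ramp <- ramp_current(model, window = preset$place_window, total_s = dur,
                         target_mV = preset$ramp_target)
  }
  syn <- model$syn
  events <- lapply(seq_len(nrow(syn)), function(s) {
    if (syn$plastic[s]) {
      theta_train(A = preset$theta_A, duration = dur,
                  seed = .trial_seed(seed, 8, 2, s),
                  window = preset$place_window)
    } else {
      theta_train(A = preset$theta_A, duration = dur,
                  seed = .trial_seed(seed, 8, 1, s))
    }
  })
  sim <- simulate(model, duration = dur * 1000, events = events,
                  plasticity = plasticity, coupling = coupling,
                  wave = list(comp = 1, i = ramp$wave), settle = 50)
  prof <- rate_profile(sim$spikes, dur, sd_ms = preset$smoothing_sd)
  structure(list(sim = sim, spikes = sim$spikes, profile = prof,
                 peak_rate = max(prof$rate),
                 w_final = sim$w_final[syn$plastic],
                 gh_scale_final = sim$gh_scale_final, ramp = ramp),
            class = "place_field_result")
}

#' Run the full place-field study
#'
#' Baseline run, uncoupled plasticity (induction run, permeability update,
#' measurement run), and coupled plasticity over a slope grid with the same
#' sequence; the place-field profile RMSE against baseline is the stability
#' measure and the slope minimizing it is the optimum.
#'
#' @param model From [build_place_study()].
#' @param seed Integer seed for theta event draws.
#' @param slope_grid Coupling slopes to evaluate.
#' @param preset Study preset.
#' @return List: `baseline`, `uncoupled`, `coupled` (per-slope results),
#'   `rmse_uncoupled`, `rmse_coupled`, `optimal_slope`, `ramp`.
#' @export
place_field_study <- function(model, seed = 1, slope_grid = c(1, 2.5, 5),
                              preset = reduced_preset()) {
  ramp <- ramp_current(model, window = preset$place_window,
                       total_s = preset$place_duration,
                       target_mV = preset$ramp_target)
  base <- place_field(model, seed = seed, plasticity = FALSE,
                      preset = preset, ramp = ramp)
  measure_after <- function(coupling) {
    ind <- place_field(model, seed = seed, plasticity = TRUE,
                       coupling = coupling, preset = preset, ramp = ramp)
    m2 <- apply_plasticity(model, ind$sim)
    post <- place_field(m2, seed = seed, plasticity = FALSE,
                        preset = preset, ramp = ramp)
    post$induction <- ind
    post
  }
  unc <- measure_after(NULL)
  cpl <- lapply(slope_grid, function(s) measure_after(hcn_coupling(s)))
  rms_c <- vapply(cpl, function(p) place_rmse(p, base), 0)
  list(baseline = base, uncoupled = unc, coupled = cpl,
       rmse_uncoupled = place_rmse(unc, base), rmse_coupled = rms_c,
       slope_grid = slope_grid,
       optimal_slope = slope_grid[which.min(rms_c)], ramp = ramp)
}

#' RMSE between two place-field rate profiles
#'
#' @param a,b [place_field()] results (or their `profile` data frames) on
#'   the same time grid.
#' @return RMSE (Hz).
#' @export
place_rmse <- function(a, b) {
  pa <- if (inherits(a, "place_field_result")) a$profile else a
  pb <- if (inherits(b, "place_field_result")) b$profile else b
  stopifnot(nrow(pa) == nrow(pb))
  sqrt(mean((pa$rate - pb$rate)^2))
}
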