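# Presynaptic event-time generators and somatic current waveforms.

#' Homogeneous Poisson event train
#'
#' @param rate Event rate (Hz), `>= 0`.
#' @param duration Duration (s).
#' @param seed Integer seed; identical seeds give identical trains.
#' @return Sorted event times (ms) in `[0, duration)`.
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  stopifnot(rate >= 0, duration > 0)
  if (rate == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  # draw exponential gaps until past the window
  t <- numeric(0)
  cur <- 0
  n_guess <- max(10, ceiling(rate * duration * 1.5 + 5 * sqrt(rate * duration)))
  repeat {
    gaps <- rexp(n_guess, rate)
    cum <- cur + cumsum(gaps)
    t <- c(t, cum[cum < duration])
    if (length(cum) && cum[length(cum)] >= duration) break
    cur <- cum[length(cum)]
  }
  t * 1000
}

#' Theta-modulated event train
#'
#' Events are drawn per theta cycle: the count is Poisson with mean `A`, and
#' event phases are Gaussian around each cycle midpoint with standard
#' deviation `sigma` (default one-eighth of the cycle), implementing a
#' Gaussian-modulated inhomogeneous point process at the theta frequency
#' (8 Hz by default, i.e. a 125 ms period).
#'
#' @param t_theta Theta period (ms).
#' @param sigma Phase SD (ms); defaults to `t_theta/8`.
#' @param A Scaling factor: mean events per synapse per cycle.
#' @param duration Duration (s).
#' @param seed Integer seed.
#' @param window Optional active window `c(t0, t1)` (s); events outside are
#'   dropped.
#' @return Sorted event times (ms).
#' @export
theta_train <- function(t_theta = 125, sigma = t_theta / 8, A = 1,
                        duration = 10, seed = NULL, window = NULL) {
  stopifnot(t_theta > 0, A >= 0, duration > 0)
  if (A == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  ncyc <- ceiling(duration * 1000 / t_theta)
  centers <- (seq_len(ncyc) - 0.5) * t_theta
  counts <- rpois(ncyc, A)
  t <- rep(centers, counts) + rnorm(sum(counts), 0, sigma)
  t <- sort(t[t >= 0 & t < duration * 1000])
  if (!is.null(window)) t <- t[t >= window[1] * 1000 & t < window[2] * 1000]
  t
}

#' Asymmetric somatic ramp current
#'
#' Builds an asymmetric triangular ramp (slow rise over `rise_frac` of the
#' window, fast fall over the rest) and calibrates its amplitude on the model
#' held at rest so the peak somatic depolarization matches `target_mV`.
#'
#' @param model A `neuron_model` (synapses, if any, are left silent during
#'   calibration).
#' @param window Ramp window `c(t0, t1)` (s).
#' @param total_s Total waveform duration (s).
#' @param target_mV Peak somatic depolarization (mV).
#' @param rise_frac Fraction of the window occupied by the rise.
#' @param tol_mV Calibration tolerance (mV).
#' @param max_iter Calibration iterations.
#' @return List: `wave` (nA at every engine step over `total_s`), `amplitude`
#'   (nA), `peak_mV` achieved, `window`.
#' @export
ramp_current <- function(model, window = c(3, 8), total_s = 10,
                         target_mV = 4, rise_frac = 0.8, tol_mV = 0.25,
                         max_iter = 6) {
  stopifnot(window[1] < window[2], window[2] <= total_s)
  dt <- model$dt
  nstep <- round(total_s * 1000 / dt)
  tms <- (seq_len(nstep) - 1) * dt
  t0 <- window[1] * 1000; t1 <- window[2] * 1000
  tpk <- t0 + rise_frac * (t1 - t0)
  shape <- numeric(nstep)
  rising <- tms >= t0 & tms < tpk
  falling <- tms >= tpk & tms < t1
  shape[rising] <- (tms[rising] - t0) / (tpk - t0)
  shape[falling] <- (t1 - tms[falling]) / (t1 - tpk)
  if (target_mV == 0) {
    return(list(wave = shape * 0, amplitude = 0, peak_mV = 0, window = window))
  }
  peak_of <- function(amp) {
    sim <- simulate(model, duration = total_s * 1000,
                    wave = list(comp = 1, i = shape * amp), settle = 200)
    if (length(sim$spikes) > 0) return(NA_real_)   # suprathreshold probe
    max(sim$soma_v) - sim$soma_v[1]
  }
  amp <- 0.02
  last_peak <- peak_of(amp)
  for (k in seq_len(6)) {
    if (!is.na(last_peak)) break
    amp <- amp / 4
    last_peak <- peak_of(amp)
  }
  if (is.na(last_peak)) stop("ramp calibration failed: spiking at all probes")
  if (last_peak <= 0) stop("ramp calibration failed: non-positive response")
  for (i in seq_len(max_iter)) {
    if (abs(last_peak - target_mV) <= tol_mV) break
    amp_new <- amp * target_mV / last_peak
    peak_new <- peak_of(amp_new)
    if (is.na(peak_new)) stop("ramp calibration evoked spikes; lower the target")
    if (amp_new > amp && peak_new < last_peak) {
      stop("ramp calibration failed: non-monotone response")
    }
    amp <- amp_new; last_peak <- peak_new
  }
  if (abs(last_peak - target_mV) > tol_mV) {
    stop("ramp calibration did not converge")
  }
  list(wave = shape * amp, amplitude = amp, peak_mV = last_peak,
       window = window)
}
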