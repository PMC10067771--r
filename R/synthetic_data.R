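# Synthetic response-profile fixtures: response matrices with prescribed
# marginal distributions of response frequency, for exercising the
# information and RMSE modules without running simulations.

#' Synthetic response-profile fixture
#'
#' Generates a response matrix whose trial-mean response frequencies follow
#' a named marginal distribution across stimuli (the distribution shapes the
#' iterated-plasticity study passes through: uniform at baseline, then
#' exponential, bimodal, lognormal), with Gaussian trial noise.
#'
#' @param shape `"uniform"`, `"exponential"`, `"bimodal"` or `"lognormal"`.
#' @param n_stim Number of stimulus frequencies.
#' @param trials Trials per stimulus.
#' @param sd Trial noise SD (Hz).
#' @param range Response-frequency range (Hz) spanned by the means.
#' @param seed Integer seed.
#' @return A `response_profile` whose `rf` matrix is non-negative.
#' @export
make_fixture_profile <- function(shape = c("uniform", "exponential",
                                           "bimodal", "lognormal"),
                                 n_stim = 50, trials = 10, sd = 2,
                                 range = c(1, 45), seed = 1) {
  shape <- match.arg(shape)
  set.seed(seed)
  u <- (seq_len(n_stim) - 0.5) / n_stim
  means <- switch(shape,
    uniform = range[1] + u * diff(range),
    exponential = range[1] + diff(range) * (1 - exp(-3 * u)) / (1 - exp(-3)),
    bimodal = {
      lo <- range[1] + 0.15 * diff(range); hi <- range[1] + 0.85 * diff(range)
      ifelse(u < 0.5, lo + (u - 0.25) * 0.3 * diff(range),
             hi + (u - 0.75) * 0.3 * diff(range))
    },
    lognormal = {
      q <- stats::qlnorm(u, meanlog = 0, sdlog = 0.6)
      range[1] + diff(range) * (q - min(q)) / (max(q) - min(q))
    })
  rf <- matrix(pmax(0, rep(means, trials) + rnorm(n_stim * trials, 0, sd)),
               n_stim, trials)
  structure(list(freqs = seq_len(n_stim), trials = trials, rf = rf,
                 seed = seed, shape = shape),
            class = "response_profile")
}
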