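# Rate-coding mutual information between stimulus frequency and response
# rate: Gaussian-smoothed conditional response distributions, response and
# noise entropies, and their difference.

#' Conditional response distributions p[r|s]
#'
#' For each stimulus frequency, the mean and standard deviation of the
#' response rates across trials parameterize a Gaussian evaluated at the
#' response-bin centers and renormalized over the grid (tail mass outside the
#' grid is folded back in by the normalization). A zero-SD stimulus places
#' all mass on the nearest bin.
#'
#' @param profile A `response_profile` (needs at least 2 trials).
#' @param bins Response bin centers (Hz); 1 Hz bins spanning 1-100 Hz by
#'   default.
#' @return Matrix p[r|s], rows = stimuli, columns = bins; each row sums to 1.
#' @export
conditional_distributions <- function(profile, bins = 1:100) {
  stopifnot(inherits(profile, "response_profile"))
  rf <- profile$rf
  if (ncol(rf) < 2) stop("need at least 2 trials per stimulus")
  p <- matrix(0, nrow(rf), length(bins))
  for (i in seq_len(nrow(rf))) {
    m <- mean(rf[i, ]); s <- sd(rf[i, ])
    if (!is.finite(s) || s < 1e-12) {
      p[i, which.min(abs(bins - m))] <- 1
    } else {
      row <- dnorm(bins, m, s)
      p[i, ] <- row / sum(row)
    }
  }
  rownames(p) <- profile$freqs
  p
}

.xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Mutual information from conditional response distributions
#'
#' Computes the marginal response distribution `p[r] = sum_s p[r|s] p[s]`,
#' the total response entropy `H = -sum_r p[r] log2 p[r]`, the noise entropy
#' `H_noise = sum_s p[s] H_s` with `H_s` the entropy of row s, and the
#' mutual information `I_m = H - H_noise`.
#'
#' @param p_rs Conditional distribution matrix (rows = stimuli, each summing
#'   to 1).
#' @param p_s Stimulus distribution; uniform by default.
#' @return Object of class `info_result`: `H`, `H_noise`, `I_m` (bits),
#'   `p_r`, `p_s`, and the input `p_rs`.
#' @export
mutual_information <- function(p_rs, p_s = NULL) {
  p_rs <- as.matrix(p_rs)
  if (any(abs(rowSums(p_rs) - 1) > 1e-6)) {
    stop("rows of p[r|s] must each sum to 1")
  }
  ns <- nrow(p_rs)
  if (is.null(p_s)) p_s <- rep(1 / ns, ns)
  if (abs(sum(p_s) - 1) > 1e-6) stop("p[s] must sum to 1")
  p_r <- as.numeric(t(p_rs) %*% p_s)
  H <- -sum(.xlogx(p_r))
  Hs <- -rowSums(.xlogx(p_rs))
  H_noise <- sum(p_s * Hs)
  structure(list(H = H, H_noise = H_noise, I_m = H - H_noise,
                 p_r = p_r, p_s = p_s, p_rs = p_rs),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("mutual information: %.4f bits (H = %.4f, H_noise = %.4f)\n",
              x$I_m, x$H, x$H_noise))
  invisible(x)
}

#' Mutual information of a response profile
#'
#' Convenience wrapper: conditional distributions on a 1-100 Hz response
#' grid, optionally restricted to a stimulus-frequency subrange, then
#' [mutual_information()].
#'
#' @param profile A `response_profile`.
#' @param bins Response bin centers (Hz).
#' @param freq_range Optional stimulus frequency range `c(min, max)` (Hz);
#'   e.g. restrict to 10-50 Hz for the information-maximization variant.
#' @return An `info_result`.
#' @export
profile_information <- function(profile, bins = 1:100, freq_range = NULL) {
  if (!is.null(freq_range)) {
    keep <- profile$freqs >= freq_range[1] & profile$freqs <= freq_range[2]
    profile <- structure(list(freqs = profile$freqs[keep],
                              trials = profile$trials,
                              rf = profile$rf[keep, , drop = FALSE]),
                         class = "response_profile")
  }
  mutual_information(conditional_distributions(profile, bins))
}
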