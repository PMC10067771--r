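# Small text-format exporters for simulation artifacts.

#' Write recorded voltage traces as CSV
#'
#' Time (ms) plus the somatic trace and any recorded compartments.
#'
#' @param sim A [simulate()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  out <- data.frame(t_ms = sim$t, soma_mV = sim$soma_v)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the plasticity event log as CSV
#'
#' Decimated weight and calcium-shell trajectories of every synapse during a
#' plasticity run: one row per (time, synapse).
#'
#' @param sim A [simulate()] result from a run with `plasticity = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plasticity_log <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  w <- sim$w_trace
  if (is.null(dim(w)) || ncol(w) == 0) stop("run had no plasticity traces")
  tt <- (seq_len(ncol(w)) - 1) * sim$dt * sim$w_stride
  out <- data.frame(t_ms = rep(tt, each = nrow(w)),
                    synapse = rep(seq_len(nrow(w)), times = ncol(w)),
                    w = as.vector(w),
                    ca_mM = as.vector(sim$ca_trace))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the HCN conductance-scale trace as CSV
#'
#' @param sim A [simulate()] result from a run with an active coupling.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gh_trace <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  write.csv(data.frame(t_ms = sim$gh_t, gh_scale = sim$gh_scale_trace),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize an information result as JSON
#'
#' Entropies, mutual information and the marginal response distribution
#' (the conditional matrix is written alongside as CSV if `p_rs_csv` is
#' given).
#'
#' @param info An [mutual_information()] result.
#' @param path Output JSON path.
#' @param p_rs_csv Optional CSV path for the conditional matrix p[r|s].
#' @return `path`, invisibly.
#' @export
write_info <- function(info, path, p_rs_csv = NULL) {
  stopifnot(inherits(info, "info_result"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_info() needs the jsonlite package")
  }
  jsonlite::write_json(list(H = info$H, H_noise = info$H_noise,
                            I_m = info$I_m, p_r = info$p_r,
                            p_s = info$p_s),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(p_rs_csv)) write.csv(info$p_rs, p_rs_csv, row.names = FALSE)
  invisible(path)
}
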