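test_that("induction stimuli are seeded, in-range, and reusable", {
  mod <- fixture("model")
  st <- assign_induction_stimuli(mod, duration_s = 5, seed = 21)
  expect_length(st$freqs, nrow(mod$syn))
  expect_true(all(st$freqs >= 4 & st$freqs <= 12))
  expect_true(all(unlist(st$events) >= 0 & unlist(st$events) < 5000))
  st2 <- assign_induction_stimuli(mod, duration_s = 5, seed = 21)
  expect_identical(st, st2)
})

test_that("silent induction leaves weights and HCN conductance untouched", {
  mod <- fixture("model")
  quiet <- list(freqs = rep(0, nrow(mod$syn)),
                events = replicate(nrow(mod$syn), numeric(0), simplify = FALSE))
  sim <- induce_plasticity(mod, quiet, coupling = hcn_coupling(3.5),
                           duration_s = 3)
  expect_true(all(abs(sim$w_final - 0.25) < 1e-4))
  expect_equal(sim$gh_scale_final, 1, tolerance = 1e-9)
})

test_that("folding plasticity into the model preserves the drive", {
  mod <- fixture("model")
  st <- fixture("stimuli")
  sim <- induce_plasticity(mod, st, duration_s = fixture("preset")$induction_s)
  m2 <- apply_plasticity(mod, sim)
  expect_equal(m2$syn$w, mod$syn$w)                       # weights reset
  expect_equal(m2$syn$p_ampa, mod$syn$p_ampa * sim$w_final / 0.25)
  # equivalent drive: profile with folded permeabilities matches the profile
  # with explicit weights
  p1 <- io_profile(mod, freqs = c(8, 16), trials = 2, seed = 30,
                   weights = sim$w_final)
  p2 <- io_profile(m2, freqs = c(8, 16), trials = 2, seed = 30)
  expect_identical(p1$rf, p2$rf)
})

test_that("a degenerate slope grid is returned as a flagged boundary", {
  mod <- fixture("model")
  st <- fixture("stimuli")
  pre <- fixture("preset")
  pre$freqs <- c(8, 16); pre$trials <- 2; pre$induction_s <- 3
  opt <- optimize_slope(mod, st, "rmse_min", grid = 2, preset = pre,
                        seed = 31, widen_retries = 0)
  expect_equal(opt$optimal_slope, 2)
  expect_true(opt$boundary)
  expect_length(opt$objective, 1)
})

test_that("rate profiles integrate to the spike count", {
  sp <- c(500, 1500, 1520, 4000, 7800)
  pr <- rate_profile(sp, duration_s = 10, bin_ms = 10, sd_ms = 300)
  expect_true(all(pr$rate >= 0))
  expect_equal(sum(pr$rate) * 0.01, length(sp), tolerance = 0.01)
  expect_equal(nrow(pr), 1000)
  expect_length(rate_profile(numeric(0), 10)$rate, 1000)
})

test_that("place study populations follow the preset layout", {
  pmod <- fixture("place_model")
  pre <- fixture("preset")
  syn <- pmod$syn
  expect_equal(sum(!syn$plastic), pre$base_n)
  expect_equal(sum(syn$plastic), pre$place_n)
  expect_true(all(syn$nar[!syn$plastic] == 0))     # base: AMPA only
  expect_true(all(syn$nar[syn$plastic] == 1.5))    # place: AMPA + NMDA
  expect_true(all(syn$x >= 12.5 & syn$x <= 286.7))
  expect_false(any(duplicated(syn$comp)))
})

test_that("baseline place-field activity is sparse outside the field", {
  st <- fixture("place_study")
  base <- st$baseline
  inside <- in_field(base$spikes)
  outside <- length(base$spikes) - inside
  expect_gt(inside, 10)
  expect_lt(outside, inside / 4)
  # in-field membrane potential is depolarized by the ramp + place drive
  v <- base$sim$soma_v
  dt <- base$sim$dt
  mid <- function(a, b) mean(v[(a / dt):(b / dt)])
  depol <- mid(4000, 7000) - mid(500, 2500)
  expect_gt(depol, 2)
  # no depolarization block at baseline: firing persists to the field's end
  expect_gt(sum(base$spikes >= 7000 & base$spikes < 8000), 0)
  # the calibrated ramp itself peaks around 4 mV
  expect_equal(st$ramp$peak_mV, 4, tolerance = 0.125)
})

test_that("plasticity and conductance traces export as CSV logs", {
  mod <- fixture("model")
  st <- fixture("stimuli")
  sim <- induce_plasticity(mod, st, coupling = hcn_coupling(2),
                           duration_s = 2)
  fw <- withr::local_tempfile(fileext = ".csv")
  fg <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".csv")
  write_plasticity_log(sim, fw)
  write_gh_trace(sim, fg)
  write_traces(sim, ft)
  lg <- read.csv(fw)
  expect_true(all(c("t_ms", "synapse", "w", "ca_mM") %in% names(lg)))
  expect_equal(length(unique(lg$synapse)), nrow(mod$syn))
  gh <- read.csv(fg)
  expect_equal(nrow(gh), length(sim$gh_t))
  expect_equal(nrow(read.csv(ft)), length(sim$soma_v))
})
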