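test_that("magnesium block matches its closed form and is monotone", {
  expect_equal(mg_block(0), 1 / (1 + 2 / 3.57), tolerance = 1e-12)
  expect_equal(mg_block(0), 0.6409, tolerance = 1e-4)
  expect_equal(mg_block(-65), 1 / (1 + 2 * exp(0.062 * 65) / 3.57),
               tolerance = 1e-12)
  expect_equal(mg_block(-65), 0.0307, tolerance = 1e-2)
  expect_equal(mg_block(1e4), 1)
  v <- seq(-120, 60, 1)
  b <- mg_block(v)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
  expect_equal(mg_block(-65, mg_o = 0), 1)
})

test_that("double-exponential gating peaks at exactly 1 at its argmax", {
  expect_equal(gating_s(0, 5, 50), 0)
  tstar <- log(50 / 5) * 5 * 50 / (50 - 5)
  expect_equal(tstar, 12.79, tolerance = 1e-3)
  expect_equal(gating_s(tstar, 5, 50), 1, tolerance = 1e-12)
  # interior maximum: nearby lags are below 1
  expect_lt(gating_s(tstar - 1, 5, 50), 1)
  expect_lt(gating_s(tstar + 1, 5, 50), 1)
  expect_lt(gating_s(1e4, 5, 50), 1e-10)
  # AMPA kinetics peak at their own argmax
  ta <- log(10 / 2) * 2 * 10 / (10 - 2)
  expect_equal(gating_s(ta, 2, 10), 1, tolerance = 1e-12)
  # superposition is additive over events
  ev <- c(0, 3, 9)
  s <- gating_s(15, 5, 50, events = ev)
  expect_equal(s, sum(gating_s(15 - ev, 5, 50)), tolerance = 1e-12)
  expect_error(gating_s(1, 50, 5))
})

test_that("periodic stimulation reaches a sublinear periodic steady state", {
  for (f in c(5, 20)) {
    period <- 1000 / f
    ev <- seq(0, 5000, by = period)
    tt <- seq(4000, 5000, by = 0.5)
    s <- gating_s(tt, 5, 50, events = ev)
    # period-1/f steady state
    expect_equal(gating_s(4500, 5, 50, events = ev),
                 gating_s(4500 + period, 5, 50, events = ev),
                 tolerance = 1e-6)
    # amplitude grows sublinearly with rate
    if (f == 5) s5 <- max(s) else s20 <- max(s)
  }
  expect_lt(s20 / s5, 4)
  expect_gt(s20 / s5, 1)
})

test_that("receptor current components vanish and scale as GHK dictates", {
  kc <- physical_constants()
  e_na <- 1e3 * kc$gas * kc$temp_K / kc$faraday * log(kc$na_o / kc$na_i)
  at_ena <- receptor_currents(e_na, s_ampa = 0.5, s_nmda = 0.5, w = 0.5,
                              p_ampa = 1e-6)
  expect_equal(at_ena$i_nmda_na, 0, tolerance = 1e-15)
  expect_equal(at_ena$i_ampa_na, 0, tolerance = 1e-15)
  # zero weight silences AMPA only
  w0 <- receptor_currents(-60, 0.5, 0.5, w = 0, p_ampa = 1e-6)
  expect_equal(w0$i_ampa_na, 0)
  expect_equal(w0$i_ampa_k, 0)
  expect_true(w0$i_nmda_ca != 0)
  # linearity in maximum permeability
  a <- receptor_currents(-60, 0.5, 0.5, 0.5, p_ampa = 1e-6, p_nmda = 1e-6)
  b <- receptor_currents(-60, 0.5, 0.5, 0.5, p_ampa = 1e-6, p_nmda = 2e-6)
  for (comp in c("i_nmda_na", "i_nmda_k", "i_nmda_ca")) {
    expect_equal(b[[comp]], 2 * a[[comp]], tolerance = 1e-12, info = comp)
  }
  # total NMDA current reverses near 0 mV for the stated concentration set
  i_tot <- function(v) {
    r <- receptor_currents(v, 0, 1, 0, p_ampa = 1e-6)
    r$i_nmda_na + r$i_nmda_k + r$i_nmda_ca
  }
  expect_lt(i_tot(-5), 0)
  expect_gt(i_tot(5), 0)
})

test_that("calcium shell relaxes analytically and respects its fixed point", {
  p <- calcium_params()
  # resting fixed point
  expect_equal(step_calcium(1e-4, 0, 0, dt = 5), 1e-4)
  # pure exponential decay from 2e-4 over one time constant
  expect_equal(step_calcium(2e-4, 0, 0, dt = 30), 1e-4 + 1e-4 / exp(1),
               tolerance = 1e-12)
  # constant influx settles at ca_inf + tau * influx
  i_ca <- -1e-4   # mA/cm2, inward
  influx <- -1e4 * i_ca / (3.6 * p$depth * physical_constants()$faraday)
  ca <- 1e-4
  for (k in 1:400) ca <- step_calcium(ca, i_ca, 0, dt = 5)
  expect_equal(ca, p$ca_inf + p$tau_ca * influx, tolerance = 1e-6)
  # outward flux clamps at zero with a warning
  expect_warning(out <- step_calcium(1e-5, 1, 0, dt = 30), "clamped")
  expect_equal(out, 0)
})
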