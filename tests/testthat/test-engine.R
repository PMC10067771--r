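test_that("an unstimulated balanced model stays at its holding potential", {
  mod <- build_model(compartmentalize(make_morphology(seed = 3)))
  sim <- simulate(mod, duration = 500)
  expect_lt(max(abs(sim$soma_v - (-65))), 0.5)
  expect_length(sim$spikes, 0)
  # charge drift over 1 s with all active conductances removed
  pas <- build_model(compartmentalize(make_morphology(seed = 3)),
                     passive_only = TRUE)
  simp <- simulate(pas, duration = 1000)
  expect_lt(max(abs(simp$soma_v - (-65))), 0.065)  # < 0.1% of 65 mV
})

test_that("identical seed and configuration reproduce spike times exactly", {
  mod <- fixture("model")
  nsyn <- nrow(mod$syn)
  ev <- lapply(seq_len(nsyn), function(s) poisson_train(8, 0.6, seed = 40 + s))
  s1 <- simulate(mod, duration = 600, events = ev, ampa_only = TRUE)
  s2 <- simulate(mod, duration = 600, events = ev, ampa_only = TRUE)
  expect_identical(s1$soma_v, s2$soma_v)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("the classic soma fires repetitively and converges in dt", {
  mod <- soma_only_model(gna = 16, gkdr = 10)
  inj <- data.frame(comp = 1, amp = 0.1, t0 = 0, t1 = 1000)
  sim <- simulate(mod, duration = 1000, inj = inj)
  expect_gt(length(sim$spikes), 10)
  # spike count stable when dt is halved
  mod2 <- mod
  mod2$vec$dt <- mod$dt / 2
  mod2$dt <- mod$dt / 2
  sim2 <- simulate(mod2, duration = 1000, inj = inj)
  expect_lte(abs(length(sim$spikes) - length(sim2$spikes)), 1)
})

test_that("single-compartment dynamics match a high-accuracy reference", {
  skip_if_not_installed("deSolve")
  mod <- soma_only_model(gna = 16, gkdr = 10)
  cfg <- channel_config()
  cp <- mod$comps
  gpas <- 1 / cp$Rm
  # leak balanced exactly as the engine does at -65 mV
  v0 <- -65
  iion0 <- 16 * gate_kinetics("na", "m", v0, cfg)$inf^3 *
    gate_kinetics("na", "h", v0, cfg)$inf * (v0 - 55) +
    10 * gate_kinetics("kdr", "n", v0, cfg)$inf * (v0 + 90)
  epas <- v0 + iion0 / gpas
  amp <- 0.1
  i_dens <- amp * 1e-3 / cp$area   # uA/cm2
  deriv <- function(t, y, parms) {
    v <- y[1]
    m <- gate_kinetics("na", "m", v, cfg)
    h <- gate_kinetics("na", "h", v, cfg)
    nn <- gate_kinetics("kdr", "n", v, cfg)
    iion <- 16 * y[2]^3 * y[3] * (v - 55) + 10 * y[4] * (v + 90) +
      gpas * (v - epas)
    list(c((-iion + i_dens) / cp$Cm,
           (m$inf - y[2]) / m$tau,
           (h$inf - y[3]) / h$tau,
           (nn$inf - y[4]) / nn$tau))
  }
  y0 <- c(v0,
          gate_kinetics("na", "m", v0, cfg)$inf,
          gate_kinetics("na", "h", v0, cfg)$inf,
          gate_kinetics("kdr", "n", v0, cfg)$inf)
  out <- deSolve::lsoda(y0, seq(0, 1000, by = 0.05), deriv, NULL,
                        rtol = 1e-8, atol = 1e-8)
  ref_spikes <- detect_spikes(out[, 2], dt = 0.05)
  sim <- simulate(mod, duration = 1000,
                  inj = data.frame(comp = 1, amp = amp, t0 = 0, t1 = 1000))
  expect_lte(abs(length(sim$spikes) - length(ref_spikes)), 1)
})

test_that("passive cylinder input resistance matches the sealed-end cable", {
  Rm <- 30; Ra <- 150; d_um <- 2; L_um <- 400
  m <- cylinder_morphology(L = L_um, diam = d_um, soma = 1, step = 10)
  tr <- compartmentalize(m, uniform_passive(Rm = Rm, Ra = Ra))
  mod <- build_model(tr, passive_only = TRUE)
  got <- input_resistance(mod, comp = 1, amps_pA = seq(-10, 10, 2),
                          pulse_ms = 400)
  # analytic sealed-end solution: R_inf * coth(L/lambda)
  Rm_cgs <- Rm * 1000          # Ohm cm2
  d <- d_um * 1e-4; L <- L_um * 1e-4
  lambda <- sqrt((Rm_cgs / Ra) * d / 4)
  R_inf <- (2 / pi) * sqrt(Rm_cgs * Ra) * d^(-3 / 2)
  R_analytic <- R_inf / tanh(L / lambda) / 1e6   # MOhm
  expect_equal(got$rin, R_analytic, tolerance = 0.01)
  expect_gt(got$r2, 0.99)
})

test_that("spike detection applies threshold and refractory rules", {
  dt <- 0.1
  flat <- rep(-65, 1000)
  expect_length(detect_spikes(flat, dt), 0)
  # synthetic 10-spike train crossing 0 mV
  v <- rep(-65, 5000)
  at <- seq(200, 4700, length.out = 10)
  for (i in at) v[i:(i + 5)] <- 10
  sp <- detect_spikes(v, dt, threshold = 0)
  expect_length(sp, 10)
  expect_equal(sp, at * dt, tolerance = 1e-9)
  expect_true(all(diff(sp) > 0))
  # two crossings 1 ms apart merge under a 2 ms refractory
  v2 <- rep(-65, 100)
  v2[20:22] <- 0; v2[30:32] <- 0
  expect_length(detect_spikes(v2, dt, threshold = -20, refractory = 2), 1)
  expect_length(detect_spikes(v2, dt, threshold = -20, refractory = 0.5), 2)
})

test_that("numerical divergence is reported with a diagnostic", {
  mod <- soma_only_model()
  inj <- data.frame(comp = 1, amp = Inf, t0 = 0, t1 = 100)
  expect_error(simulate(mod, duration = 100, inj = inj), "divergence")
})
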