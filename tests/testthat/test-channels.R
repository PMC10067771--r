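test_that("channel gradient densities match their closed forms", {
  expect_equal(gradient_density("KA", 0), 3.1)
  # sigmoid midpoint of the HCN gradient: 25 * (1 + 12/2)
  expect_equal(gradient_density("HCN", 320), 175)
  # CaT asymptote: 80 * (1 + 30)
  expect_equal(gradient_density("CaT", 1e9), 2480, tolerance = 1e-9)
  # continuity and monotone non-decrease over the apical extent
  x <- seq(0, 600, by = 1)
  for (ch in c("KA", "HCN", "CaT")) {
    g <- gradient_density(ch, x)
    expect_true(all(diff(g) >= 0), info = ch)
    expect_true(all(is.finite(g)), info = ch)
  }
  expect_error(gradient_density("Kv7", 10), "unknown channel")
})

test_that("HCN half-activation voltage is piecewise linear in distance", {
  expect_equal(hcn_half_activation(50), -82)
  expect_equal(hcn_half_activation(200), -86)
  expect_equal(hcn_half_activation(400), -90)
  x <- seq(0, 500, by = 0.5)
  v <- hcn_half_activation(x)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= -90 & v <= -82))
})

test_that("A-type K model selection splits at 100 um", {
  expect_equal(ka_model_select(0), "proximal")
  expect_equal(ka_model_select(100), "distal")
  expect_equal(ka_model_select(250), "distal")
  expect_equal(ka_model_select(99.999), "proximal")
})

test_that("GHK flux obeys Nernst zero, the v->0 limit, and monotonicity", {
  kc <- physical_constants()
  # zero crossing at the Nernst potential
  e_na <- 1e3 * kc$gas * kc$temp_K / kc$faraday * log(kc$na_o / kc$na_i)
  expect_equal(ghk_flux(e_na, 1, kc$na_i, kc$na_o), 0, tolerance = 1e-9)
  e_ca <- 1e3 * kc$gas * kc$temp_K / (2 * kc$faraday) * log(kc$ca_o / kc$ca_i)
  expect_equal(ghk_flux(e_ca, 2, kc$ca_i, kc$ca_o, P = 1e-5), 0,
               tolerance = 1e-12)
  # v -> 0 limit: P z F (Ci - Co), concentrations in mol/cm3, result mA/cm2
  lim <- 1 * 1 * kc$faraday * (18e-6 - 140e-6) * 1e3
  expect_equal(ghk_flux(0, 1, 18, 140), lim, tolerance = 1e-6)
  expect_equal(ghk_flux(1e-9, 1, 18, 140), lim, tolerance = 1e-3)
  # symmetric concentrations give an ohmic (linear, odd) response
  v <- seq(-80, 80, by = 5)
  i_sym <- ghk_flux(v, 1, 50, 50)
  expect_equal(i_sym, -rev(i_sym), tolerance = 1e-9)
  # strictly increasing in v for fixed positive concentrations
  i_na <- ghk_flux(seq(-100, 100, 1), 1, 18, 140)
  expect_true(all(diff(i_na) > 0))
  i_ca <- ghk_flux(seq(-100, 100, 1), 2, 1e-4, 2)
  expect_true(all(diff(i_ca) > 0))
})

test_that("gating curves are proper steady states with positive taus", {
  cfg <- channel_config()
  v <- seq(-120, 60, by = 0.5)
  gates <- list(c("na", "m"), c("na", "h"), c("na", "s"), c("kdr", "n"),
                c("kap", "n"), c("kap", "l"), c("kad", "n"), c("kad", "l"),
                c("hd", "l"), c("cat", "m"), c("cat", "h"))
  for (g in gates) {
    k <- gate_kinetics(g[1], g[2], v, cfg)
    expect_true(all(k$inf >= 0 & k$inf <= 1), info = paste(g, collapse = "/"))
    expect_true(all(k$tau > 0), info = paste(g, collapse = "/"))
  }
  # HCN activates on hyperpolarization; its half-activation shifts with the
  # supplied per-location V1/2
  hd <- gate_kinetics("hd", "l", c(-120, -40), cfg)
  expect_gt(hd$inf[1], 0.95)
  expect_lt(hd$inf[2], 0.05)
  h1 <- gate_kinetics("hd", "l", -86, cfg, hd_vhalf = -82)$inf
  h2 <- gate_kinetics("hd", "l", -86, cfg, hd_vhalf = -90)$inf
  expect_gt(h1, 0.5)
  expect_lt(h2, 0.5)
  expect_error(gate_kinetics("na", "z", -60, cfg), "no gate")
})
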