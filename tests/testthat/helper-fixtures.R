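# Shared fixtures, built lazily and cached for the whole test run. The
# reduced-preset study model and the protocol results derived from it are
# expensive, so every test file pulls them from this cache.

.fx <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  pre <- if (name != "preset") fixture("preset") else NULL
  val <- switch(name,
    preset = reduced_preset(),
    model = build_study(pre),
    stimuli = assign_induction_stimuli(fixture("model"), pre$induction_s,
                                       seed = 7),
    base_profile = io_profile(fixture("model"), pre$freqs, pre$trials,
                              seed = 11),
    uncoupled = iterate(fixture("model"), 4, fixture("stimuli"),
                        coupling = NULL, preset = pre, seed = 11,
                        base_profile = fixture("base_profile")),
    slope_sweep = optimize_slope(fixture("model"), fixture("stimuli"),
                                 "rmse_min", preset = pre, seed = 11,
                                 base_profile = fixture("base_profile")),
    coupled = {
      pre2 <- pre
      pre2$slope_grid <- c(0, 2.5, 5, 7.5, 10, 15)
      iterate(fixture("model"), 3, fixture("stimuli"),
              coupling = "optimal", preset = pre2, seed = 11,
              base_profile = fixture("base_profile"))
    },
    place_model = build_place_study(pre),
    place_study = place_field_study(fixture("place_model"), seed = 5,
                                    slope_grid = c(1, 2.5, 5), preset = pre),
    stop("unknown fixture: ", name))
  .fx[[name]] <- val
  val
}

# soma-only morphology (single compartment after discretization)
soma_morphology <- function(L = 20, diam = 20) {
  structure(list(soma = list(L = L, diam = diam, center = c(0, 0, 0)),
                 sections = list()),
            class = "neuro_morphology")
}

# unbranched apical cylinder on a vanishingly small soma stub
cylinder_morphology <- function(L = 400, diam = 2, soma = 1, step = 20) {
  y <- seq(soma / 2, soma / 2 + L, by = step)
  pts <- cbind(x = 0, y = y, z = 0, diam = diam)
  structure(list(soma = list(L = soma, diam = soma, center = c(0, 0, 0)),
                 sections = list(list(id = 1L, region = "apical",
                                      parent = 0L, points = pts))),
            class = "neuro_morphology")
}

# uniform passive parameters (gradients flattened)
uniform_passive <- function(Rm = 30, Ra = 150, Cm = 1) {
  p <- passive_params()
  p$Rm_max <- Rm; p$Rm_min <- Rm
  p$Ra_max <- Ra; p$Ra_min <- Ra
  p$Cm <- Cm
  p
}

# single-compartment model with only Na + KDR + leak (classic soma test)
soma_only_model <- function(gna = 16, gkdr = 10) {
  tr <- compartmentalize(soma_morphology())
  mod <- build_model(tr)
  mod$vec$gka[] <- 0
  mod$vec$gh[] <- 0
  mod$vec$pcat[] <- 0
  mod$vec$gna[] <- gna
  mod$vec$gkdr[] <- gkdr
  mod
}

in_field <- function(spikes, window = c(3000, 8000)) {
  sum(spikes >= window[1] & spikes < window[2])
}
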