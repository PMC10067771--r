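test_that("SWC round trips through parsing with correct geometry", {
  swc <- c("# toy neuron",
           "1 1 0 0 0 5 -1",
           "2 4 0 10 0 1 1",
           "3 4 0 22 0 1 2")
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc, f)
  m <- load_swc(f)
  expect_s3_class(m, "neuro_morphology")
  expect_length(m$sections, 1)
  expect_equal(m$sections[[1]]$region, "apical")
  # section length equals the Euclidean distance between its own points
  pts <- m$sections[[1]]$points
  expect_equal(sqrt(sum((pts[2, 1:3] - pts[1, 1:3])^2)), 12)
  # equivalent-area soma: sphere of radius 5 -> cylinder with L = diam
  expect_equal(m$soma$L, m$soma$diam)
  expect_equal(pi * m$soma$diam * m$soma$L, 4 * pi * 25, tolerance = 1e-10)
})

test_that("malformed SWC rows give descriptive parse errors", {
  write_tmp <- function(lines) {
    f <- withr::local_tempfile(fileext = ".swc", .local_envir = parent.frame())
    writeLines(lines, f)
    f
  }
  expect_error(load_swc(write_tmp(c("1 1 0 0 0 5 -1", "2 4 0 10 0 1 7"))),
               "parent id 7 not defined")
  expect_error(load_swc(write_tmp(c("1 1 0 0 0 5 -1", "2 4 0 10 0 0 1"))),
               "non-positive radius")
  expect_error(load_swc(write_tmp(c("1 1 0 0 0 5 -1", "2 4 0 10 0 1"))),
               "expected 7 columns")
  expect_error(load_swc(write_tmp("2 4 0 10 0 1 -1")), "no soma")
})

test_that("passive resistivity gradient matches its closed form", {
  # sigmoid midpoint: (125 + 85)/2
  expect_equal(assign_passive(300, which = "Rm"), 105)
  # somatic value: 125 - 40/(1 + e^6)
  expect_equal(assign_passive(0, which = "Rm"), 125 - 40 / (1 + exp(6)),
               tolerance = 1e-12)
  # distal asymptote
  expect_equal(assign_passive(1e7, which = "Rm"), 85, tolerance = 1e-6)
  # monotone decreasing and bounded
  x <- seq(0, 800, by = 5)
  rm <- assign_passive(x, which = "Rm")
  ra <- assign_passive(x, which = "Ra")
  expect_true(all(diff(rm) < 0))
  expect_true(all(rm <= 125 & rm >= 85))
  expect_true(all(ra <= 120 & ra >= 70))
  expect_error(assign_passive(-1))
})

test_that("d_lambda rule produces the odd compartment counts of cable theory", {
  # cylinder exactly one lambda_100 long -> ratio 10 -> 11 compartments
  p <- uniform_passive(Rm = 30, Ra = 150)
  lam <- 1e5 * sqrt(2 / (4 * pi * 100 * 150 * 1))
  m <- cylinder_morphology(L = lam, diam = 2, soma = 1, step = lam / 40)
  tr <- compartmentalize(m, p)
  expect_equal(sum(tr$comps$region == "apical"), 11)
  # much shorter than 0.1 lambda -> single compartment
  m2 <- cylinder_morphology(L = lam / 50, diam = 2, soma = 1, step = lam / 200)
  tr2 <- compartmentalize(m2, p)
  expect_equal(sum(tr2$comps$region == "apical"), 1)
  # every compartment respects the local d_lambda bound
  tr3 <- compartmentalize(make_morphology(seed = 3))
  cp <- tr3$comps[tr3$comps$region != "soma", ]
  lam_loc <- 1e5 * sqrt(cp$diam / (4 * pi * 100 * cp$Ra * cp$Cm))
  expect_true(all(cp$L <= 0.1 * lam_loc * 1.0001))
  # re-application is deterministic
  tr4 <- compartmentalize(make_morphology(seed = 3))
  expect_identical(tr3$comps, tr4$comps)
})

test_that("compartment areas integrate the frustum surface exactly", {
  m <- make_morphology(seed = 5)
  tr <- compartmentalize(m)
  for (s in m$sections) {
    pts <- s$points
    n <- nrow(pts)
    h <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] -
                         pts[-n, 1:3, drop = FALSE])^2))
    r1 <- pts[-n, 4] / 2; r2 <- pts[-1, 4] / 2
    frustum <- sum(pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)) * 1e-8
    got <- sum(tr$comps$area[tr$comps$section == s$id])
    expect_equal(got, frustum, tolerance = 1e-3)
  }
})

test_that("synthetic morphology hits the apical extent and round trips", {
  m <- make_morphology(seed = 1)
  tr <- compartmentalize(m)
  ap <- tr$comps[tr$comps$region == "apical", ]
  extent <- max(ap$x + ap$L / 2)
  expect_lt(abs(extent - 425), 1)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  tr2 <- compartmentalize(load_swc(f))
  expect_equal(nrow(tr$comps), nrow(tr2$comps))
  expect_equal(sort(tr$comps$x), sort(tr2$comps$x), tolerance = 1e-5)
  expect_equal(sort(tr$comps$area), sort(tr2$comps$area), tolerance = 1e-5)
  # different seeds move the obliques but keep the trunk extent
  m2 <- make_morphology(seed = 2)
  tr3 <- compartmentalize(m2)
  ap3 <- tr3$comps[tr3$comps$region == "apical", ]
  expect_lt(abs(max(ap3$x + ap3$L / 2) - 425), 1)
  expect_false(identical(tr$comps$x, tr3$comps$x))
})

test_that("compartment table export is a readable CSV", {
  tr <- compartmentalize(make_morphology(seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_compartments(tr, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), nrow(tr$comps))
  expect_true(all(c("x", "L", "diam", "area", "Rm", "Ra", "Cm") %in%
                    names(tab)))
})
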