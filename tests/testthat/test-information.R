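test_that("mutual information is exact on hand-computable channels", {
  # identity channel over 50 stimuli
  p_rs <- diag(50)
  info <- mutual_information(p_rs)
  expect_equal(info$I_m, log2(50), tolerance = 1e-9)
  expect_equal(info$H_noise, 0, tolerance = 1e-12)
  # identical rows carry no information
  p_same <- matrix(rep(c(0.2, 0.3, 0.5), each = 4), 4, 3)
  expect_equal(mutual_information(p_same)$I_m, 0, tolerance = 1e-12)
  # 2x2 binary channel: direct summation
  p2 <- rbind(c(0.75, 0.25), c(0.25, 0.75))
  i2 <- mutual_information(p2)
  h <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
  expect_equal(i2$I_m, h(c(0.5, 0.5)) - h(c(0.75, 0.25)), tolerance = 1e-12)
  expect_equal(i2$I_m, 0.1887, tolerance = 1e-3)
  expect_error(mutual_information(rbind(c(0.5, 0.4), c(0.5, 0.5))), "sum to 1")
})

test_that("conditional response distributions are normalized Gaussians", {
  prof <- structure(list(freqs = c(10, 20), trials = 4,
                         rf = rbind(c(20, 20, 20, 20), c(18, 20, 22, 20))),
                    class = "response_profile")
  p <- conditional_distributions(prof, bins = 1:100)
  # zero-SD row collapses to a delta at the nearest bin
  expect_equal(unname(p[1, 20]), 1)
  expect_equal(sum(p[1, ]), 1)
  # Gaussian row: normalized, peaked at its mean, symmetric
  expect_equal(sum(p[2, ]), 1, tolerance = 1e-12)
  expect_equal(which.max(p[2, ]), 20)
  expect_equal(p[2, 18], p[2, 22], tolerance = 1e-6)
  # random profiles always yield stochastic rows
  set.seed(1)
  prof2 <- structure(list(freqs = 1:6, trials = 5,
                          rf = matrix(runif(30, 0, 50), 6, 5)),
                     class = "response_profile")
  p2 <- conditional_distributions(prof2)
  expect_equal(unname(rowSums(p2)), rep(1, 6), tolerance = 1e-9)
})

test_that("information behaves under relabeling, merging, and noise growth", {
  mk <- function(means, sds, bins = 1:100) {
    p <- t(vapply(seq_along(means), function(i) {
      row <- dnorm(bins, means[i], sds[i]); row / sum(row)
    }, numeric(length(bins))))
    p
  }
  means <- seq(10, 90, by = 10)
  p <- mk(means, rep(3, length(means)))
  base <- mutual_information(p)$I_m
  # invariance under stimulus relabeling
  perm <- sample(nrow(p))
  expect_equal(mutual_information(p[perm, ])$I_m, base, tolerance = 1e-12)
  # merging adjacent response bins never increases information
  merged <- p[, seq(1, 99, by = 2)] + p[, seq(2, 100, by = 2)]
  expect_lte(mutual_information(merged)$I_m, base + 1e-12)
  # information falls monotonically as response noise grows
  mis <- vapply(c(2, 4, 8, 16), function(sd)
    mutual_information(mk(means, rep(sd, length(means))))$I_m, 0)
  expect_true(all(diff(mis) < 0))
  # and the loss is carried by noise entropy
  i1 <- mutual_information(mk(means, rep(2, length(means))))
  i2 <- mutual_information(mk(means, rep(16, length(means))))
  expect_gt(i2$H_noise, i1$H_noise)
})

test_that("profile information restricts to a stimulus subrange", {
  prof <- make_fixture_profile("uniform", n_stim = 20, trials = 6, sd = 1.5,
                               seed = 2)
  all_r <- profile_information(prof)
  sub <- profile_information(prof, freq_range = c(10, 20))
  expect_lt(sub$I_m, all_r$I_m + 1e-9)
  expect_gt(sub$I_m, 0)
})

test_that("information results serialize to JSON with their entropies", {
  skip_if_not_installed("jsonlite")
  info <- mutual_information(rbind(c(0.75, 0.25), c(0.25, 0.75)))
  f <- withr::local_tempfile(fileext = ".json")
  g <- withr::local_tempfile(fileext = ".csv")
  write_info(info, f, p_rs_csv = g)
  back <- jsonlite::read_json(f)
  expect_equal(back$I_m, info$I_m, tolerance = 1e-9)
  expect_equal(nrow(read.csv(g)), 2)
})
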