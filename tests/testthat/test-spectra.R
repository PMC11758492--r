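test_that("centroids are intensity-weighted means converted to neutral mass", {
  pl <- peak_list(c(100, 102), c(1, 1), charge = 1)
  expect_equal(attr(centroid(pl), "mz"), 101)
  expect_equal(as.numeric(centroid(pl)), 101 - 1.00728)
  pl2 <- peak_list(c(100, 101), c(3, 1), charge = 1)
  expect_equal(attr(centroid(pl2), "mz"), 100.25)
  # invariance under uniform intensity rescaling
  pl3 <- peak_list(c(100, 101), c(3, 1) * 17.3, charge = 1)
  expect_equal(as.numeric(centroid(pl3)), as.numeric(centroid(pl2)))
  # charge conversion removes z protons
  plz <- peak_list(c(50, 51), c(1, 1), charge = 2)
  expect_equal(as.numeric(centroid(plz)), 2 * 50.5 - 2 * 1.00728)
  expect_error(peak_list(c(100, 101), c(0, 0)))
  expect_error(peak_list(c(101, 100), c(1, 1)))
})

test_that("uptake handles identity, saturation and back-exchange", {
  b <- peak_list(c(100, 101, 102), c(1, 0.5, 0.1))
  expect_equal(uptake(b, b, n_sites = 5)$shift, 0)
  expect_equal(uptake(b, b, n_sites = 5)$percent_of_sites, 0)
  # shift of n_sites * delta_mD -> 100%
  dm <- 1.00628
  a <- peak_list(c(100, 101, 102) + 5 * dm, c(1, 0.5, 0.1))
  expect_equal(uptake(b, a, n_sites = 5)$percent_of_sites, 100)
  # a loss of deuterium relative to 'before' flags back-exchange
  a2 <- peak_list(c(100, 101, 102) - 0.4, c(1, 0.5, 0.1))
  expect_warning(u <- uptake(b, a2, n_sites = 5), "back-exchange")
  expect_true(u$back_exchange)
  expect_error(uptake(b, peak_list(c(50, 51), c(1, 1), charge = 2), 5))
})

test_that("binomial envelopes recover the planted incorporation exactly", {
  for (cs in list(c(6, 0), c(6, 1), c(6, 0.5), c(12, 0.37), c(3, 0.9))) {
    env <- make_envelope(n_sites = cs[1], p = cs[2], seed = 11)
    u <- uptake(env$before, env$after, n_sites = cs[1])
    expect_equal(u$shift, cs[1] * cs[2] * 1.00628, tolerance = 1e-9)
    expect_equal(u$percent_of_sites, 100 * cs[2], tolerance = 1e-9)
  }
  # p = 0 leaves the envelope untouched
  env0 <- make_envelope(n_sites = 6, p = 0)
  expect_equal(env0$after$mz, env0$before$mz)
  expect_equal(env0$after$intensity, env0$before$intensity)
  # multiply charged envelopes give the same neutral-mass uptake
  env2 <- make_envelope(n_sites = 6, p = 0.5, charge = 2)
  expect_equal(uptake(env2$before, env2$after, 6)$shift, 6 * 0.5 * 1.00628,
               tolerance = 1e-9)
})

test_that("internal-standard scaling evaluates the fitted exposure line", {
  # points exactly on y = 0.2 x -> 15 Da at the 75% reference
  s <- scale_to_standard(c(20, 50, 90), 0.2 * c(20, 50, 90), level = 75)
  expect_equal(s$value, 15, tolerance = 1e-12)
  expect_equal(s$se, 0, tolerance = 1e-9)
  # two exact points: interpolation through them
  s2 <- scale_to_standard(c(40, 80), c(8, 12), level = 60)
  expect_equal(s2$value, 10)
  # evaluating at an observed x with exact data reproduces the observation
  s3 <- scale_to_standard(c(30, 60, 90), c(5, 9, 13), level = 60)
  expect_equal(s3$value, 9, tolerance = 1e-12)
  expect_error(scale_to_standard(c(50, 50, 50), c(1, 2, 3)))
  # noisy line with known slope/intercept: recovery within 3 SE
  set.seed(101)
  x <- seq(20, 95, length.out = 12)
  y <- 0.18 * x + 1.5 + rnorm(12, 0, 0.3)
  sn <- scale_to_standard(x, y, level = 75)
  expect_lt(abs(sn$value - (0.18 * 75 + 1.5)), 3 * sn$se + 1e-9)
})

test_that("charge-state pooling propagates uncertainty", {
  one <- combine_charge_states(5.1, 0.2)
  expect_equal(one$value, 5.1)
  expect_equal(one$uncertainty, 0.2)
  two <- combine_charge_states(c(5, 5), c(0.2, 0.2))
  expect_equal(two$value, 5)
  expect_equal(two$uncertainty, 0.2 / sqrt(2))
  # intensity weighting pulls toward the stronger charge state
  w <- combine_charge_states(c(4, 6), c(0.1, 0.1), weights = c(3, 1))
  expect_equal(w$value, 4.5)
  iv <- combine_charge_states(c(4, 6), c(0.1, 0.3),
                              scheme = "inverse_variance")
  expect_lt(iv$value, 5)
  # pooled replicates land within 3 SE of the truth
  set.seed(5)
  reps <- rnorm(30, 7, 0.5)
  pooled <- combine_charge_states(reps, rep(0.5, 30))
  expect_lt(abs(pooled$value - 7), 3 * pooled$uncertainty)
})

test_that("peak lists round-trip through delimited files", {
  p <- file.path(tempdir(), "peaks.csv")
  writeLines(c("mz,intensity", "100.5,3", "101.5,1"), p)
  pl <- read_peak_list(p, charge = 2)
  expect_equal(pl$mz, c(100.5, 101.5))
  expect_equal(attr(centroid(pl), "mz"), 100.75)
  p2 <- file.path(tempdir(), "peaks.tsv")
  writeLines(c("mz\tintensity", "100.5\t3", "101.5\t1"), p2)
  expect_equal(read_peak_list(p2)$intensity, c(3, 1))
})
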