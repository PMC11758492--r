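test_that("diagonal designs decouple into per-class ratios", {
  counts <- diag(c(2, 4, 1))
  colnames(counts) <- c("amine", "guanidino", "hydroxyl")
  obs <- c(1.8, 2.0, 0.8)
  pt <- fit_propensities(counts, obs)
  expect_equal(pt$propensity, c(0.9, 0.5, 0.8), tolerance = 1e-10)
  # over-saturated observation clips at 1 with a warning
  expect_warning(ptc <- fit_propensities(counts, c(2.5, 2, 0.8)), "clipped")
  expect_equal(ptc$propensity[1], 1)
})

test_that("NNLS equals the analytic OLS solution when OLS is nonnegative", {
  set.seed(13)
  for (i in 1:25) {
    n_cls <- sample(2:4, 1)
    counts <- matrix(rpois(8 * n_cls, 3), 8, n_cls)
    colnames(counts) <- paste0("c", seq_len(n_cls))
    if (qr(counts)$rank < n_cls) next
    truth <- runif(n_cls, 0.2, 0.9)
    obs <- drop(counts %*% truth) + rnorm(8, 0, 0.01)
    pt <- fit_propensities(counts, obs, clip = FALSE)
    ols <- attr(pt, "ols")
    if (all(ols >= 0)) {
      expect_equal(pt$propensity, unname(ols), tolerance = 1e-8)
    } else {
      expect_true(all(pt$propensity >= 0))
    }
    # optimality: no random nonnegative candidate beats the solution
    rss <- function(p) sum((obs - counts %*% p)^2)
    for (k in 1:5)
      expect_lte(attr(pt, "residual_norm"),
                 rss(pmax(pt$propensity + rnorm(n_cls, 0, 0.05), 0)) + 1e-12)
  }
})

test_that("propensities are recovered from noisy synthetic standards", {
  truth <- c(amine = 0.92, guanidino = 0.55, hydroxyl = 0.8,
             terminal = 0.85)
  des <- standard_design(c("K", "R", "S", "A", "T", "G"))
  # ~1% of a typical standard's uptake, with replicate standards
  des_rep <- des[rep(seq_len(nrow(des)), 4), ]
  std <- make_standards(truth, des_rep, noise = 0.03, seed = 21)
  pt <- fit_propensities(std$counts, std$observed)
  for (i in seq_len(nrow(pt))) {
    expect_lt(abs(pt$propensity[i] - truth[pt$class[i]]),
              3 * pt$se[i] + 1e-9)
  }
  # zero-noise recovery is exact
  std0 <- make_standards(truth, des, noise = 0)
  pt0 <- fit_propensities(std0$counts, std0$observed)
  expect_equal(stats::setNames(pt0$propensity, pt0$class), truth,
               tolerance = 1e-10)
})

test_that("a zero-propensity class pinned by negative noise sits exactly on the boundary", {
  counts <- cbind(amine = c(2, 2, 0, 0), hydroxyl = c(0, 1, 1, 2))
  truth <- c(amine = 0.8, hydroxyl = 0)
  obs <- drop(counts %*% truth) + c(0, -0.05, -0.02, -0.04)
  pt <- fit_propensities(counts, obs)
  expect_identical(pt$propensity[pt$class == "hydroxyl"], 0)
})

test_that("rank-deficient designs are rejected naming the classes", {
  counts <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(1, 0, 1))
  expect_error(fit_propensities(counts, c(1, 2, 3)), "a, b")
})

test_that("side contributions are dot products over covered classes", {
  inv <- enumerate_sites(peptide("PAAAAKAAAAKAAAAKAAAAK", n_term = "acetyl"))
  all1 <- stats::setNames(rep(1, 11), hdxcalib:::SITE_CLASSES)
  expect_equal(as.numeric(side_contribution(inv, all1)), 9)
  expect_equal(as.numeric(side_contribution(inv, all1 * 0)), 0)
  # pooled terminal class via an explicit pooling map
  tab <- c(amine = 0.9, terminal = 0.8)
  pool <- c(n_terminal_amine = "terminal", c_terminal_acid = "terminal")
  expect_equal(as.numeric(side_contribution(inv, tab, pooling = pool)),
               8 * 0.9 + 1 * 0.8)
  expect_error(side_contribution(inv, c(amine = 0.9)), "c_terminal_acid")
  # random inventories match a hand-summed dot product
  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(names(hdxcalib:::AA1TO3), 8, TRUE), collapse = "")
    iv <- enumerate_sites(peptide(s))
    p <- stats::setNames(runif(11), hdxcalib:::SITE_CLASSES)
    expect_equal(as.numeric(side_contribution(iv, p)),
                 sum(iv$side_chain_counts * p[names(iv$side_chain_counts)]))
  }
})

test_that("percent backbone exchange reproduces the worked arithmetic", {
  ps <- percent_backbone(total = 24.0, n_bb = 20, side = 17.79,
                         u_total = 0.5)
  expect_equal(ps$percent_bb, 31.05, tolerance = 1e-10)
  expect_equal(ps$uncertainty, 100 * 0.5 / 20)
  pa <- percent_backbone(total = 9.1, n_bb = 20, side = 8.79)
  expect_equal(pa$percent_bb, 1.55, tolerance = 1e-10)
  expect_equal(percent_backbone(10, 10, 0)$percent_bb, 100)
  expect_warning(neg <- percent_backbone(5, 10, 6), "negative")
  expect_true(neg$negative)
  # linear in total, decreasing in side
  expect_equal(percent_backbone(12, 20, 5)$percent_bb -
                 percent_backbone(10, 20, 5)$percent_bb, 10)
  expect_lt(percent_backbone(10, 20, 6)$percent_bb,
            percent_backbone(10, 20, 5)$percent_bb)
})
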