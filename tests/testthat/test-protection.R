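trace_from_fo <- function(f_open, n = 1000) {
  open <- t(vapply(f_open, function(f) seq_len(n) <= round(f * n),
                   logical(n)))
  state_trace_from_matrix(open, model = "inter")
}

test_that("protection factors follow the population ratio with clamping", {
  pf <- protection_factors(trace_from_fo(c(0.5, 0.2, 0.8)))
  expect_equal(pf$pf, c(1, 4, 0.25), tolerance = 1e-12)
  expect_equal(pf$ln_pf[1], 0)
  expect_equal(pf$ln_pf[2], log(4), tolerance = 1e-12)
  expect_equal(pf$k_eq * pf$pf, rep(1, 3))
  # f_open = 0 clamps to 1/n -> PF = n - 1, flagged
  pf0 <- protection_factors(trace_from_fo(c(0, 1), n = 25000))
  expect_equal(pf0$pf[1], 24999)
  expect_true(all(pf0$clamped))
  expect_equal(pf0$pf[2], 1 / 24999, tolerance = 1e-9)
  expect_error(protection_factors(trace_from_fo(0), clamp = FALSE))
})

test_that("digital exchange counts open-dominated residues", {
  pf <- protection_factors(trace_from_fo(c(0.9, 0.8, 0.6, 0.4, 0.1)))
  dig <- digital_exchange(pf)
  expect_equal(dig$contribution, c(1, 1, 1, 0, 0))
  expect_equal(dig$percent_bb_theory, 60)
  # all open-dominated -> 100%; all closed-dominated -> 0%
  expect_equal(digital_exchange(protection_factors(
    trace_from_fo(c(0.7, 0.9))))$percent_bb_theory, 100)
  expect_equal(digital_exchange(protection_factors(
    trace_from_fo(c(0.3, 0.1))))$percent_bb_theory, 0)
  # ln PF exactly 0 counts as NOT exchanged (strict inequality)
  expect_equal(digital_exchange(protection_factors(
    trace_from_fo(0.5)))$percent_bb_theory, 0)
  # brute-force count over random profiles
  set.seed(12)
  for (i in 1:10) {
    fo <- runif(8, 0.05, 0.95)
    pf <- protection_factors(trace_from_fo(fo))
    expect_equal(digital_exchange(pf)$percent_bb_theory,
                 100 * sum(log((1 - pf$f_open) / pf$f_open) < 0) / 8)
  }
})

test_that("combined kinetic exchange matches its closed forms and limits", {
  mk_kint <- function(k, resno) {
    df <- data.frame(residue = resno, aa = "A", k_acid = 0, k_base = k,
                     k_water = 0, k_int = k)
    class(df) <- c("kint_profile", "data.frame")
    df
  }
  pf <- protection_factors(trace_from_fo(0.5))  # PF = 1
  # k_int * t = PF -> 1 - 1/e
  expect_equal(cmb_exchange(pf, mk_kint(1, pf$resno), t = 1)$contribution,
               1 - exp(-1), tolerance = 1e-12)
  # saturation and full-protection limits
  expect_equal(cmb_exchange(pf, mk_kint(1e12, pf$resno), t = 1)$contribution, 1)
  pf_hi <- protection_factors(trace_from_fo(0, n = 1e6))  # PF ~ 1e6
  expect_lt(cmb_exchange(pf_hi, mk_kint(1, pf_hi$resno), t = 1)$contribution,
            2e-6)
  # strictly decreasing in PF, increasing in k_int * t, bounded in (0,1)
  fo <- seq(0.1, 0.9, by = 0.1)
  pfs <- protection_factors(trace_from_fo(fo))
  con <- cmb_exchange(pfs, mk_kint(rep(2, 9), pfs$resno), t = 1)$contribution
  expect_true(all(diff(con[order(pfs$pf)]) < 0))
  expect_true(all(con > 0 & con < 1))
  con_t2 <- cmb_exchange(pfs, mk_kint(rep(2, 9), pfs$resno),
                         t = 2)$contribution
  expect_true(all(con_t2 > con))
  # monotone consistency with the digital rule: lower ln PF -> no smaller
  # contribution at equal k_int
  ord <- order(pfs$ln_pf)
  expect_true(all(diff(con[ord]) <= 0))
  expect_error(cmb_exchange(pfs, mk_kint(1, 99), t = 1), "missing")
})

test_that("replicate aggregation averages populations with SEM", {
  tr <- trace_from_fo(c(0.4, 0.6))
  p1 <- protection_factors(tr)
  same <- aggregate_replicates(list(p1, p1, p1))
  expect_equal(same$f_open, p1$f_open)
  expect_equal(same$ln_pf, p1$ln_pf)
  expect_equal(same$ln_pf_sem, c(0, 0))
  # two replicates with ln PF +1 and -1 -> mean 0, SEM 1 (ln_pf method)
  fo_a <- 1 / (1 + exp(1))   # ln PF = +1
  fo_b <- 1 / (1 + exp(-1))  # ln PF = -1
  pa <- protection_factors(trace_from_fo(fo_a, n = 1e6))
  pb <- protection_factors(trace_from_fo(fo_b, n = 1e6))
  agg <- aggregate_replicates(list(pa, pb), method = "ln_pf")
  expect_equal(agg$ln_pf, 0, tolerance = 1e-3)
  expect_equal(agg$ln_pf_sem, 1, tolerance = 1e-3)
  # k noisy replicates straddle the truth within 3 SEM
  set.seed(44)
  true_fo <- 0.3
  reps <- lapply(1:6, function(i)
    protection_factors(trace_from_fo(true_fo + runif(1, -0.05, 0.05))))
  agg <- aggregate_replicates(reps)
  expect_lt(abs(agg$f_open - true_fo), 3 * agg$f_open_sem + 0.01)
  # model mismatch is rejected
  p_intra <- protection_factors(state_trace_from_matrix(
    matrix(TRUE, 2, 10), model = "intra"))
  expect_error(aggregate_replicates(list(p1, p_intra)), "model")
})
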