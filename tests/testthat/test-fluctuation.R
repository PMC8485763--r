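test_that("mutant-count pmf: hand values and parameter validation", {
  expect_equal(ld_pmf(0, 1, 4), c(1, 0, 0, 0, 0))
  p <- ld_pmf(1, 1, 3)
  expect_equal(p[1], exp(-1), tolerance = 1e-12)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-12)
  expect_error(ld_pmf(-1, 1, 5), "non-negative")
  expect_error(ld_pmf(1, 0, 5), "epsilon")
  expect_error(ld_pmf(1, 1.5, 5), "epsilon")
})

test_that("whole-plate pmf equals the MSS recursion term by term", {
  for (m in c(0.3, 1, 2.5, 6)) {
    expect_equal(ld_pmf(m, 1, 300), oracle_mss_pmf(m, 300),
                 tolerance = 1e-13)
  }
})

test_that("pmf is a near-normalized distribution", {
  for (eps in c(1, 0.4, 0.1)) {
    p <- ld_pmf(2, eps, 2000)
    expect_true(all(p >= 0))
    expect_lte(sum(p), 1 + 1e-12)
    ## mass above n_max decays like m/n for a heavy-tailed clone law
    expect_lt(1 - sum(p), 5e-3)
  }
})

test_that("partial-plating pmf matches Monte-Carlo frequencies", {
  n <- 2e5
  cfg <- sim_config(seed = 42, n_cultures = n, m_true = 1.2, epsilon = 0.35)
  x <- simulate_fluctuation_counts(cfg)
  p <- ld_pmf(1.2, 0.35, 30)
  emp <- tabulate(x + 1L, nbins = 31L) / n
  keep <- p * n >= 5  # classes where the normal approximation applies
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(emp[keep] - p[keep]) <= 3 * se[keep]))
})

test_that("all-zero counts give a zero MLE with a closed-form upper bound", {
  f <- ld_fit(rep(0L, 24))
  expect_identical(f$m, 0)
  expect_identical(f$ci_m[1], 0)
  expect_equal(f$ci_m[2], qchisq(0.95, 1) / 2 / 24, tolerance = 1e-10)
  ## with partial plating the zero class is flatter, the bound wider
  f2 <- ld_fit(rep(0L, 24), epsilon = 0.2)
  expect_gt(f2$ci_m[2], f$ci_m[2])
})

test_that("MLE agrees with an independent grid-search oracle", {
  set.seed(314)
  for (rep in 1:5) {
    cfg <- sim_config(seed = 400 + rep, n_cultures = 15,
                      m_true = runif(1, 0.5, 3))
    counts <- simulate_fluctuation_counts(cfg)
    if (all(counts == 0)) next
    f <- ld_fit(counts)
    m_grid <- oracle_grid_mle(counts, oracle_mss_pmf)
    expect_equal(f$m, m_grid, tolerance = 1e-6)
  }
})

test_that("MLE recovers the true m from a large simulated experiment", {
  cfg <- sim_config(seed = 42, n_cultures = 1e4, m_true = 2, epsilon = 1)
  f <- ld_fit(simulate_fluctuation_counts(cfg))
  expect_lt(abs(f$m - 2), 0.1)
  expect_true(f$ci_m[1] <= 2 && 2 <= f$ci_m[2])
  ## consistency: the small-sample estimate is further off on average,
  ## and the large-sample interval is much tighter
  f_small <- ld_fit(simulate_fluctuation_counts(
    sim_config(seed = 42, n_cultures = 100, m_true = 2)))
  expect_lt(diff(f$ci_m), diff(f_small$ci_m))
})

test_that("rates are m / Nt with CI bounds divided identically", {
  r <- rate_from_m(0.408, c(0.26, 0.592), Nt = 2e8)
  expect_equal(r$rate, 2.04e-9)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)
  expect_equal(rate_from_m(0, c(0, 0.1), 1e8)$rate, 0)
  fit <- ld_fit(c(0, 1, 0, 4, 0, 2), Nt = 2e8)
  expect_equal(fit$rate, fit$m / 2e8)
  expect_equal(fit$ci_rate, fit$ci_m / 2e8)
})

test_that("likelihood-ratio test: identity, symmetry, discrimination", {
  counts <- c(0, 2, 1, 0, 0, 5, 1, 0, 3, 0)
  f <- ld_fit(counts, label = "a")
  g <- ld_fit(counts, label = "b")
  ht <- ld_lrt(f, g)
  expect_equal(unname(ht$statistic), 0, tolerance = 1e-6)
  expect_equal(ht$p.value, 1, tolerance = 1e-6)

  c2 <- c(8, 30, 2, 11, 0, 25, 7, 60, 4, 12)
  h12 <- ld_lrt(ld_fit(counts), ld_fit(c2))
  h21 <- ld_lrt(ld_fit(c2), ld_fit(counts))
  expect_equal(unname(h12$statistic), unname(h21$statistic), tolerance = 1e-8)
  expect_lt(h12$p.value, 0.01)

  ## different Nt branch: equal rates, different m scales
  fa <- ld_fit(simulate_fluctuation_counts(
    sim_config(seed = 10, n_cultures = 30, m_true = 1)), Nt = 1e8)
  fb <- ld_fit(simulate_fluctuation_counts(
    sim_config(seed = 11, n_cultures = 30, m_true = 2)), Nt = 2e8)
  hab <- ld_lrt(fa, fb)
  expect_gte(unname(hab$statistic), 0)
  expect_true(hab$p.value >= 0 && hab$p.value <= 1)
  expect_gt(hab$p.value, 0.05)  # same underlying rate 1e-8
})

test_that("jackpot censoring keeps the fit finite and close to the exact fit", {
  counts <- c(0, 1, 0, 2, 0, 0, 3, 1, 0, 4, 2500)
  f_cens <- ld_fit(counts, max_count = 1000L)
  expect_identical(f_cens$n_censored, 1L)
  f_exact <- ld_fit(counts, max_count = 5000L)
  expect_identical(f_exact$n_censored, 0L)
  expect_lt(abs(f_cens$m - f_exact$m) / f_exact$m, 0.02)
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
  set.seed(99)
  for (r in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("ld_fit methods behave like a standard model object", {
  counts <- c(0, 3, 1, 0, 7, 2, 0, 1, 0, 5)
  f <- ld_fit(counts, Nt = 2e8, label = "wt")
  expect_named(coef(f), c("m", "rate"))
  ci <- confint(f, "m")
  expect_equal(unname(ci[1, ]), f$ci_m)
  ci90 <- confint(f, "m", level = 0.90)
  expect_true(ci90[1, 1] > ci[1, 1] && ci90[1, 2] < ci[1, 2])
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "nobs"), 10L)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(10L, 3L))
  expect_output(print(summary(f)), "zero-count fraction")
  ht <- anova(f, ld_fit(counts, Nt = 2e8))
  expect_equal(ht$p.value, 1, tolerance = 1e-6)
})
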