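make_profile <- function(d, I, ...) lane_profile(d, I, ...)

test_that("lane_profile validates its invariants", {
  expect_error(lane_profile(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(lane_profile(c(1, 3, 2), c(1, 1, 1)), "increasing")
  expect_s3_class(lane_profile(1:5, rep(1, 5)), "lane_profile")
})

test_that("preprocessing subtracts a constant, clips, and preserves smooth input", {
  d <- seq(0, 99, by = 1)
  flat <- make_profile(d, rep(7, 100))
  expect_error(preprocess_lane(flat, background = "constant", bg_value = 7),
               "empty")

  lin <- make_profile(d, 5 + 2 * d)
  out <- preprocess_lane(lin, df = 40, background = "constant", bg_value = 0)
  expect_equal(out$intensities, lin$intensities, tolerance = 1e-6)

  set.seed(1)
  noisy <- make_profile(d, pmax(rnorm(100, 10, 20), 0))
  out <- preprocess_lane(noisy, df = 10)
  expect_true(all(out$intensities >= 0))
})

test_that("calibration is recovered exactly from exact band positions", {
  sizes <- c(1000, 2000, 5000, 10000, 20000)
  pos <- 200 - 25 * log(sizes)
  d <- seq(-80, 60, by = 0.1)
  dummy <- make_profile(d, rep(1, length(d)) + dnorm(d))  # profile unused
  cal <- fit_calibration(dummy, sizes, peak_positions = sort(pos))
  expect_equal(cal$a, 200, tolerance = 1e-9)
  expect_equal(cal$b, -25, tolerance = 1e-9)
  expect_equal(cal$r2, 1, tolerance = 1e-12)

  ## symmetric offsets across two lanes average away exactly
  cal2 <- fit_calibration(list(dummy, dummy), sizes,
                          peak_positions = list(sort(pos) + 0.4,
                                                sort(pos) - 0.4))
  expect_equal(cal2$a, cal$a, tolerance = 1e-9)
  expect_equal(cal2$b, cal$b, tolerance = 1e-9)
})

test_that("detected ladder peaks give a near-exact calibration", {
  cfg <- sim_config(seed = 2)
  cfg$noise_sd <- 0
  sizes <- c(1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5)
  lane <- render_gel_lane(sizes, cfg, counts = round(max(sizes) / sizes))
  lane <- preprocess_lane(lane, background = "constant",
                          bg_value = cfg$background)
  cal <- fit_calibration(lane, sizes)
  expect_equal(cal$a, cfg$calib_a, tolerance = 0.01)
  expect_equal(cal$b, cfg$calib_b, tolerance = 0.01)
  expect_gt(cal$r2, 0.9999)
})

test_that("noisy peak positions keep the slope inside its sampling error", {
  sizes <- c(1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5)
  pos_true <- 450 - 25 * log(sizes)
  d <- seq(0, 400, by = 0.5)
  dummy <- make_profile(d, rep(1, length(d)))
  set.seed(11)
  for (r in 1:10) {
    pos <- sort(pos_true + rnorm(length(sizes), sd = 0.5))
    cal <- fit_calibration(dummy, sizes, peak_positions = pos)
    se_b <- summary(cal$fit)$coefficients[2, 2]
    expect_lt(abs(cal$b - (-25)), 3 * se_b + 1e-9)
  }
})

test_that("peak-count mismatch asks for supervision", {
  d <- seq(0, 100, by = 0.5)
  y <- 10 + dnorm(d, 30, 2) * 100 + dnorm(d, 60, 2) * 100
  lane <- make_profile(d, y)
  expect_error(fit_calibration(lane, c(1e3, 1e4, 1e5)),
               "peak_positions")
})

test_that("fragment counting divides intensity by size and conserves mass", {
  d <- seq(10, 200, by = 1)
  cal <- structure(list(a = 300, b = -30), class = "gel_calibration")
  I <- rep(0, length(d))
  i1000 <- which.min(abs(d - (300 - 30 * log(1000))))
  I[i1000] <- 500
  I[50] <- 123.4
  lane <- make_profile(d, I)
  fsd <- fragment_count_profile(lane, cal, d_max = max(d))
  expect_equal(fsd$n_sz[i1000], 500 / exp((d[i1000] - 300) / -30),
               tolerance = 1e-12)
  expect_equal(fsd$n_sz[I == 0], rep(0, sum(I == 0)))
  ## exact algebraic identity sum(sz * n_sz) == sum(I)
  expect_equal(sum(fsd$sz * fsd$n_sz), sum(I), tolerance = 1e-12)
  expect_error(fragment_count_profile(lane, cal, d_max = 500), "range")
})

test_that("mean fragment size and the sub-cutoff correction", {
  fsd <- fragment_size_distribution(c(1000, 2000), c(1, 1), sz_min = 0)
  ms <- mean_fragment_size(fsd)
  expect_equal(unname(ms["mean_raw"]), 1500)
  expect_equal(unname(ms["mean_corr"]), 1500)  # exp(0) = 1

  fsd2 <- fragment_size_distribution(1000, 1, sz_min = 1000)
  expect_equal(unname(mean_fragment_size(fsd2)["mean_corr"]),
               1000 * exp(-1), tolerance = 1e-12)

  expect_error(mean_fragment_size(
    fragment_size_distribution(1000, 0, sz_min = 0)), "empty")
})

test_that("the correction recovers an exponential mean from truncated data", {
  lambda <- 20000; sz_min <- 500
  sz <- seq(sz_min, 30 * lambda, by = 20)
  n_sz <- exp(-sz / lambda)
  fsd <- fragment_size_distribution(sz, n_sz, sz_min = sz_min)
  ms <- mean_fragment_size(fsd)
  expect_equal(unname(ms["mean_raw"]), lambda + sz_min, tolerance = 1e-3)
  expect_lt(abs(ms["mean_corr"] - lambda) / lambda, 0.005)
})

test_that("breakpoints and embedded-ribonucleotide differencing", {
  expect_equal(genome_breakpoints(9.28e6), 1)
  expect_equal(genome_breakpoints(20000, G = 9.28e6), 464)
  expect_equal(genome_breakpoints(20000, G = 2 * 9.28e6),
               2 * genome_breakpoints(20000, G = 9.28e6))
  expect_error(genome_breakpoints(0), "positive")

  expect_equal(embedded_ribos(1000, c(450, 460)), 545)
  expect_equal(embedded_ribos(455, c(450, 460)), 0)
  expect_warning(r <- embedded_ribos(400, c(450, 460)), "negative")
  expect_equal(r, -55)
  expect_error(embedded_ribos(1000, numeric()), "wild-type")
})

test_that("Welch test matches the hand formulas and is symmetric", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5)
  w <- welch_t(x, y)
  o <- oracle_welch(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-9)
  expect_equal(w$df, o$df, tolerance = 1e-9)
  expect_equal(w$p, o$p, tolerance = 1e-9)
  expect_equal(welch_t(y, x)$p, w$p, tolerance = 1e-12)
  same <- welch_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, y), ">= 2")
})

test_that("ribo summary: folds, identical-list degenerate case, validation", {
  s <- summarize_ribo(list(dnaE_wt = c(450, 455, 465),
                           mutant = c(450, 455, 465)))
  expect_equal(s$fold[s$strain == "mutant"], 1, tolerance = 1e-12)
  expect_equal(s$p_value[s$strain == "mutant"], 1, tolerance = 1e-12)
  expect_equal(s$p_value[s$strain == "dnaE_wt"], 1)

  single <- summarize_ribo(list(dnaE_wt = c(450, 460), m = 900))
  expect_true(is.na(single$p_value[single$strain == "m"]))

  expect_error(summarize_ribo(list(a = 1), reference = "dnaE_wt"), "missing")
})

test_that("inferred breakpoints increase with the nick density", {
  cfg <- sim_config(seed = 8)
  ladder <- c(1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5)
  marker <- render_gel_lane(ladder, cfg, counts = round(max(ladder) / ladder),
                            label = "lad", seed = 9)
  Ns <- vapply(c(2e-5, 5e-5, 1e-4), function(rho) {
    c2 <- cfg; c2$rho <- rho
    fr <- simulate_nicked_fragments(c2, seed = 77)
    lane <- render_gel_lane(fr, cfg, label = "s", seed = 78)
    rq <- ribo_quant(list(lane), marker, ladder)
    rq$lanes$breakpoints
  }, numeric(1))
  expect_true(all(diff(Ns) > 0))
})
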