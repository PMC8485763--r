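ALL12 <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
ALL12 <- ALL12[ALL12$ref != ALL12$alt, ]

test_that("substitution calling: mismatches, offsets, ambiguity", {
  expect_identical(nrow(call_substitutions("ACGT", "ACGT")), 0L)

  one <- call_substitutions("ACGT", "TCGT", offset = 1516)
  expect_identical(one$position, 1516L)
  expect_identical(one$ref, "A")
  expect_identical(one$alt, "T")

  amb <- call_substitutions("ACGT", "NCGA", offset = 1516)
  expect_identical(amb$position, 1519L)  # the N mismatch is skipped

  expect_error(call_substitutions("ACG", "ACGT"), "equal length")
  expect_identical(call_substitutions("acgt", "aCgA")$alt, "A")
})

test_that("classification collapses strands onto the six pair classes", {
  expected <- c("A>C" = "AT>CG", "A>G" = "AT>GC", "A>T" = "AT>TA",
                "C>A" = "CG>AT", "C>G" = "CG>GC", "C>T" = "CG>TA",
                "G>A" = "CG>TA", "G>C" = "CG>GC", "G>T" = "CG>AT",
                "T>A" = "AT>TA", "T>C" = "AT>GC", "T>G" = "AT>CG")
  got <- classify_substitution(ALL12$ref, ALL12$alt)
  key <- paste0(ALL12$ref, ">", ALL12$alt)
  expect_identical(got$class, unname(expected[key]))
  ts <- got$class %in% c("CG>TA", "AT>GC")
  expect_identical(got$type, ifelse(ts, "transition", "transversion"))

  ## strand symmetry: complementing both bases never changes the class
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  got_c <- classify_substitution(comp[ALL12$ref], comp[ALL12$alt])
  expect_identical(got$class, got_c$class)

  expect_error(classify_substitution("N", "A"), "non-canonical")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("window filtering uses a closed 1-based interval", {
  calls <- data.frame(position = c(1515L, 1516L, 1600L, 1717L, 1718L),
                      ref = "A", alt = "T")
  kept <- filter_window(calls)
  expect_identical(kept$position, c(1516L, 1600L, 1717L))
  expect_identical(nrow(filter_window(calls[0, ])), 0L)
  expect_error(filter_window(calls, 10, 5), "lo")
})

test_that("spectrum tabulation: totals, percentages, permutation invariance", {
  calls <- calls_from_class_counts(c(2, 8, 9, 89, 174, 20))
  sp <- tabulate_spectrum(calls)
  expect_identical(sp$total, 302L)
  expect_identical(sp$transitions + sp$transversions, sp$total)
  expect_equal(sum(sp$percents), 100, tolerance = 1e-12)

  set.seed(21)
  sp2 <- tabulate_spectrum(calls[sample(nrow(calls)), ])
  expect_identical(sp$counts, sp2$counts)
  expect_identical(sp$transitions, sp2$transitions)

  one <- tabulate_spectrum(data.frame(position = 1600L, ref = "A", alt = "C"))
  expect_identical(one$total, 1L)
  expect_equal(unname(one$percents["AT>CG"]), 100)

  empty <- tabulate_spectrum(calls[0, ])
  expect_identical(empty$total, 0L)
  expect_true(all(is.na(empty$percents)))
})

test_that("conservation holds for random generated spectra", {
  for (s in 1:10) {
    calls <- simulate_substitution_calls(sim_config(seed = s), 50)
    sp <- tabulate_spectrum(calls)
    expect_identical(sp$transitions + sp$transversions, sp$total)
    expect_identical(sum(sp$counts), sp$total)
  }
})

test_that("hotspot detection thresholds and orders positions", {
  calls <- rbind(
    data.frame(position = rep(1714L, 50), ref = "A", alt = "T"),
    data.frame(position = rep(1547L, 30), ref = "A", alt = "C"),
    data.frame(position = 1600L, ref = "C", alt = "T"))
  sp <- tabulate_spectrum(calls)
  expect_identical(find_hotspots(sp, 0.05), c(1714L, 1547L))
  expect_identical(find_hotspots(sp, 1), integer())

  all_one <- tabulate_spectrum(data.frame(position = rep(1600L, 4),
                                          ref = "G", alt = "T"))
  expect_identical(find_hotspots(all_one, 1), 1600L)

  ## generator round trip: position weights spiking at 1714 dominate
  w <- setNames(rep(1, 202), 1516:1717)
  w["1714"] <- 50
  cfg <- sim_config(seed = 12, position_weights = w)
  sp_sim <- tabulate_spectrum(simulate_substitution_calls(cfg, 400))
  expect_identical(find_hotspots(sp_sim, 0.05)[1], 1714L)
})

test_that("Monte-Carlo spectrum comparison returns a valid test", {
  a <- tabulate_spectrum(calls_from_class_counts(c(2, 8, 9, 89, 174, 20)))
  b <- tabulate_spectrum(calls_from_class_counts(c(5, 15, 12, 316, 10, 13)))
  set.seed(5)
  ht <- spectrum_compare(a, b, B = 500)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)  # grossly different spectra
})
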