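test_that("carrier frequency methods agree with diplotype enumeration", {
  expect_identical(carrier_frequency(numeric(0)), 0)
  expect_identical(carrier_frequency(numeric(0), "at_least_one_allele"), 0)
  expect_error(carrier_frequency(c(0.1, 1.2)), "fraction")

  p <- c(0.001, 0.002)
  expect_equal(carrier_frequency(p, "at_least_one_allele"),
               1 - (0.999^2 * 0.998^2), tolerance = 1e-15)
  # brute-force genotype enumeration oracle on 1-3 site panels
  for (mafs in list(0.3, c(0.1, 0.05), c(0.001, 0.002, 0.0005),
                    c(0.2, 0.3, 0.4))) {
    expect_equal(carrier_frequency(mafs, "at_least_one_allele"),
                 enumerate_carrier_prob(mafs), tolerance = 1e-12)
  }

  # additive reproduces the published cumulative carrier frequency
  ears2 <- default_panel_frequencies()
  ears2 <- ears2$maf[ears2$gene == "EARS2"]
  expect_equal(carrier_frequency(ears2, "additive"), 0.0135, tolerance = 1e-12)

  # hardy_weinberg_het counts heterozygotes only
  expect_equal(carrier_frequency(0.5, "hardy_weinberg_het"), 0.5)

  # diploid at-least-one-allele probability is bounded by twice the additive
  # MAF sum and approaches exactly twice it in the rare-allele limit
  withr::with_seed(8, {
    for (i in 1:20) {
      mafs <- runif(3, 0, 0.3)
      expect_lte(carrier_frequency(mafs, "at_least_one_allele"),
                 min(1, 2 * carrier_frequency(mafs, "additive")))
    }
  })
  tiny <- rep(1e-4, 3)
  add <- carrier_frequency(tiny, "additive")
  alo <- carrier_frequency(tiny, "at_least_one_allele")
  expect_lt(abs(alo - 2 * add) / (2 * add), 1e-3)
})

test_that("co-occurrence, penetrance, prevalence and case arithmetic reproduce the headline figures", {
  expect_equal(co_occurrence_probability(1e-4, 0.0135), 1.35e-6,
               tolerance = 1e-15)
  expect_equal(co_occurrence_probability(0.7, 0), 0)
  expect_equal(co_occurrence_probability(1e-4, 0.09695), 9.695e-6,
               tolerance = 1e-15)
  expect_equal(signif(co_occurrence_probability(1e-4, 0.09695), 1), 1e-5)

  expect_equal(predicted_penetrance(default_panel_frequencies()), 0.32,
               tolerance = 1e-12)
  expect_equal(predicted_penetrance(c(0, 0, 0)), 0)
  # additive vs exact differ by the inclusion-exclusion term
  two <- c(0.1, 0.05)
  expect_equal(predicted_penetrance(two, "at_least_one_allele"),
               enumerate_carrier_prob(two), tolerance = 1e-12)
  # the two aggregations differ by the inclusion-exclusion/diploid terms
  expect_false(isTRUE(all.equal(predicted_penetrance(two, "additive"),
                                predicted_penetrance(two, "at_least_one_allele"))))

  expect_equal(predicted_prevalence(1e-4, 0.30), 3e-5, tolerance = 1e-15)
  expect_equal(predicted_prevalence(0.37, 1), 0.37)
  expect_equal(predicted_prevalence(1e-4, 0.32), 3.2e-5, tolerance = 1e-15)

  expect_equal(expected_cases(1 / 30000, 66e6), 2200)
  expect_gte(expected_cases(1 / 30000, 66e6), 2000)
  expect_equal(expected_cases(0, 1e6), 0)
  expect_equal(expected_cases(3e-5, 1e6), 30)
})

test_that("carrier-count MAF estimation handles both inheritance modes", {
  ukb <- maf_from_carrier_counts(11, 358916, "haploid_mt")
  expect_equal(ukb, 11 / 358916, tolerance = 1e-15)
  expect_equal(signif(ukb, 1), 3e-5)
  expect_equal(maf_from_carrier_counts(0, 1000), 0)
  # 5 heterozygous carriers among 100 diploids carry 5 of 200 alleles
  expect_equal(maf_from_carrier_counts(5, 100, "autosomal"), 0.025)
  expect_error(maf_from_carrier_counts(1, 0), "positive")
  expect_error(maf_from_carrier_counts(-1, 10), "carriers")
})

test_that("risk chain is monotone and the one-in-N formatter is display-only", {
  r1 <- digenic_risk(default_panel_frequencies(), freq_mt = 1e-4)
  r2 <- digenic_risk(default_panel_frequencies(), freq_mt = 2e-4)
  expect_gt(r2$co_occurrence, r1$co_occurrence)
  expect_gt(r2$predicted_prevalence, r1$predicted_prevalence)
  expect_equal(r1$expected_cases,
               r1$predicted_prevalence * r1$population_size)

  expect_identical(format_one_in(0), "1 in Inf")
  expect_match(format_one_in(1.35e-6), "^1 in ")
  # formatting does not feed back into the exact arithmetic
  expect_equal(r1$co_occurrence, 1e-4 * 0.32, tolerance = 1e-15)
})

test_that("frequencies round-trip through a simulated population", {
  cfg <- simulation_config(seed = 33, freq_mt = 0.02, n_controls = 5000)
  pop <- simulate_control_genotypes(cfg, mt_at_frequency = TRUE)
  n <- nrow(pop$individuals)

  mt_hat <- maf_from_carrier_counts(sum(pop$individuals$mt_carrier), n,
                                    "haploid_mt")
  se_mt <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(mt_hat - 0.02), 3 * se_mt)

  # per-variant allele frequency recovery for the common TRMU-like allele
  trmu_alleles <- sum(pop$genotypes$allele_count[
    pop$genotypes$variant_id == "TRMU_A10S"])
  maf_hat <- maf_from_carrier_counts(trmu_alleles, 2 * n, "haploid_mt") # alleles/2n
  se <- sqrt(0.09695 * (1 - 0.09695) / (2 * n))
  expect_lt(abs(maf_hat - 0.09695), 3 * se)
})
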