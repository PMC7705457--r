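test_that("simulation is fully deterministic given the seed", {
  cfg <- simulation_config(seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  c1 <- simulate_control_genotypes(cfg, n = 50)
  c2 <- simulate_control_genotypes(cfg, n = 50)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))

  a1 <- simulate_assay_tables(cfg)
  a2 <- simulate_assay_tables(cfg)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))

  # different seeds give different draws
  s3 <- simulate_cohort(simulation_config(seed = 78))
  expect_false(identical(s1$truth$affected, s3$truth$affected))

  expect_error(simulation_config(), "seed")
})

test_that("mtDNA transmission is maternal and penetrance model drives affection", {
  cfg <- simulation_config(seed = 13, n_families = 30, n_children = 3)
  sim <- simulate_cohort(cfg)
  ind <- sim$cohort$individuals
  # every child of a homoplasmic mother carries the variant; fathers never do
  kids <- ind[!is.na(ind$mother_id), ]
  mothers <- ind$mt_carrier[match(kids$mother_id, ind$id)]
  expect_true(all(kids$mt_carrier == mothers))
  dads <- ind[is.na(ind$mother_id) & ind$sex == "male", ]
  expect_true(all(!dads$mt_carrier))

  # degenerate penetrance: every affected individual is a digenic carrier
  cfg1 <- simulation_config(seed = 14, n_families = 40, pi_digenic = 1,
                            pi_mt_only = 0, pi_background = 0)
  sim1 <- simulate_cohort(cfg1)
  aff <- sim1$truth[sim1$truth$affected, ]
  expect_true(all(aff$mt_carrier & aff$modifier_count >= 1))

  # no mtDNA variant in the population: no carriers at all
  cfg0 <- simulation_config(seed = 15, freq_mt = 0)
  sim0 <- simulate_cohort(cfg0)
  expect_true(all(!sim0$cohort$individuals$mt_carrier))
})

test_that("founder carrier fraction matches the binomial expectation", {
  cfg <- simulation_config(seed = 16, n_controls = 10000)
  pop <- simulate_control_genotypes(cfg)
  expected <- carrier_frequency(cfg$panel_mafs$maf, "at_least_one_allele")
  carriers <- length(unique(pop$genotypes$individual_id))
  phat <- carriers / 10000
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(phat - expected), 3 * se)

  # degenerate MAFs
  cfg0 <- simulation_config(seed = 17,
                            panel_mafs = tibble::tibble(
                              gene = "G", variant_id = "g0", maf = 0))
  expect_identical(nrow(simulate_control_genotypes(cfg0, n = 100)$genotypes), 0L)
  cfg1 <- simulation_config(seed = 18,
                            panel_mafs = tibble::tibble(
                              gene = "G", variant_id = "g1", maf = 1))
  hom <- simulate_control_genotypes(cfg1, n = 100)
  expect_true(all(hom$genotypes$allele_count == 2L))
})

test_that("penetrance among carriers matches the mixture prediction at scale", {
  cfg <- simulation_config(seed = 19, n_families = 1800, n_children = 2)
  sim <- simulate_cohort(cfg)
  carriers <- sim$truth[sim$truth$mt_carrier, ]
  expect_gt(nrow(carriers), 5000)
  cfreq <- carrier_frequency(cfg$panel_mafs$maf, "at_least_one_allele")
  # founders draw at panel MAFs; children inherit, so the marginal carrier
  # rate among all carriers stays at the population value
  predicted <- cfreq * cfg$pi_digenic + (1 - cfreq) * cfg$pi_mt_only
  observed <- mean(carriers$affected)
  se <- sqrt(predicted * (1 - predicted) / nrow(carriers))
  expect_lt(abs(observed - predicted), 3 * se)
})

test_that("assay simulator reproduces closed-form fold changes and labelled outliers", {
  cfg <- simulation_config(seed = 20, ct_noise_sd = 0,
                           ct_delta_by_group = c(control = 5, affected = 3))
  tabs <- simulate_assay_tables(cfg)
  out <- summarize_copy_number(tabs$ct)
  fc <- out$fold_changes
  expect_equal(
    fc$fold_change[fc$group_a == "control" & fc$group_b == "affected"],
    4, tolerance = 1e-12
  )

  # injected outliers sit 4 SD out with small p: all recovered by the flags
  cfg2 <- simulation_config(seed = 21, prot_n = 1000, prot_n_up = 10,
                            prot_n_down = 10)
  tab <- simulate_assay_tables(cfg2)$proteins
  thr <- regulation_thresholds(tab$log2_ratio)
  flags <- flag_regulated(dplyr::select(tab, -truth), thr)
  joined <- dplyr::bind_cols(flags, truth = tab$truth)
  recovered <- joined$truth %in% c("up", "down") &
    joined$unique_peptides & joined$quantified_in_all
  expect_true(all(
    as.character(joined$regulation[recovered]) == joined$truth[recovered]
  ))
  # false-positive rate among nulls stays near the joint tail x alpha rate
  nulls <- joined[joined$truth == "null", ]
  expect_lt(mean(nulls$regulation != "unchanged"), 0.05)
})

test_that("synthetic proteome generator is deterministic with exact E+Q counts", {
  p1 <- simulate_mt_proteome(1)
  p2 <- simulate_mt_proteome(1)
  expect_identical(p1, p2)
  expect_identical(length(p1), 13L)
  # packaged fixture is the seed-1 output
  fixture <- composition_table()
  regen <- composition_table(p1)
  expect_equal(as.data.frame(fixture), as.data.frame(regen))
})
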