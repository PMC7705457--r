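test_that("classification follows the truncating-or-damaging-missense rule", {
  cfg <- filter_config()

  # pathogenic recessive-disease missense: damaging, conserved, in domain
  v <- make_variant(id = "EARS2:p.Arg516Gln")
  expect_true(classify_pathogenic(v, cfg)$pathogenic)

  # synonymous never qualifies regardless of flags
  v <- make_variant(consequence = "synonymous")
  expect_false(classify_pathogenic(v, cfg)$pathogenic)

  # missense outside a domain fails when the domain requirement is on
  v <- make_variant(in_domain = FALSE)
  expect_false(classify_pathogenic(v, cfg)$pathogenic)
  relaxed <- filter_config(require_domain = FALSE)
  expect_true(classify_pathogenic(v, relaxed)$pathogenic)

  # truncating classes qualify with any flag state
  for (csq in c("splice_site", "frameshift", "stop_gain", "stop_loss")) {
    v <- make_variant(consequence = csq, predicted_damaging = FALSE,
                      conserved = FALSE, in_domain = FALSE)
    out <- classify_pathogenic(v, cfg)
    expect_true(out$pathogenic)
    expect_match(out$reason, "truncating")
  }

  # missing annotation on a missense variant must error, never silently fail
  v <- make_variant(predicted_damaging = NA)
  expect_error(classify_pathogenic(v, cfg), "missing")
})

test_that("rarity filter keeps sub-threshold variants, preserves order, flags NA", {
  cfg <- filter_config(maf_threshold = 0.005)
  v <- dplyr::bind_rows(
    make_variant(id = "a", population_maf = 0.0005),
    make_variant(id = "b", population_maf = 0.05)
  )
  expect_identical(apply_rarity_filter(v, cfg)$id, "a")
  expect_identical(nrow(apply_rarity_filter(v[0, ], cfg)), 0L)

  v$population_maf <- c(NA, 0.5)
  expect_warning(out <- apply_rarity_filter(v, cfg), "Missing MAF")
  expect_identical(out$id, "a")

  v$population_maf <- c(-0.1, 0.5)
  expect_error(apply_rarity_filter(v, cfg), "Negative")

  # 100 uniform MAFs vs an independent linear scan
  withr::with_seed(99, {
    mafs <- runif(100, 0, 0.01)
  })
  v100 <- dplyr::bind_rows(lapply(seq_along(mafs), function(i) {
    make_variant(id = paste0("u", i), population_maf = mafs[i])
  }))
  kept <- apply_rarity_filter(v100, cfg)
  manual <- 0L
  for (m in mafs) if (m < 0.005) manual <- manual + 1L
  expect_identical(nrow(kept), manual)
})

test_that("classify + rarity is idempotent and monotone in the threshold", {
  withr::with_seed(4, {
    v <- dplyr::bind_rows(lapply(1:40, function(i) {
      make_variant(
        id = paste0("v", i),
        consequence = sample(c("missense", "synonymous", "frameshift"), 1),
        predicted_damaging = sample(c(TRUE, FALSE), 1),
        conserved = sample(c(TRUE, FALSE), 1),
        in_domain = sample(c(TRUE, FALSE), 1),
        population_maf = runif(1, 0, 0.02)
      )
    }))
  })
  cfg <- filter_config()
  once <- damaging_rare_variants(v, cfg)
  twice <- damaging_rare_variants(once, cfg)
  expect_identical(once, twice)

  loose <- damaging_rare_variants(v, filter_config(maf_threshold = 0.01))
  expect_true(all(once$id %in% loose$id))
})

test_that("segregation partition matches an exhaustive per-variant scan", {
  v_aff <- tibble::tibble(individual_id = c("i01", "i02"),
                          variant_id = "vx", allele_count = 1L)
  ind <- tibble::tibble(
    id = c("i01", "i02", "i03"), family_id = "F1",
    father_id = NA_character_, mother_id = NA_character_, sex = NA_character_,
    affection = c("affected", "affected", "unaffected"), mt_carrier = FALSE
  )
  co <- cohort(ind, v_aff)
  expect_identical(partition_by_segregation(co)$segregation, "affected_only")

  co2 <- cohort(ind, tibble::tibble(individual_id = c("i01", "i03"),
                                    variant_id = "vy", allele_count = 1L))
  expect_identical(partition_by_segregation(co2)$segregation, "shared")

  # seeded random cohort vs brute force; disjointness/completeness
  co3 <- make_random_cohort(11, n_ind = 20, n_var = 50)
  all_ids <- sprintf("v%03d", 1:50)
  got <- suppressMessages(partition_by_segregation(co3, all_ids))
  want <- brute_force_partition(co3, all_ids)
  expect_equal(got[, c("variant_id", "segregation")], want,
               ignore_attr = TRUE)
  expect_identical(anyDuplicated(got$variant_id), 0L)
  expect_setequal(got$variant_id,
                  unique(co3$genotypes$variant_id[co3$genotypes$allele_count > 0]))

  # unknown-affection carriers force 'shared' with a warning
  co4 <- make_random_cohort(12, n_ind = 15, n_var = 20, p_unknown = 0.4)
  expect_warning(got4 <- suppressMessages(partition_by_segregation(co4)),
                 "unknown")
  want4 <- brute_force_partition(co4, unique(co4$genotypes$variant_id))
  expect_equal(got4[, c("variant_id", "segregation")], want4,
               ignore_attr = TRUE)
})

test_that("variant tables round-trip through the TSV and VCF dialects", {
  v <- dplyr::bind_rows(
    make_variant(id = "rs1", gene = "EARS2", population_maf = 0.001),
    make_variant(id = "rs2", gene = "TRMU", consequence = "synonymous",
                 population_maf = 0.2),
    make_variant(id = "mt1", gene = "MT-TE", consequence = "other",
                 genome = "mitochondrial", population_maf = 1e-4)
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v, tsv)
  expect_equal(as.data.frame(read_variants(tsv)), as.data.frame(v))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQCLS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=DMG,Number=1,Type=Integer,Description=\"Damaging consensus\">",
    "##INFO=<ID=CONS,Number=1,Type=Integer,Description=\"Conserved\">",
    "##INFO=<ID=DOM,Number=1,Type=Integer,Description=\"InterPro domain\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population MAF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr16\t1000\trs1\tA\tG\t.\t.\tGENE=EARS2;CSQCLS=missense;DMG=1;CONS=1;DOM=1;MAF=0.001",
    "chrM\t14674\t.\tT\tC\t.\t.\tGENE=MT-TE;CSQCLS=other;DMG=1;CONS=1;DOM=0;MAF=0.0001"
  ), vcf)
  got <- read_variants(vcf)
  expect_identical(got$id, c("rs1", "chrM:14674:T>C"))
  expect_identical(got$genome, c("nuclear", "mitochondrial"))
  expect_equal(got$population_maf, c(0.001, 1e-4))
  expect_true(classify_pathogenic(got)$pathogenic[1])
})
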