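# Fixtures built in code; seeded so every run sees the same data.

make_variant <- function(id = "v1", gene = "EARS2", consequence = "missense",
                         predicted_damaging = TRUE, conserved = TRUE,
                         in_domain = TRUE, population_maf = 0.0005,
                         genome = "nuclear") {
  tibble::tibble(
    id = id, contig = if (genome == "nuclear") "chr16" else "chrM",
    position = 1L, ref_allele = "A", alt_allele = "G", gene = gene,
    consequence = consequence, predicted_damaging = predicted_damaging,
    conserved = conserved, in_domain = in_domain,
    population_maf = population_maf, genome = genome
  )
}

# random cohort for exhaustive-scan oracles
make_random_cohort <- function(seed, n_ind = 20, n_var = 50,
                               p_unknown = 0) {
  withr::with_seed(seed, {
    ids <- sprintf("i%02d", seq_len(n_ind))
    individuals <- tibble::tibble(
      id = ids,
      family_id = sample(sprintf("F%d", 1:5), n_ind, replace = TRUE),
      father_id = NA_character_, mother_id = NA_character_,
      sex = sample(c("male", "female"), n_ind, replace = TRUE),
      affection = sample(c("affected", "unaffected", "unknown"), n_ind,
                         replace = TRUE,
                         prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2,
                                  p_unknown)),
      mt_carrier = sample(c(TRUE, FALSE), n_ind, replace = TRUE)
    )
    genotypes <- tidyr::expand_grid(
      individual_id = ids,
      variant_id = sprintf("v%03d", seq_len(n_var))
    ) |>
      dplyr::mutate(allele_count = sample(0:2, dplyr::n(), replace = TRUE,
                                          prob = c(0.85, 0.12, 0.03))) |>
      dplyr::filter(allele_count > 0)
    suppressWarnings(cohort(individuals, genotypes))
  })
}

# independent diplotype-enumeration oracle for carrier probabilities:
# enumerates every combination of per-site genotype counts (0/1/2) under
# Hardy-Weinberg and sums the probability of carrying >= 1 allele.
enumerate_carrier_prob <- function(mafs) {
  stopifnot(length(mafs) <= 3)
  grids <- rep(list(0:2), length(mafs))
  combos <- expand.grid(grids)
  total <- 0
  for (i in seq_len(nrow(combos))) {
    counts <- as.numeric(combos[i, ])
    prob <- prod(stats::dbinom(counts, 2, mafs))
    if (sum(counts) >= 1) total <- total + prob
  }
  total
}

# brute-force segregation classification, one variant at a time
brute_force_partition <- function(co, variant_ids) {
  res <- list()
  for (v in variant_ids) {
    carriers <- co$genotypes$individual_id[
      co$genotypes$variant_id == v & co$genotypes$allele_count > 0]
    if (length(carriers) == 0) next
    aff <- co$individuals$affection[match(carriers, co$individuals$id)]
    cls <- if (any(aff == "unknown")) "shared"
    else if (all(aff == "affected")) "affected_only"
    else if (all(aff == "unaffected")) "unaffected_only"
    else "shared"
    res[[v]] <- cls
  }
  tibble::tibble(variant_id = names(res), segregation = unlist(res)) |>
    dplyr::arrange(variant_id)
}

# brute-force per-individual allele count (genotype-table summation)
brute_force_counts <- function(co, variant_ids = NULL) {
  sapply(co$individuals$id, function(i) {
    rows <- co$genotypes$individual_id == i
    if (!is.null(variant_ids)) {
      rows <- rows & co$genotypes$variant_id %in% variant_ids
    }
    sum(co$genotypes$allele_count[rows]) +
      co$individuals$mt_carrier[co$individuals$id == i]
  })
}
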