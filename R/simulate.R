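#' Simulation configuration
#'
#' Collects every parameter of the cohort/genotype/assay simulators in one
#' seeded object. Defaults encode the study conditions the analysis assumes:
#' a homoplasmic mtDNA variant at frequency 1e-4, the six-gene modifier panel
#' at its published cumulative MAFs (EARS2 0.0135, TRMU 0.09695, panel total
#' 0.32), 19 maternally ascertained families, 1,044 population controls, and
#' a digenic penetrance model in which an mtDNA carrier with at least one
#' modifier allele is affected with high probability while mtDNA-only
#' carriers and non-carriers almost never are.
#'
#' @param seed Integer root seed (mandatory; every simulator stream is derived
#'   from it deterministically).
#' @param n_families Number of nuclear families (default 19).
#' @param n_children Children per family (default 2).
#' @param freq_mt Population frequency of the homoplasmic mtDNA variant
#'   (default 1e-4). Setting it to 0 removes all carriers, including from
#'   ascertained families.
#' @param panel_mafs Modifier-panel frequency table (gene, variant_id, maf);
#'   default [default_panel_frequencies()].
#' @param pi_digenic P(affected | mtDNA carrier & >= 1 modifier allele),
#'   default 0.9.
#' @param pi_mt_only P(affected | mtDNA carrier, no modifier), default 0.01.
#' @param pi_background P(affected | no mtDNA variant), default 0.001.
#' @param n_controls Number of population controls (default 1044).
#' @param n_noise_variants Non-qualifying background variants added to the
#'   cohort variant table (synonymous/benign, random MAFs), default 20.
#' @param expression_beta,expression_sigma Slope and noise SD of the
#'   composition-coupled expression generator. The defaults (18 and 0.35)
#'   give a population correlation near 0.6 over the 13 proteins: with the
#'   packaged composition spread (SD of the E+Q fraction ~ 0.0148),
#'   r = beta*sd_x / sqrt((beta*sd_x)^2 + sigma^2) ~ 0.61.
#' @param ct_delta_by_group Named vector of true delta-Ct per qPCR group
#'   (default `c(control = 5, affected = 3)`: patients at one quarter the
#'   control copy number).
#' @param ct_n_per_group,ct_baseline_mt,ct_noise_sd qPCR group size, target
#'   baseline Ct and per-measurement Ct noise SD.
#' @param prot_n,prot_mean,prot_sd,prot_n_up,prot_n_down Size, location,
#'   scale and injected up/down outlier counts of the proteome ratio table.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_families = 19,
                              n_children = 2,
                              freq_mt = 1e-4,
                              panel_mafs = default_panel_frequencies(),
                              pi_digenic = 0.9,
                              pi_mt_only = 0.01,
                              pi_background = 0.001,
                              n_controls = 1044,
                              n_noise_variants = 20,
                              expression_beta = 18,
                              expression_sigma = 0.35,
                              ct_delta_by_group = c(control = 5, affected = 3),
                              ct_n_per_group = 4,
                              ct_baseline_mt = 20,
                              ct_noise_sd = 0.1,
                              prot_n = 1600,
                              prot_mean = -0.61,
                              prot_sd = 0.795,
                              prot_n_up = 20,
                              prot_n_down = 20) {
  if (missing(seed)) abort("`seed` is mandatory: no unseeded simulation.")
  check_fraction(freq_mt, "freq_mt")
  check_fraction(c(pi_digenic, pi_mt_only, pi_background), "penetrance model")
  check_fraction(panel_mafs$maf, "panel_mafs$maf")
  structure(
    list(seed = as.integer(seed), n_families = n_families,
         n_children = n_children, freq_mt = freq_mt, panel_mafs = panel_mafs,
         pi_digenic = pi_digenic, pi_mt_only = pi_mt_only,
         pi_background = pi_background, n_controls = n_controls,
         n_noise_variants = n_noise_variants,
         expression_beta = expression_beta,
         expression_sigma = expression_sigma,
         ct_delta_by_group = ct_delta_by_group,
         ct_n_per_group = ct_n_per_group, ct_baseline_mt = ct_baseline_mt,
         ct_noise_sd = ct_noise_sd, prot_n = prot_n, prot_mean = prot_mean,
         prot_sd = prot_sd, prot_n_up = prot_n_up, prot_n_down = prot_n_down),
    class = "simulation_config"
  )
}

panel_variant_table <- function(panel_mafs) {
  tibble(
    id = panel_mafs$variant_id,
    contig = "nuclear", position = seq_len(nrow(panel_mafs)),
    ref_allele = "A", alt_allele = "G",
    gene = panel_mafs$gene, consequence = "missense",
    predicted_damaging = TRUE, conserved = TRUE, in_domain = TRUE,
    population_maf = panel_mafs$maf, genome = "nuclear"
  )
}

mt_variant_row <- function(freq_mt) {
  tibble(
    id = "mt_tRNAGlu_homoplasmic", contig = "chrM", position = 14674L,
    ref_allele = "T", alt_allele = "C", gene = "MT-TE",
    consequence = "other", predicted_damaging = TRUE, conserved = TRUE,
    in_domain = FALSE, population_maf = freq_mt, genome = "mitochondrial"
  )
}

#' Simulate an ascertained family cohort with maternal mtDNA transmission
#'
#' Builds nuclear families (two founders plus children). Families are
#' ascertained through the maternal line: every founder mother is a
#' homoplasmic mtDNA carrier whenever `freq_mt > 0` (and never when
#' `freq_mt = 0`), and all her children inherit the variant — homoplasmic
#' mtDNA passes maternally without segregation. Nuclear panel alleles are
#' drawn binomially at their MAFs in founders and transmitted Mendelianly
#' (each parent passes each allele with probability count/2). Affection is
#' assigned from the digenic penetrance model given the latent state
#' (mtDNA carrier, modifier allele present).
#'
#' @param config A [simulation_config()].
#' @return List with components `cohort` (an [cohort()] object), `variants`
#'   (annotated variant table: panel + mtDNA + noise variants) and `truth`
#'   (per-individual latent state: `mt_carrier`, `modifier_count`,
#'   `p_affected`, `affected`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pm <- config$panel_mafs
  founder_mt <- config$freq_mt > 0

  sim <- withr::with_seed(derive_seed(config$seed, 1L), {
    inds <- list(); genos <- list()
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("F%02d", f)
      mother <- paste0(fam, "_mo"); father <- paste0(fam, "_fa")
      kids <- paste0(fam, "_c", seq_len(config$n_children))

      draw_founder <- function() rbinom(nrow(pm), 2L, pm$maf)
      g_mo <- draw_founder(); g_fa <- draw_founder()
      transmit <- function(g) rbinom(length(g), 1L, g / 2)
      g_kids <- lapply(kids, function(k) transmit(g_mo) + transmit(g_fa))

      ids <- c(mother, father, kids)
      gmat <- do.call(rbind, c(list(g_mo, g_fa), g_kids))
      mt <- c(founder_mt, FALSE, rep(founder_mt, length(kids)))

      inds[[f]] <- tibble(
        id = ids, family_id = fam,
        father_id = c(NA, NA, rep(father, length(kids))),
        mother_id = c(NA, NA, rep(mother, length(kids))),
        sex = c("female", "male",
                sample(c("male", "female"), length(kids), replace = TRUE)),
        mt_carrier = mt,
        modifier_count = rowSums(gmat)
      )
      genos[[f]] <- tibble(
        individual_id = rep(ids, each = nrow(pm)),
        variant_id = rep(pm$variant_id, length(ids)),
        allele_count = as.integer(t(gmat))
      )
    }
    individuals <- bind_rows(inds)
    p_aff <- ifelse(
      individuals$mt_carrier & individuals$modifier_count >= 1, config$pi_digenic,
      ifelse(individuals$mt_carrier, config$pi_mt_only, config$pi_background)
    )
    individuals$affected <- runif(nrow(individuals)) < p_aff
    individuals$p_affected <- p_aff

    # background variants that should fail classification or rarity
    noise <- if (config$n_noise_variants > 0) {
      tibble(
        id = sprintf("noise_%03d", seq_len(config$n_noise_variants)),
        contig = "nuclear",
        position = 1000L + seq_len(config$n_noise_variants),
        ref_allele = "C", alt_allele = "T",
        gene = sprintf("GENE%03d", seq_len(config$n_noise_variants)),
        consequence = sample(c("synonymous", "missense", "other"),
                             config$n_noise_variants, replace = TRUE),
        predicted_damaging = FALSE, conserved = FALSE, in_domain = FALSE,
        population_maf = runif(config$n_noise_variants, 0, 0.5),
        genome = "nuclear"
      )
    } else NULL
    noise_geno <- if (!is.null(noise)) {
      tidyr::expand_grid(individual_id = individuals$id, nv = seq_len(nrow(noise))) |>
        mutate(variant_id = noise$id[.data$nv],
               allele_count = rbinom(n(), 2L, noise$population_maf[.data$nv])) |>
        select("individual_id", "variant_id", "allele_count")
    } else NULL

    list(individuals = individuals, genotypes = bind_rows(genos),
         noise = noise, noise_geno = noise_geno)
  })

  individuals <- sim$individuals |>
    mutate(affection = ifelse(.data$affected, "affected", "unaffected"))
  truth <- select(individuals, individual_id = "id", "family_id", "mt_carrier",
                  "modifier_count", "p_affected", "affected")
  genotypes <- bind_rows(sim$genotypes, sim$noise_geno) |>
    filter(.data$allele_count > 0)
  variants <- bind_rows(panel_variant_table(pm), mt_variant_row(config$freq_mt),
                        sim$noise)

  co <- cohort(
    select(individuals, "id", "family_id", "father_id", "mother_id", "sex",
           "affection", "mt_carrier"),
    genotypes
  )
  list(cohort = co, variants = variants, truth = truth)
}

#' Simulate population control genotypes
#'
#' Independent binomial genotype draws per panel variant at its MAF for
#' `n_controls` unrelated individuals. Controls are unaffected, pedigree-free
#' and are non-carriers of the mtDNA variant unless `mt_at_frequency = TRUE`,
#' in which case carrier status is drawn at `freq_mt` (useful for
#' frequency-recovery checks on large simulated populations).
#'
#' @param config A [simulation_config()].
#' @param n Number of controls; defaults to `config$n_controls`.
#' @param mt_at_frequency Draw mtDNA carrier status at `config$freq_mt`
#'   instead of setting it `FALSE`.
#' @return An [cohort()] object whose individuals carry `group = "control"`.
#' @export
simulate_control_genotypes <- function(config, n = config$n_controls,
                                       mt_at_frequency = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  pm <- config$panel_mafs
  out <- withr::with_seed(derive_seed(config$seed, 2L), {
    ids <- sprintf("ctrl_%05d", seq_len(n))
    gmat <- vapply(pm$maf, function(p) rbinom(n, 2L, p), integer(n))
    if (n == 1L) gmat <- matrix(gmat, nrow = 1)
    mt <- if (mt_at_frequency) runif(n) < config$freq_mt else rep(FALSE, n)
    list(ids = ids, gmat = gmat, mt = mt)
  })
  individuals <- tibble(
    id = out$ids, family_id = NA_character_,
    father_id = NA_character_, mother_id = NA_character_,
    sex = NA_character_, affection = "unaffected",
    mt_carrier = out$mt, group = "control"
  )
  genotypes <- tibble(
    individual_id = rep(out$ids, times = nrow(config$panel_mafs)),
    variant_id = rep(config$panel_mafs$variant_id, each = n),
    allele_count = as.integer(out$gmat)
  ) |> filter(.data$allele_count > 0)
  cohort(individuals, genotypes)
}

#' Merge a family cohort with population controls
#'
#' @param family_cohort,control_cohort [cohort()] objects; individuals of the
#'   second receive `group = "control"` if not already set.
#' @return A combined [cohort()] object with a `group` column.
#' @export
bind_cohorts <- function(family_cohort, control_cohort) {
  fi <- family_cohort$individuals
  if (!"group" %in% names(fi)) fi$group <- fi$affection
  ci <- control_cohort$individuals
  if (!"group" %in% names(ci)) ci$group <- "control"
  cohort(bind_rows(fi, ci),
         bind_rows(family_cohort$genotypes, control_cohort$genotypes),
         panel = family_cohort$panel)
}

#' Simulate composition-coupled expression changes
#'
#' Per-gene expression metric generated as a linear function of the
#' target-residue fraction plus Gaussian noise:
#' `metric = intercept + beta * fraction_target + N(0, sigma^2)`. With the
#' sign convention that larger values mean stronger decrease, a positive
#' `beta` reproduces the pattern where residue-rich proteins lose more
#' expression.
#'
#' @param comp Composition table from [composition_table()].
#' @param beta Slope on `fraction_target`.
#' @param sigma Noise SD.
#' @param seed Integer seed (mandatory).
#' @param intercept Baseline metric value (default 0).
#' @param metric Name of the output metric column (default `"log2fc"`).
#' @return Tibble `gene`, `<metric>`.
#' @export
simulate_expression <- function(comp, beta, sigma, seed, intercept = 0,
                                metric = "log2fc") {
  stopifnot("gene" %in% names(comp), "fraction_target" %in% names(comp))
  vals <- withr::with_seed(derive_seed(seed, 3L), {
    intercept + beta * comp$fraction_target + rnorm(nrow(comp), 0, sigma)
  })
  out <- tibble(gene = comp$gene)
  out[[metric]] <- vals
  out
}

#' Simulate qPCR Ct and proteome log2-ratio tables
#'
#' Generates (i) a Ct table whose groups differ by specified true delta-Ct
#' values — mitochondrial Ct around a baseline, nuclear Ct at
#' `ct_mt + delta_ct`, both with independent measurement noise — and (ii) a
#' proteome table of log2 ratios drawn from N(mean, sd) with injected up- and
#' down-regulated outliers placed 4 SD outside the centre and given small
#' ANOVA p-values; null proteins get uniform p-values. Ground-truth labels
#' are retained in the `truth` column.
#'
#' @param config A [simulation_config()].
#' @return List with tibbles `ct` (sample_id, group, ct_nuclear, ct_mt) and
#'   `proteins` (protein_id, log2_ratio, anova_p, unique_peptides,
#'   quantified_in_all, truth).
#' @export
simulate_assay_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(derive_seed(config$seed, 4L), {
    groups <- names(config$ct_delta_by_group)
    ct <- purrr::map(groups, function(g) {
      n <- config$ct_n_per_group
      ct_mt <- rnorm(n, config$ct_baseline_mt, config$ct_noise_sd)
      tibble(
        sample_id = paste0(g, "_", seq_len(n)),
        group = g,
        ct_nuclear = ct_mt + config$ct_delta_by_group[[g]] +
          rnorm(n, 0, config$ct_noise_sd),
        ct_mt = ct_mt
      )
    }) |> bind_rows()

    n_null <- config$prot_n - config$prot_n_up - config$prot_n_down
    stopifnot(n_null > 0)
    ratios <- c(
      rnorm(n_null, config$prot_mean, config$prot_sd),
      config$prot_mean + 4 * config$prot_sd +
        abs(rnorm(config$prot_n_up, 0, config$prot_sd / 2)),
      config$prot_mean - 4 * config$prot_sd -
        abs(rnorm(config$prot_n_down, 0, config$prot_sd / 2))
    )
    truth <- c(rep("null", n_null), rep("up", config$prot_n_up),
               rep("down", config$prot_n_down))
    pvals <- ifelse(truth == "null", runif(config$prot_n),
                    runif(config$prot_n, 0, 0.01))
    proteins <- tibble(
      protein_id = sprintf("P%05d", seq_len(config$prot_n)),
      log2_ratio = ratios,
      anova_p = pvals,
      unique_peptides = runif(config$prot_n) > 0.02,
      quantified_in_all = runif(config$prot_n) > 0.02,
      truth = truth
    )
    list(ct = ct, proteins = proteins)
  })
}

# Real chain lengths of the 13 mtDNA-encoded proteins, and synthetic E+Q
# targets emulating the complex-I enrichment (ND5 highest absolute count).
mt_protein_targets <- function() {
  tibble(
    gene = c("MT-ATP6", "MT-ATP8", "MT-CO1", "MT-CO2", "MT-CO3", "MT-CYB",
             "MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
             "MT-ND6"),
    length = c(226L, 68L, 513L, 227L, 261L, 380L,
               318L, 347L, 115L, 459L, 98L, 603L, 174L),
    eq_count = c(9L, 5L, 20L, 12L, 10L, 15L,
                 22L, 24L, 8L, 32L, 7L, 42L, 12L)
  )
}

#' Generate the synthetic mtDNA-encoded proteome
#'
#' Deterministic generator behind the packaged FASTA stand-in for the 13
#' human mtDNA-encoded proteins: chain lengths match the human subunits
#' (e.g. ND5 = 603 residues), glutamate+glutamine counts follow the real
#' qualitative pattern (complex I subunits enriched, ND5 carrying the highest
#' absolute count), E/Q positions are placed uniformly at random and the
#' remaining residues are drawn from a hydrophobic, membrane-protein-like
#' background distribution. These are synthetic sequences, not the human
#' reference.
#'
#' @param seed Integer seed (default 1, the seed of the packaged fixture).
#' @return Named character vector of 13 protein sequences.
#' @export
simulate_mt_proteome <- function(seed = 1) {
  targets <- mt_protein_targets()
  background <- c(
    L = 0.16, I = 0.09, T = 0.08, A = 0.08, S = 0.07, F = 0.06, V = 0.06,
    M = 0.05, P = 0.05, G = 0.05, N = 0.05, Y = 0.04, W = 0.03, H = 0.03,
    R = 0.025, K = 0.025, D = 0.02, C = 0.02
  )
  withr::with_seed(derive_seed(seed, 5L), {
    seqs <- purrr::pmap_chr(targets, function(gene, length, eq_count) {
      chars <- sample(names(background), length, replace = TRUE,
                      prob = background)
      pos <- sample.int(length, eq_count)
      chars[pos] <- sample(c("E", "Q"), eq_count, replace = TRUE,
                           prob = c(0.6, 0.4))
      paste(chars, collapse = "")
    })
    setNames(seqs, targets$gene)
  })
}
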