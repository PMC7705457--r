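#' Per-individual cumulative damaging-allele counts
#'
#' Sums, for every individual, the allele counts of the qualifying nuclear
#' panel variants, and adds one allele for carriers of the homoplasmic mtDNA
#' variant. The homoplasmic variant is counted as a single allele per carrier:
#' the typical digenic patient (mtDNA variant plus one heterozygous nuclear
#' modifier) then scores 2, and a severe patient with variants in two modifier
#' genes scores 3, matching how per-person allele counts are tallied in
#' pedigree burden plots.
#'
#' @param cohort An [cohort()] object.
#' @param variant_ids Variant ids to count over (typically the damaging-rare
#'   set from [damaging_rare_variants()]); defaults to all genotyped variants.
#' @return Tibble with one row per individual: `individual_id`, `family_id`,
#'   `group` (`affected`, `unaffected` or `control`; unknown-affection
#'   individuals are excluded with a message) and `allele_count`.
#' @export
burden_table <- function(cohort, variant_ids = NULL) {
  stopifnot(inherits(cohort, "mt_cohort"))
  ind <- cohort$individuals
  if (!"group" %in% names(ind)) ind$group <- ind$affection

  n_unknown <- sum(ind$group == "unknown")
  if (n_unknown > 0) {
    inform(sprintf(
      "%d individual(s) of unknown affection excluded from the burden table.",
      n_unknown
    ))
    ind <- filter(ind, .data$group != "unknown")
  }
  if (nrow(ind) == 0) {
    return(tibble(individual_id = character(), family_id = character(),
                  group = character(), allele_count = integer()))
  }

  geno <- cohort$genotypes
  if (!is.null(variant_ids)) {
    geno <- filter(geno, .data$variant_id %in% .env$variant_ids)
  }
  nuc <- geno |>
    group_by(individual_id = .data$individual_id) |>
    summarise(nuclear = sum(.data$allele_count), .groups = "drop")

  ind |>
    left_join(nuc, by = c(id = "individual_id")) |>
    mutate(
      nuclear = dplyr::coalesce(.data$nuclear, 0L),
      allele_count = as.integer(.data$nuclear + .data$mt_carrier)
    ) |>
    select(individual_id = "id", "family_id", "group", "allele_count")
}

#' Cumulative allele count for one individual
#'
#' @param individual_id Individual id present in the cohort.
#' @inheritParams burden_table
#' @return A single non-negative integer.
#' @export
individual_allele_count <- function(individual_id, cohort, variant_ids = NULL) {
  stopifnot(inherits(cohort, "mt_cohort"))
  ind <- filter(cohort$individuals, .data$id == individual_id)
  if (nrow(ind) != 1L) abort(sprintf("Individual '%s' not in cohort.", individual_id))
  geno <- filter(cohort$genotypes, .data$individual_id == .env$individual_id)
  if (!is.null(variant_ids)) {
    geno <- filter(geno, .data$variant_id %in% .env$variant_ids)
  }
  as.integer(sum(geno$allele_count) + ind$mt_carrier)
}

#' Compare mean allele burden between two groups
#'
#' Two-sided comparison of per-individual cumulative allele counts between two
#' groups, by pooled-variance Student's t-test (default), Welch's t-test, or a
#' seeded label-permutation test on the difference of means. The permutation
#' p-value uses the add-one estimator
#' `(1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_perm)`, so it is never
#' exactly zero and the seed fully determines the resampling stream.
#'
#' @param counts_a,counts_b Numeric vectors of allele counts (first group is
#'   conventionally the affected one).
#' @param method `"student_t"`, `"welch_t"` or `"permutation"`.
#' @param n_perm Number of label permutations (permutation method only).
#' @param seed Integer seed for the permutation stream; required for
#'   `method = "permutation"`.
#' @param labels Length-2 character vector naming the groups.
#' @return A `burden_comparison` object; see [tidy.burden_comparison()] and
#'   [glance.burden_comparison()].
#' @details Degenerate inputs are resolved explicitly: equal means with zero
#'   variance give `t = 0`, `p = 1`; unequal means with zero pooled variance
#'   give the smallest representable positive p-value with a warning.
#' @examples
#' compare_group_means(c(0, 1, 1, 2), c(2, 3, 3, 4))
#' @export
compare_group_means <- function(counts_a, counts_b,
                                method = c("student_t", "welch_t", "permutation"),
                                n_perm = 10000, seed = NULL,
                                labels = c("group_a", "group_b")) {
  method <- match.arg(method)
  counts_a <- as.numeric(counts_a)
  counts_b <- as.numeric(counts_b)
  min_n <- if (method == "permutation") 1L else 2L
  if (length(counts_a) < min_n || length(counts_b) < min_n) {
    abort(sprintf("Each group needs at least %d observation(s) for method '%s'.",
                  min_n, method))
  }

  diff_obs <- mean(counts_a) - mean(counts_b)
  res <- list(
    labels = labels,
    ns = c(length(counts_a), length(counts_b)),
    means = c(mean(counts_a), mean(counts_b)),
    sds = c(sd(counts_a), sd(counts_b)),
    mean_difference = diff_obs,
    method = method,
    permutation_p = NA_real_
  )

  pooled_var <- function() {
    na <- length(counts_a); nb <- length(counts_b)
    ((na - 1) * stats::var(counts_a) + (nb - 1) * stats::var(counts_b)) /
      (na + nb - 2)
  }

  if (method %in% c("student_t", "welch_t")) {
    degenerate <- isTRUE(all.equal(pooled_var(), 0)) || pooled_var() == 0
    if (degenerate) {
      if (diff_obs == 0) {
        res$t_statistic <- 0
        res$degrees_of_freedom <- sum(res$ns) - 2
        res$p_value <- 1
      } else {
        warn("Zero pooled variance with unequal means; p set to smallest positive value.")
        res$t_statistic <- sign(diff_obs) * Inf
        res$degrees_of_freedom <- sum(res$ns) - 2
        res$p_value <- .Machine$double.xmin
      }
    } else {
      tt <- t.test(counts_a, counts_b, var.equal = (method == "student_t"))
      res$t_statistic <- unname(tt$statistic)
      res$degrees_of_freedom <- unname(tt$parameter)
      res$p_value <- tt$p.value
    }
  } else {
    if (is.null(seed)) abort("`seed` is required for the permutation method.")
    pooled <- c(counts_a, counts_b)
    na <- length(counts_a)
    perm_diffs <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), na)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm_diffs) >= abs(diff_obs))) / (1 + n_perm)
    res$t_statistic <- NA_real_
    res$degrees_of_freedom <- NA_real_
    res$p_value <- p
    res$permutation_p <- p
  }

  structure(res, class = "burden_comparison")
}

#' Compare burden between two groups of a burden table
#'
#' Tidy front end to [compare_group_means()]: picks two groups out of a
#' [burden_table()] result and compares their allele counts.
#'
#' @param burden A tibble from [burden_table()] (columns `group`,
#'   `allele_count`).
#' @param groups Length-2 character vector of group labels to compare.
#' @inheritParams compare_group_means
#' @return A `burden_comparison` object.
#' @export
compare_burden <- function(burden, groups = c("affected", "unaffected"),
                           method = c("student_t", "welch_t", "permutation"),
                           n_perm = 10000, seed = NULL) {
  stopifnot(length(groups) == 2L, all(c("group", "allele_count") %in% names(burden)))
  a <- burden$allele_count[burden$group == groups[1]]
  b <- burden$allele_count[burden$group == groups[2]]
  compare_group_means(a, b, method = method, n_perm = n_perm, seed = seed,
                      labels = groups)
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat("<burden_comparison> ", x$method, "\n", sep = "")
  cat(sprintf("  %s: n = %d, mean = %.3f (sd %.3f)\n",
              x$labels[1], x$ns[1], x$means[1], x$sds[1]))
  cat(sprintf("  %s: n = %d, mean = %.3f (sd %.3f)\n",
              x$labels[2], x$ns[2], x$means[2], x$sds[2]))
  if (!is.na(x$t_statistic)) {
    cat(sprintf("  t = %.3f, df = %.2f, p = %.3g\n",
                x$t_statistic, x$degrees_of_freedom, x$p_value))
  } else {
    cat(sprintf("  permutation p = %.3g\n", x$p_value))
  }
  invisible(x)
}

#' Tidy a burden comparison into per-group rows
#'
#' @param x A `burden_comparison` object.
#' @param ... Unused.
#' @return Tibble with one row per group: `group`, `n`, `mean`, `sd`.
#' @method tidy burden_comparison
#' @export
tidy.burden_comparison <- function(x, ...) {
  tibble(group = x$labels, n = x$ns, mean = x$means, sd = x$sds)
}

#' One-row summary of a burden comparison
#'
#' @param x A `burden_comparison` object.
#' @param ... Unused.
#' @return One-row tibble: `mean_difference`, `statistic`, `df`, `p.value`,
#'   `permutation_p`, `method`.
#' @method glance burden_comparison
#' @export
glance.burden_comparison <- function(x, ...) {
  tibble(
    mean_difference = x$mean_difference,
    statistic = x$t_statistic,
    df = x$degrees_of_freedom,
    p.value = x$p_value,
    permutation_p = x$permutation_p,
    method = x$method
  )
}

#' Monte-Carlo power of the burden comparison
#'
#' Simulates per-individual allele counts for two groups under a shared
#' panel-frequency model, adds an effect (extra expected alleles, drawn
#' Poisson) to the first group, runs the chosen comparison in each replicate
#' and reports the rejection rate at level `alpha` with its binomial
#' Monte-Carlo standard error. With `effect = 0` this measures type-I error.
#'
#' @param panel_mafs Numeric vector of per-variant MAFs defining the baseline
#'   count model (each individual draws `rbinom(2, maf)` alleles per variant).
#' @param group_sizes Length-2 integer vector, e.g. `c(22, 12)`.
#' @param effect Expected extra alleles per individual in group 1 (Poisson
#'   mean; 0 = null model).
#' @param n_sims Number of simulated datasets (>= 100).
#' @param alpha Significance level.
#' @param method Comparison method, as in [compare_group_means()].
#' @param n_perm Permutations per replicate if `method = "permutation"`.
#' @param seed Integer root seed (required).
#' @return One-row tibble: `power`, `mc_se`, `n_sims`, `alpha`, `effect`.
#' @export
simulate_burden_power <- function(panel_mafs, group_sizes = c(22, 12),
                                  effect = 1, n_sims = 1000, alpha = 0.05,
                                  method = "student_t", n_perm = 199,
                                  seed) {
  check_fraction(panel_mafs, "panel_mafs")
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 2), n_sims >= 100)

  draw_counts <- function(n) {
    base <- vapply(seq_len(n), function(i) {
      sum(rbinom(length(panel_mafs), 2L, panel_mafs))
    }, numeric(1))
    base
  }

  rejected <- withr::with_seed(derive_seed(seed, 101L), {
    vapply(seq_len(n_sims), function(i) {
      a <- draw_counts(group_sizes[1])
      if (effect > 0) a <- a + rpois(group_sizes[1], effect)
      b <- draw_counts(group_sizes[2])
      cmp <- compare_group_means(
        a, b, method = method, n_perm = n_perm,
        seed = if (method == "permutation") derive_seed(seed, 10000L + i) else NULL
      )
      cmp$p_value < alpha
    }, logical(1))
  })

  power <- mean(rejected)
  tibble(
    power = power,
    mc_se = sqrt(power * (1 - power) / n_sims),
    n_sims = n_sims,
    alpha = alpha,
    effect = effect
  )
}
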