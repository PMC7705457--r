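#' Filtering configuration for damaging-variant classification
#'
#' Bundles the tunable thresholds of the variant-classification step.
#' Truncating consequences (splice site, frameshift, stop gain/loss) always
#' qualify; missense variants must additionally be predicted damaging and,
#' depending on the switches here, fall in an evolutionarily conserved position
#' and a known InterPro domain.
#'
#' @param maf_threshold Population minor-allele-frequency cutoff; variants with
#'   MAF strictly below this pass the rarity filter. The default 0.005 strictly
#'   contains all modifier MAFs reported for the RIRCD gene panel (the rarest
#'   published EARS2 alleles sit below 0.002).
#' @param require_domain Must a qualifying missense variant fall in a known
#'   protein domain? Default `TRUE`.
#' @param require_conservation Must a qualifying missense variant affect a
#'   conserved residue? Default `TRUE`.
#' @return A `filter_config` list.
#' @examples
#' filter_config(maf_threshold = 0.002)
#' @export
filter_config <- function(maf_threshold = 0.005,
                          require_domain = TRUE,
                          require_conservation = TRUE) {
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      !is.finite(maf_threshold) || maf_threshold <= 0 || maf_threshold > 1) {
    abort("`maf_threshold` must be a single value in (0, 1].")
  }
  structure(
    list(
      maf_threshold = maf_threshold,
      require_domain = isTRUE(require_domain),
      require_conservation = isTRUE(require_conservation)
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat("  maf_threshold:        ", format(x$maf_threshold), "\n")
  cat("  require_domain:       ", x$require_domain, "\n")
  cat("  require_conservation: ", x$require_conservation, "\n")
  invisible(x)
}

consequence_levels <- function() {
  c("splice_site", "frameshift", "stop_gain", "stop_loss",
    "missense", "synonymous", "other")
}

truncating_consequences <- function() {
  c("splice_site", "frameshift", "stop_gain", "stop_loss")
}

validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  needed <- c("id", "gene", "consequence", "predicted_damaging",
              "conserved", "in_domain", "population_maf")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("Variant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(variants$consequence), consequence_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown consequence class(es): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(variants$id)) abort("Variant ids must be unique.")
  variants
}

#' Classify variants as potentially pathogenic
#'
#' Applies the qualifying-variant rule used for modifier discovery: a variant
#' is potentially pathogenic if its consequence is truncating (splice site,
#' frameshift, stop gain or stop loss), or if it is missense and predicted
#' damaging by the upstream in-silico consensus, at a conserved residue (unless
#' waived) and inside a known protein domain (unless waived). All other
#' classes, including synonymous, never qualify.
#'
#' @param variants Tibble of annotated variants with columns `id`, `gene`,
#'   `consequence` (one of `splice_site`, `frameshift`, `stop_gain`,
#'   `stop_loss`, `missense`, `synonymous`, `other`), `predicted_damaging`,
#'   `conserved`, `in_domain` (logicals) and `population_maf`.
#' @param config A [filter_config()].
#' @return The input tibble with logical column `pathogenic` and character
#'   column `reason` explaining which branch of the rule fired.
#' @examples
#' v <- tibble::tibble(
#'   id = "EARS2:p.Arg516Gln", gene = "EARS2", consequence = "missense",
#'   predicted_damaging = TRUE, conserved = TRUE, in_domain = TRUE,
#'   population_maf = 0.0005
#' )
#' classify_pathogenic(v)
#' @export
classify_pathogenic <- function(variants, config = filter_config()) {
  variants <- validate_variants(variants)
  stopifnot(inherits(config, "filter_config"))

  is_missense <- variants$consequence == "missense"
  flag_cols <- c("predicted_damaging", "conserved", "in_domain")
  incomplete <- is_missense &
    Reduce(`|`, lapply(variants[flag_cols], is.na))
  if (any(incomplete)) {
    abort(paste0(
      "Missense variant(s) with missing damage/conservation/domain ",
      "annotation: ", paste(variants$id[incomplete], collapse = ", "),
      ". Annotate fully before classification."
    ))
  }

  truncating <- variants$consequence %in% truncating_consequences()
  missense_ok <- is_missense &
    variants$predicted_damaging %in% TRUE &
    (variants$conserved %in% TRUE | !config$require_conservation) &
    (variants$in_domain %in% TRUE | !config$require_domain)

  reason <- dplyr::case_when(
    truncating ~ paste0("truncating consequence (", variants$consequence, ")"),
    missense_ok ~ "damaging missense meeting conservation/domain requirements",
    is_missense ~ "missense failing damage/conservation/domain requirements",
    TRUE ~ paste0("non-qualifying consequence (", variants$consequence, ")")
  )

  mutate(variants, pathogenic = truncating | missense_ok, reason = reason)
}

#' Filter variants by population rarity
#'
#' Keeps variants whose population MAF is strictly below the configured
#' threshold, preserving input order. A missing MAF is treated as 0 (a novel
#' variant passes), with a warning naming the affected variants.
#'
#' @inheritParams classify_pathogenic
#' @return The subset of `variants` passing the rarity filter.
#' @export
apply_rarity_filter <- function(variants, config = filter_config()) {
  variants <- as_tibble(variants)
  stopifnot(inherits(config, "filter_config"), "population_maf" %in% names(variants))
  maf <- variants$population_maf
  if (any(maf < 0, na.rm = TRUE)) abort("Negative population MAF encountered.")
  if (any(maf > 1, na.rm = TRUE)) abort("Population MAF above 1 encountered.")
  if (anyNA(maf)) {
    warn(paste0(
      "Missing MAF treated as 0 (novel allele) for: ",
      paste(variants$id[is.na(maf)], collapse = ", ")
    ))
    maf[is.na(maf)] <- 0
  }
  variants[maf < config$maf_threshold, , drop = FALSE]
}

#' Classify and rarity-filter in one step
#'
#' Convenience composition of [classify_pathogenic()] and
#' [apply_rarity_filter()]: returns only potentially pathogenic variants that
#' are also rare. Idempotent — applying it to its own output returns the same
#' set.
#'
#' @inheritParams classify_pathogenic
#' @return Tibble of damaging, rare variants (with `pathogenic`/`reason`).
#' @export
damaging_rare_variants <- function(variants, config = filter_config()) {
  classified <- classify_pathogenic(variants, config)
  apply_rarity_filter(filter(classified, .data$pathogenic), config)
}

#' Partition variants by segregation with affection status
#'
#' Assigns each variant observed in at least one genotyped carrier to one of
#' three disjoint classes: `affected_only` (every carrier is affected),
#' `unaffected_only` (every carrier is unaffected) or `shared`. Variants with
#' no carriers are dropped and reported in a message. A carrier of unknown
#' affection status forces the variant to `shared` with a warning, because its
#' segregation cannot be resolved.
#'
#' @param cohort A [cohort()] object.
#' @param variant_ids Character vector of variant ids to partition (typically
#'   the damaging-rare set). Defaults to every variant in the genotype table.
#' @return Tibble with columns `variant_id`, `n_affected`, `n_unaffected`,
#'   `n_unknown` (carrier counts) and `segregation`.
#' @export
partition_by_segregation <- function(cohort, variant_ids = NULL) {
  stopifnot(inherits(cohort, "mt_cohort"))
  geno <- cohort$genotypes
  variant_ids <- variant_ids %||% unique(geno$variant_id)

  carriers <- geno |>
    filter(.data$variant_id %in% .env$variant_ids, .data$allele_count > 0) |>
    left_join(
      select(cohort$individuals, individual_id = "id", "affection"),
      by = "individual_id"
    )

  seen <- unique(carriers$variant_id)
  uncarried <- setdiff(variant_ids, seen)
  if (length(uncarried) > 0) {
    inform(sprintf(
      "%d variant(s) with zero carriers excluded from segregation partition.",
      length(uncarried)
    ))
  }
  if (any(carriers$affection == "unknown")) {
    warn("Carrier(s) with unknown affection status: variant(s) forced to 'shared'.")
  }

  carriers |>
    group_by(.data$variant_id) |>
    summarise(
      n_affected = sum(.data$affection == "affected"),
      n_unaffected = sum(.data$affection == "unaffected"),
      n_unknown = sum(.data$affection == "unknown"),
      .groups = "drop"
    ) |>
    mutate(
      segregation = dplyr::case_when(
        .data$n_unknown > 0 ~ "shared",
        .data$n_unaffected == 0 ~ "affected_only",
        .data$n_affected == 0 ~ "unaffected_only",
        TRUE ~ "shared"
      )
    ) |>
    arrange(.data$variant_id)
}
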