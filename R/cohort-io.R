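#' Default nuclear modifier gene panel
#'
#' The six nuclear genes interacting with mt-tRNA(Glu) whose heterozygous
#' damaging alleles are counted in the burden analysis.
#'
#' @return Character vector of gene symbols.
#' @export
default_panel <- function() {
  c("EARS2", "TRMU", "QRSL1", "GOT2", "GLS", "MSS51")
}

#' Assemble a cohort of individuals and genotype calls
#'
#' A cohort couples a pedigree-style individual table (with affection status
#' and homoplasmic mtDNA carrier state) to a long genotype table of nuclear
#' modifier allele counts. The mtDNA variant is carried as the `mt_carrier`
#' flag, not as a genotype row, because the cohort is homoplasmic: carrier
#' status and allele frequency coincide.
#'
#' @param individuals Tibble with columns `id`, `family_id`, `father_id`,
#'   `mother_id` (use `NA` for founders), `sex`, `affection` (one of
#'   `affected`, `unaffected`, `unknown`) and logical `mt_carrier`. An
#'   optional `group` column (`affected`/`unaffected`/`control`) overrides the
#'   grouping derived from `affection`.
#' @param genotypes Tibble with columns `individual_id`, `variant_id`,
#'   `allele_count` (0, 1 or 2).
#' @param panel Gene symbols defining the modifier panel; defaults to
#'   [default_panel()].
#' @return An `mt_cohort` object (a validated list of the two tibbles plus the
#'   panel).
#' @details Maternal consistency of the homoplasmic mtDNA variant is checked
#'   where pedigree links are present: a child whose mother is in the table
#'   should match the mother's carrier state. Violations warn but do not
#'   error, so that genotyping errors can be inspected rather than hidden.
#' @export
cohort <- function(individuals, genotypes, panel = default_panel()) {
  individuals <- as_tibble(individuals)
  genotypes <- as_tibble(genotypes)

  need_ind <- c("id", "family_id", "affection", "mt_carrier")
  missing_cols <- setdiff(need_ind, names(individuals))
  if (length(missing_cols) > 0) {
    abort(paste0("`individuals` missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("father_id", "mother_id", "sex")) {
    if (!col %in% names(individuals)) individuals[[col]] <- NA_character_
  }
  if (anyDuplicated(individuals$id)) abort("Individual ids must be unique.")
  bad_aff <- setdiff(unique(individuals$affection),
                     c("affected", "unaffected", "unknown"))
  if (length(bad_aff) > 0) {
    abort(paste0("Unknown affection value(s): ", paste(bad_aff, collapse = ", ")))
  }

  need_gen <- c("individual_id", "variant_id", "allele_count")
  missing_cols <- setdiff(need_gen, names(genotypes))
  if (length(missing_cols) > 0) {
    abort(paste0("`genotypes` missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(genotypes$allele_count %in% 0:2)) {
    abort("`allele_count` must be 0, 1 or 2.")
  }
  orphan <- setdiff(genotypes$individual_id, individuals$id)
  if (length(orphan) > 0) {
    abort(paste0("Genotype rows reference unknown individual(s): ",
                 paste(head(orphan, 5), collapse = ", ")))
  }

  # homoplasmic mtDNA follows the maternal line; check where links resolve
  mt <- setNames(individuals$mt_carrier, individuals$id)
  has_mother <- !is.na(individuals$mother_id) &
    individuals$mother_id %in% individuals$id
  if (any(has_mother)) {
    mism <- individuals$mt_carrier[has_mother] !=
      mt[individuals$mother_id[has_mother]]
    if (any(mism, na.rm = TRUE)) {
      warn(sprintf(
        "%d individual(s) whose mtDNA carrier state disagrees with the maternal line.",
        sum(mism, na.rm = TRUE)
      ))
    }
  }

  structure(
    list(individuals = individuals, genotypes = genotypes, panel = panel),
    class = "mt_cohort"
  )
}

#' @export
print.mt_cohort <- function(x, ...) {
  aff <- table(factor(x$individuals$affection,
                      c("affected", "unaffected", "unknown")))
  cat("<mt_cohort> ", nrow(x$individuals), " individuals (",
      aff[["affected"]], " affected, ", aff[["unaffected"]], " unaffected, ",
      aff[["unknown"]], " unknown), ",
      sum(x$individuals$mt_carrier), " mtDNA carriers, ",
      nrow(x$genotypes), " genotype calls, panel of ",
      length(x$panel), " genes\n", sep = "")
  invisible(x)
}

#' Read an annotated variant table (TSV or minimal VCF)
#'
#' Two dialects are accepted. (a) A tab-separated table with columns `id`,
#' `contig`, `position`, `ref_allele`, `alt_allele`, `gene`, `consequence`,
#' `predicted_damaging`, `conserved`, `in_domain`, `population_maf`, `genome`.
#' (b) A VCF 4.x file whose INFO field carries `GENE`, `CSQCLS` (consequence
#' class), `DMG`, `CONS`, `DOM` (0/1 flags) and `MAF`; the id is taken from
#' the ID column or synthesised as `contig:pos:ref>alt`. Coordinates are
#' 1-based in both dialects.
#'
#' @param path Path to a `.tsv`/`.txt` or `.vcf` file.
#' @return Tibble of annotated variants suitable for [classify_pathogenic()].
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variants_vcf(path)
  } else {
    v <- readr::read_tsv(path, show_col_types = FALSE)
    validate_variants(v)
  }
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  id <- fix$ID
  synth <- is.na(id) | id == "." | id == ""
  id[synth] <- paste0(fix$CHROM[synth], ":", fix$POS[synth], ":",
                      fix$REF[synth], ">", fix$ALT[synth])
  tibble(
    id = id,
    contig = fix$CHROM,
    position = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    gene = info_get("GENE"),
    consequence = info_get("CSQCLS"),
    predicted_damaging = info_get("DMG") == "1",
    conserved = info_get("CONS") == "1",
    in_domain = info_get("DOM") == "1",
    population_maf = as.numeric(info_get("MAF")),
    genome = ifelse(fix$CHROM %in% c("MT", "chrM", "chrMT", "M"),
                    "mitochondrial", "nuclear")
  ) |>
    validate_variants()
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-separated columns: family id, individual id, father id, mother
#' id, sex (1 male / 2 female / 0 unknown), affection (1 unaffected /
#' 2 affected / 0 unknown). `0` parent ids become `NA` (founder).
#'
#' @param path Path to the PED file.
#' @param mt_carriers Optional character vector of individual ids carrying the
#'   homoplasmic mtDNA variant; defaults to none.
#' @return Tibble in the shape expected by [cohort()].
#' @export
read_pedigree <- function(path, mt_carriers = character()) {
  ped <- readr::read_table(
    path,
    col_names = c("family_id", "id", "father_id", "mother_id", "sex", "aff_code"),
    col_types = "ccccii",
    show_col_types = FALSE
  )
  ped |>
    mutate(
      father_id = dplyr::na_if(.data$father_id, "0"),
      mother_id = dplyr::na_if(.data$mother_id, "0"),
      sex = c("male", "female")[match(.data$sex, 1:2)],
      affection = dplyr::case_when(
        .data$aff_code == 2 ~ "affected",
        .data$aff_code == 1 ~ "unaffected",
        TRUE ~ "unknown"
      ),
      mt_carrier = .data$id %in% mt_carriers
    ) |>
    select("id", "family_id", "father_id", "mother_id", "sex",
           "affection", "mt_carrier")
}

#' Read a long genotype table
#'
#' Tab-separated columns `individual_id`, `variant_id`, `allele_count`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of genotype calls.
#' @export
read_genotypes <- function(path) {
  readr::read_tsv(path, col_types = "cci", show_col_types = FALSE)
}
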