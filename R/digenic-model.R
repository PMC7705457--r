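#' Default modifier-panel frequency table
#'
#' Published cumulative minor-allele frequencies for damaging variants in the
#' six-gene nuclear modifier panel: EARS2 contributes six rare alleles summing
#' to 0.0135, TRMU one common damaging allele (p.Ala10Ser-like) at 0.09695,
#' and the panel-wide additive total is 0.32. The residual mass
#' (0.32 - 0.0135 - 0.09695) is split evenly across QRSL1, GOT2, GLS and
#' MSS51, which the source reports only through the panel total.
#'
#' @return Tibble with columns `gene`, `variant_id`, `maf`.
#' @export
default_panel_frequencies <- function() {
  ears2 <- c(0.0019, 0.0018, 0.0023, 0.0025, 0.0028, 0.0022) # sums to 0.0135
  rest <- (0.32 - 0.0135 - 0.09695) / 4
  tibble(
    gene = c(rep("EARS2", 6), "TRMU", "QRSL1", "GOT2", "GLS", "MSS51"),
    variant_id = c(paste0("EARS2_v", 1:6), "TRMU_A10S",
                   "QRSL1_cum", "GOT2_cum", "GLS_cum", "MSS51_cum"),
    maf = c(ears2, 0.09695, rep(rest, 4))
  )
}

#' Carrier frequency from a list of per-variant MAFs
#'
#' Aggregates per-site minor-allele frequencies into the probability that a
#' person carries at least one qualifying allele, under independence across
#' sites.
#'
#' @param mafs Numeric vector of MAFs in \[0, 1\].
#' @param method Aggregation rule:
#'   * `"additive"` — plain cumulative MAF, `sum(mafs)` clamped at 1. This is
#'     the convention used for the published cumulative carrier frequencies
#'     (e.g. 0.0135 for EARS2, 0.32 panel-wide), accurate for rare alleles.
#'   * `"at_least_one_allele"` — exact probability of carrying >= 1 allele
#'     over independent diploid sites, `1 - prod((1 - p)^2)`.
#'   * `"hardy_weinberg_het"` — probability of being heterozygous at >= 1
#'     site, `1 - prod(1 - 2p(1 - p))`.
#' @return A single fraction.
#' @examples
#' carrier_frequency(c(0.001, 0.002), "at_least_one_allele")
#' @export
carrier_frequency <- function(mafs,
                              method = c("additive", "at_least_one_allele",
                                         "hardy_weinberg_het")) {
  method <- match.arg(method)
  if (length(mafs) == 0) return(0)
  check_fraction(mafs, "mafs")
  switch(method,
    additive = min(sum(mafs), 1),
    at_least_one_allele = 1 - prod((1 - mafs)^2),
    hardy_weinberg_het = 1 - prod(1 - 2 * mafs * (1 - mafs))
  )
}

#' Probability of carrying both the mtDNA variant and a nuclear modifier
#'
#' Product of the homoplasmic mtDNA variant frequency and the nuclear modifier
#' carrier frequency, under independence of the two genomes. For a homoplasmic
#' variant, carrier frequency equals allele frequency, so an mtDNA MAF can be
#' used directly.
#'
#' @param freq_mt mtDNA variant (carrier) frequency in \[0, 1\].
#' @param carrier_freq_nuclear Nuclear modifier carrier frequency in \[0, 1\].
#'   Either a true carrier frequency or a cumulative allele frequency may be
#'   supplied; which one was used should be reported alongside the result.
#' @return The exact co-occurrence probability (no display rounding).
#' @examples
#' co_occurrence_probability(1e-4, 0.0135)   # ~ 1 in a million
#' co_occurrence_probability(1e-4, 0.09695)  # ~ 1 in 100,000
#' @export
co_occurrence_probability <- function(freq_mt, carrier_freq_nuclear) {
  check_fraction(freq_mt, "freq_mt")
  check_fraction(carrier_freq_nuclear, "carrier_freq_nuclear")
  freq_mt * carrier_freq_nuclear
}

#' Predicted penetrance among mtDNA variant carriers
#'
#' Under the digenic model, an mtDNA carrier manifests disease when they also
#' carry at least one damaging allele in the modifier panel; the predicted
#' penetrance among mtDNA carriers is therefore the panel carrier frequency.
#' With the additive method this reproduces the cumulative-MAF-as-penetrance
#' identification (panel total 0.32 -> 32% of carriers affected).
#'
#' @param panel Frequency table with a `maf` column (see
#'   [default_panel_frequencies()]), or a bare numeric vector of MAFs.
#' @param method Aggregation method passed to [carrier_frequency()].
#' @return Predicted penetrance as a fraction.
#' @export
predicted_penetrance <- function(panel, method = "additive") {
  mafs <- if (is.numeric(panel)) panel else {
    stopifnot("maf" %in% names(panel))
    panel$maf
  }
  if (length(mafs) == 0) abort("Modifier panel must be non-empty.")
  carrier_frequency(mafs, method)
}

#' Predicted population prevalence of the digenic disease
#'
#' @param carrier_freq_mt mtDNA carrier frequency (fraction).
#' @param penetrance Penetrance among mtDNA carriers (fraction).
#' @return Prevalence as a fraction (e.g. 1e-4 x 0.30 = 3e-5, i.e. ~1/30,000).
#' @export
predicted_prevalence <- function(carrier_freq_mt, penetrance) {
  check_fraction(carrier_freq_mt, "carrier_freq_mt")
  check_fraction(penetrance, "penetrance")
  carrier_freq_mt * penetrance
}

#' Expected number of cases in a population
#'
#' @param prevalence Disease prevalence (fraction).
#' @param population_size Population size (> 0).
#' @return Expected case count, `prevalence * population_size`.
#' @export
expected_cases <- function(prevalence, population_size) {
  check_fraction(prevalence, "prevalence")
  if (!is.numeric(population_size) || population_size <= 0) {
    abort("`population_size` must be positive.")
  }
  prevalence * population_size
}

#' Allele frequency from observed carrier counts
#'
#' @param carriers Number of carriers observed.
#' @param n_individuals Number of individuals screened (> 0).
#' @param inheritance `"haploid_mt"` (homoplasmic mtDNA: frequency =
#'   carriers / individuals) or `"autosomal"` (heterozygous carriers each
#'   contribute one allele out of 2N).
#' @return Estimated allele frequency.
#' @examples
#' maf_from_carrier_counts(11, 358916)  # UK Biobank style, ~3e-5
#' @export
maf_from_carrier_counts <- function(carriers, n_individuals,
                                    inheritance = c("haploid_mt", "autosomal")) {
  inheritance <- match.arg(inheritance)
  if (n_individuals <= 0) abort("`n_individuals` must be positive.")
  max_carriers <- n_individuals
  if (carriers < 0 || carriers > max_carriers) {
    abort("`carriers` must lie in [0, n_individuals].")
  }
  switch(inheritance,
    haploid_mt = carriers / n_individuals,
    autosomal = carriers / (2 * n_individuals)
  )
}

#' Format a probability as a "1 in N" string
#'
#' Display layer kept separate from the exact arithmetic: rounds 1/p to the
#' requested number of significant figures. A zero probability is rendered
#' explicitly as `"1 in Inf"`.
#'
#' @param p Probability (fraction).
#' @param sig Significant figures for N (default 1, matching headline
#'   reporting such as "1 in a million").
#' @return Character string.
#' @examples
#' format_one_in(1.35e-6)  # "1 in 1e+06"
#' @export
format_one_in <- function(p, sig = 1) {
  check_fraction(p, "p")
  if (p == 0) return("1 in Inf")
  paste0("1 in ", format(signif(1 / p, sig), big.mark = ",", scientific = p < 1e-4))
}

#' Full digenic risk estimate
#'
#' One call that chains the digenic arithmetic: panel carrier frequency
#' (= predicted penetrance among mtDNA carriers), co-occurrence probability,
#' population prevalence and expected case count.
#'
#' @param panel Modifier-panel frequency table (see
#'   [default_panel_frequencies()]).
#' @param freq_mt Homoplasmic mtDNA variant frequency (default 1e-4).
#' @param penetrance_method Aggregation method for the panel (default
#'   `"additive"`).
#' @param penetrance Optional externally supplied penetrance (e.g. the ~0.30
#'   reported in earlier family studies); if `NULL`, uses the panel-derived
#'   value.
#' @param population_size Reference population (default 66,000,000,
#'   a UK-scale figure; configurable, not hard-coded policy).
#' @return One-row tibble: `freq_mt`, `carrier_freq_nuclear`, `co_occurrence`,
#'   `predicted_penetrance`, `predicted_prevalence`, `expected_cases`,
#'   `population_size`, `prevalence_one_in`.
#' @examples
#' digenic_risk(default_panel_frequencies())
#' @export
digenic_risk <- function(panel = default_panel_frequencies(),
                         freq_mt = 1e-4,
                         penetrance_method = "additive",
                         penetrance = NULL,
                         population_size = 66e6) {
  carrier_nuc <- predicted_penetrance(panel, penetrance_method)
  pen <- penetrance %||% carrier_nuc
  prev <- predicted_prevalence(freq_mt, pen)
  tibble(
    freq_mt = freq_mt,
    carrier_freq_nuclear = carrier_nuc,
    co_occurrence = co_occurrence_probability(freq_mt, carrier_nuc),
    predicted_penetrance = pen,
    predicted_prevalence = prev,
    expected_cases = expected_cases(prev, population_size),
    population_size = population_size,
    prevalence_one_in = format_one_in(prev)
  )
}
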