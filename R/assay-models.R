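#' mtDNA copy number from qPCR threshold cycles
#'
#' Relative mtDNA copies per diploid cell from a multiplex qPCR of a nuclear
#' reference amplicon (B2M-like) and a mitochondrial target (MT-ND1-like):
#' `delta_ct = ct_nuclear - ct_mt` and `copy_number = 2 * 2^delta_ct`. The
#' leading 2 accounts for the two nuclear reference copies per diploid cell;
#' each Ct cycle is a two-fold abundance difference.
#'
#' @param samples Tibble with numeric columns `ct_nuclear` and `ct_mt`
#'   (threshold cycles); other columns pass through.
#' @return The input with `delta_ct` and `copy_number` columns added.
#' @details Missing Ct values are an error. Ct values outside the plausible
#'   cycler range (0, 45) trigger a warning but are still computed.
#' @examples
#' mtdna_copy_number(tibble::tibble(ct_nuclear = c(25, 19), ct_mt = c(20, 20)))
#' @export
mtdna_copy_number <- function(samples) {
  samples <- as_tibble(samples)
  stopifnot(all(c("ct_nuclear", "ct_mt") %in% names(samples)))
  if (anyNA(samples$ct_nuclear) || anyNA(samples$ct_mt)) {
    abort("Missing Ct value(s); both cycles are required per sample.")
  }
  cts <- c(samples$ct_nuclear, samples$ct_mt)
  if (any(cts <= 0 | cts >= 45)) {
    warn("Ct value(s) outside the plausible cycler range (0, 45).")
  }
  mutate(samples,
         delta_ct = .data$ct_nuclear - .data$ct_mt,
         copy_number = 2 * 2^.data$delta_ct)
}

#' Per-group copy-number summary and fold changes
#'
#' Averages replicates at the delta-Ct level before exponentiation (default),
#' then reports per-group mean and SD of copy number and all pairwise fold
#' changes between group means. Averaging at the Ct/delta-Ct level is the
#' geometric-mean convention for exponential qPCR data; the arithmetic
#' alternative (average per-replicate copy numbers) is available by flag and
#' the choice is recorded in the output attributes.
#'
#' @param samples Tibble with `ct_nuclear`, `ct_mt`, a grouping column and
#'   optionally `sample_id` (replicates of one sample share a `sample_id`).
#' @param group Name of the grouping column (default `"group"`).
#' @param average `"delta_ct"` (default) or `"copy_number"` replicate
#'   averaging.
#' @return List with `summary` (group, n, mean_copy_number, sd_copy_number)
#'   and `fold_changes` (group_a, group_b, fold_change); the averaging choice
#'   is stored in `attr(, "averaging")` of both tibbles.
#' @export
summarize_copy_number <- function(samples, group = "group",
                                  average = c("delta_ct", "copy_number")) {
  average <- match.arg(average)
  samples <- as_tibble(samples)
  stopifnot(group %in% names(samples))
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- paste0("s", seq_len(nrow(samples)))
  }

  per_sample <- samples |>
    mtdna_copy_number() |>
    group_by(group = .data[[group]], sample_id = .data$sample_id) |>
    summarise(delta_ct = mean(.data$delta_ct),
              copy_mean = mean(.data$copy_number),
              .groups = "drop") |>
    mutate(copy_number = if (average == "delta_ct") 2 * 2^.data$delta_ct
           else .data$copy_mean)

  summary <- per_sample |>
    group_by(.data$group) |>
    summarise(n = n(),
              mean_copy_number = mean(.data$copy_number),
              sd_copy_number = sd(.data$copy_number),
              .groups = "drop")

  if (any(summary$mean_copy_number == 0)) {
    abort("Zero mean copy number in a group; fold changes undefined.")
  }
  pairs <- tidyr::expand_grid(group_a = summary$group, group_b = summary$group) |>
    filter(.data$group_a != .data$group_b) |>
    left_join(select(summary, group_a = "group", ma = "mean_copy_number"),
              by = "group_a") |>
    left_join(select(summary, group_b = "group", mb = "mean_copy_number"),
              by = "group_b") |>
    mutate(fold_change = .data$ma / .data$mb) |>
    select("group_a", "group_b", "fold_change")

  attr(summary, "averaging") <- average
  attr(pairs, "averaging") <- average
  list(summary = summary, fold_changes = pairs)
}

#' Distribution-based regulation thresholds for proteome log2 ratios
#'
#' Computes the mean and standard deviation of all quantified proteins' log2
#' abundance ratios and sets the regulated cutoffs at mean +/- 2 SD, the
#' normal-distribution convention under which ~95% of unregulated proteins
#' fall inside the band. The sample SD (n-1 denominator) is used; a robust
#' variant (median and 1.4826 x MAD) is available.
#'
#' @param log2_ratios Numeric vector of per-protein log2 ratios (>= 3 values),
#'   or a tibble with a `log2_ratio` column.
#' @param robust Use median/MAD location and scale instead of mean/SD.
#' @return One-row tibble: `mean_log2`, `sd_log2`, `lower`, `upper`.
#' @examples
#' # the published cutoffs back-calculate to mean -0.61, sd 0.795:
#' regulation_thresholds(c(-0.61 - 0.795, -0.61, -0.61 + 0.795))
#' @export
regulation_thresholds <- function(log2_ratios, robust = FALSE) {
  if (is.data.frame(log2_ratios)) {
    stopifnot("log2_ratio" %in% names(log2_ratios))
    log2_ratios <- log2_ratios$log2_ratio
  }
  if (length(log2_ratios) < 3) abort("Need at least 3 log2 ratios.")
  if (anyNA(log2_ratios)) abort("Missing log2 ratio(s).")
  m <- if (robust) stats::median(log2_ratios) else mean(log2_ratios)
  s <- if (robust) stats::mad(log2_ratios) else sd(log2_ratios)
  if (s == 0) warn("Zero spread in log2 ratios; degenerate thresholds returned.")
  tibble(mean_log2 = m, sd_log2 = s, lower = m - 2 * s, upper = m + 2 * s)
}

#' Flag regulated proteins
#'
#' Partitions proteins into `down`, `up` and `unchanged` using the combined
#' gate: a protein is `down` iff its log2 ratio falls below the lower
#' threshold AND its ANOVA p-value is <= `alpha` AND it was quantified with
#' unique peptides in all replicates; `up` is symmetric above the upper
#' threshold; everything else is `unchanged`. The partition is exhaustive and
#' disjoint by construction.
#'
#' @param proteins Tibble with columns `protein_id`, `log2_ratio`, `anova_p`,
#'   and logical `unique_peptides`, `quantified_in_all`.
#' @param thresholds One-row tibble from [regulation_thresholds()] (columns
#'   `lower`, `upper`); defaults to thresholds computed from `proteins`
#'   itself.
#' @param alpha ANOVA significance gate (default 0.05).
#' @return The input with a `regulation` factor column
#'   (`down`/`unchanged`/`up`).
#' @export
flag_regulated <- function(proteins, thresholds = NULL, alpha = 0.05) {
  proteins <- as_tibble(proteins)
  need <- c("protein_id", "log2_ratio", "anova_p",
            "unique_peptides", "quantified_in_all")
  missing_cols <- setdiff(need, names(proteins))
  if (length(missing_cols) > 0) {
    abort(paste0("`proteins` missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_fraction(proteins$anova_p, "anova_p")
  thresholds <- thresholds %||% regulation_thresholds(proteins$log2_ratio)

  eligible <- proteins$anova_p <= alpha &
    proteins$unique_peptides & proteins$quantified_in_all
  mutate(proteins, regulation = factor(
    dplyr::case_when(
      eligible & .data$log2_ratio < thresholds$lower ~ "down",
      eligible & .data$log2_ratio > thresholds$upper ~ "up",
      TRUE ~ "unchanged"
    ),
    levels = c("down", "unchanged", "up")
  ))
}
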