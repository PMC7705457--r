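#' Residue composition of a protein sequence
#'
#' Counts target residues (by default glutamic acid E and glutamine Q) in a
#' one-letter amino-acid sequence and returns their fraction of the chain
#' length. Lowercase input is normalised; any character outside the 20
#' standard residues plus `U`, `O`, `X`, `*` is rejected.
#'
#' @param sequence Protein sequence string (one-letter codes).
#' @param targets Character vector of residues to count (default `c("E","Q")`).
#' @param gene Optional gene label carried into the output.
#' @return One-row tibble: `gene`, `length`, one `count_<residue>` column per
#'   target, `count_target` (their sum) and `fraction_target`.
#' @examples
#' residue_composition("EEQ")                 # fraction 1
#' residue_composition("ACDF")                # fraction 0
#' @export
residue_composition <- function(sequence, targets = c("E", "Q"), gene = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) abort("Empty protein sequence.")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "U", "O", "X", "*")
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown residue code(s): ", paste(bad, collapse = ", ")))
  }
  targets <- toupper(targets)
  counts <- vapply(targets, function(aa) sum(chars == aa), integer(1))
  out <- tibble(gene = gene, length = length(chars))
  for (aa in targets) out[[paste0("count_", aa)]] <- counts[[aa]]
  out$count_target <- sum(counts)
  out$fraction_target <- sum(counts) / length(chars)
  out
}

#' Path to the packaged synthetic mtDNA-proteome FASTA
#'
#' The 13 mtDNA-encoded protein sequences shipped with the package are a
#' synthetic stand-in generated by [simulate_mt_proteome()] (seed 1): real
#' per-gene chain lengths, with glutamate+glutamine content emulating the
#' enrichment of complex I (ND) subunits seen in the human mitochondrial
#' proteome. They are not the human reference sequences.
#'
#' @return Path to the FASTA file.
#' @export
mt_proteome_fasta <- function() {
  system.file("extdata", "mt_proteins_synthetic.fasta", package = "mtdigenic",
              mustWork = TRUE)
}

#' Residue-composition table for a protein FASTA
#'
#' Computes [residue_composition()] for every record of a protein FASTA
#' (typically the 13 mtDNA-encoded subunits), ordered deterministically by
#' gene name. The gene label is the first whitespace-delimited token of each
#' FASTA header.
#'
#' @param fasta Path to a protein FASTA file, or a named character vector of
#'   sequences. Defaults to the packaged synthetic mtDNA proteome.
#' @param targets Residues to count, as in [residue_composition()].
#' @param expected_n Expected record count; a differing count warns (the
#'   mtDNA-encoded proteome has 13 members). Use `NA` to disable.
#' @return Tibble with one row per sequence.
#' @export
composition_table <- function(fasta = mt_proteome_fasta(),
                              targets = c("E", "Q"),
                              expected_n = 13) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aas <- Biostrings::readAAStringSet(fasta)
    setNames(as.character(aas), names(aas))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    abort("`fasta` must be a FASTA path or a named character vector of sequences.")
  }
  genes <- stringr::word(names(seqs), 1)
  if (anyDuplicated(genes)) abort("Duplicate gene names in FASTA.")
  if (!is.na(expected_n) && length(seqs) != expected_n) {
    warn(sprintf("Expected %d protein records, found %d.", expected_n, length(seqs)))
  }
  purrr::map2(unname(seqs), genes,
              ~ residue_composition(.x, targets = targets, gene = .y)) |>
    bind_rows() |>
    arrange(.data$gene)
}

#' Correlate residue composition with expression change
#'
#' Joins a composition table to a per-gene expression-change table on gene
#' name and correlates the expression metric with the target-residue fraction
#' (or absolute count). With a positive-means-decrease metric, a positive
#' correlation indicates that proteins richer in the target residues lose
#' more expression.
#'
#' @param comp Composition table from [composition_table()].
#' @param expr Tibble with a `gene` column and the expression metric column.
#' @param metric Name of the expression metric column in `expr` (default
#'   `"log2fc"`; the sign convention — negative = decreased in patients — is
#'   the caller's, and is preserved).
#' @param predictor `"fraction"` (default) or `"count"` of target residues.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An `eq_correlation` object holding `r`, `p_value`, `n`, `method`
#'   and the joined `data`; see [tidy.eq_correlation()].
#' @details At least 3 genes must survive the inner join; join losses are
#'   reported. Zero variance on either side is an error naming the degenerate
#'   variable. The two-sided p-value comes from the t distribution with n-2
#'   degrees of freedom (via [stats::cor.test()]).
#' @export
correlate_composition_expression <- function(comp, expr, metric = "log2fc",
                                             predictor = c("fraction", "count"),
                                             method = c("pearson", "spearman")) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  stopifnot("gene" %in% names(comp), "gene" %in% names(expr))
  if (!metric %in% names(expr)) {
    abort(sprintf("Expression table has no column '%s'.", metric))
  }
  pred_col <- if (predictor == "fraction") "fraction_target" else "count_target"

  joined <- inner_join(comp, expr, by = "gene")
  lost <- setdiff(union(comp$gene, expr$gene), joined$gene)
  if (length(lost) > 0) {
    inform(paste0("Genes dropped by the join: ", paste(lost, collapse = ", ")))
  }
  if (nrow(joined) < 3) abort("Need at least 3 genes after the join.")

  x <- joined[[pred_col]]
  y <- joined[[metric]]
  if (sd(x) == 0) abort("Zero variance in the residue-composition predictor.")
  if (sd(y) == 0) abort("Zero variance in the expression metric.")

  ct <- suppressWarnings(cor.test(x, y, method = method))
  structure(
    list(
      r = unname(ct$estimate),
      p_value = ct$p.value,
      n = nrow(joined),
      method = method,
      predictor = pred_col,
      metric = metric,
      data = joined
    ),
    class = "eq_correlation"
  )
}

#' @export
print.eq_correlation <- function(x, ...) {
  cat(sprintf("<eq_correlation> %s r = %.5f, p = %.3g, n = %d (%s vs %s)\n",
              x$method, x$r, x$p_value, x$n, x$predictor, x$metric))
  invisible(x)
}

#' Tidy a composition-expression correlation
#'
#' @param x An `eq_correlation` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `p.value`, `n`, `method`.
#' @method tidy eq_correlation
#' @export
tidy.eq_correlation <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname tidy.eq_correlation
#' @method glance eq_correlation
#' @export
glance.eq_correlation <- function(x, ...) tidy.eq_correlation(x)
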