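#' Boxplot of per-individual allele burden by group
#'
#' One point per person, as in pedigree burden figures: jittered individual
#' allele counts over group boxplots.
#'
#' @param burden Tibble from [burden_table()].
#' @return A ggplot object.
#' @export
plot_burden <- function(burden) {
  stopifnot(all(c("group", "allele_count") %in% names(burden)))
  ggplot2::ggplot(burden, ggplot2::aes(x = .data$group, y = .data$allele_count,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.15, height = 0.05, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "damaging allele count (panel + mtDNA)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Scatter of expression change against residue composition
#'
#' @param x An `eq_correlation` object from
#'   [correlate_composition_expression()].
#' @param ... Unused.
#' @return A ggplot object with a least-squares line and the r annotation.
#' @method autoplot eq_correlation
#' @export
autoplot.eq_correlation <- function(x, ...) {
  d <- x$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x$predictor]],
                                  y = .data[[x$metric]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "Glu + Gln residue content",
      y = x$metric,
      subtitle = sprintf("%s r = %.3f, p = %.3g, n = %d",
                         x$method, x$r, x$p_value, x$n)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of proteome regulation calls
#'
#' log2 ratio against -log10 ANOVA p, coloured by regulation call, with the
#' mean +/- 2 SD cutoffs drawn as vertical lines.
#'
#' @param flagged Tibble from [flag_regulated()].
#' @param thresholds One-row tibble from [regulation_thresholds()]; if
#'   omitted, recomputed from `flagged`.
#' @return A ggplot object.
#' @export
plot_protein_ratios <- function(flagged, thresholds = NULL) {
  stopifnot(all(c("log2_ratio", "anova_p", "regulation") %in% names(flagged)))
  thresholds <- thresholds %||% regulation_thresholds(flagged$log2_ratio)
  ggplot2::ggplot(flagged, ggplot2::aes(x = .data$log2_ratio,
                                        y = -log10(.data$anova_p),
                                        colour = .data$regulation)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(thresholds$lower, thresholds$upper),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c(down = "firebrick", unchanged = "grey50", up = "forestgreen")
    ) +
    ggplot2::labs(x = "log2 abundance ratio", y = "-log10 ANOVA p") +
    ggplot2::theme_minimal()
}
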