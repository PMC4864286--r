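## ggplot2 views of the main result types.

#' Plot the resampling null against observed term divergences
#'
#' Interquartile segments (with median dots and 2nd/98th percentile
#' whiskers) of the null codon-usage correlation per set size; observed
#' catalog terms, when supplied, are overlaid and colored by their
#' divergence call.
#'
#' @param null A `cf_null` from [sample_null()].
#' @param divergence Optional tibble from [empirical_divergence()].
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null, divergence = NULL) {
  stopifnot(inherits(null, "cf_null"))
  qs <- tidy.cf_null(null)
  p <- ggplot2::ggplot(qs, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$p02, ymax = .data$p98),
      linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      linewidth = 1.1
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 1.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "gene set size",
      y = "Spearman correlation with exonic background"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(divergence)) {
    p <- p + ggplot2::geom_point(
      data = divergence,
      ggplot2::aes(x = .data$size, y = .data$rho, colour = .data$significant),
      size = 1, alpha = 0.8
    ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "red", `FALSE` = "black"),
        name = "divergent"
      )
  }
  p
}

#' Boxplots of match vs mismatch translational efficiency
#'
#' @param te TE tibble from [compute_te()].
#' @return A ggplot object faceted by gene-set menu entry and variant.
#' @export
plot_te_contrasts <- function(te) {
  ggplot2::ggplot(
    te,
    ggplot2::aes(x = .data$match, y = .data$value, fill = .data$match)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$variant),
      ggplot2::vars(.data$gene_set),
      scales = "free_y"
    ) +
    ggplot2::labs(x = NULL, y = "translational efficiency") +
    ggplot2::theme_minimal()
}

#' Factorial map of the per-term codon-usage PCA
#'
#' @param object A `cf_pca` from [pca_codon_usage()].
#' @param gc Optional named per-term GC fractions used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_pca <- function(object, gc = NULL, ...) {
  d <- object$scores
  if (!is.null(gc)) d$gc <- gc[d$term_id]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf(
        "PC2 (%.1f%%)",
        100 * (if (length(object$var_explained) > 1) {
          object$var_explained[2]
        } else {
          0
        })
      )
    ) +
    ggplot2::theme_minimal()
  if (is.null(gc)) {
    p + ggplot2::geom_point(size = 1)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$gc), size = 1) +
      ggplot2::scale_colour_viridis_c(name = "GC")
  }
}

#' PC1 against per-term GC content
#'
#' @param pca A `cf_pca`.
#' @param gc Named per-term GC fractions ([term_gc_content()]).
#' @return A ggplot object annotated with Spearman's rho.
#' @export
plot_pc1_gc <- function(pca, gc) {
  rho <- pc1_gc_correlation(pca, gc)
  d <- pca$scores
  d$gc <- gc[d$term_id]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$gc)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate(
      "text",
      x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
      label = sprintf("Spearman rho = %.2f", rho)
    ) +
    ggplot2::labs(y = "gene-set GC content") +
    ggplot2::theme_minimal()
}
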