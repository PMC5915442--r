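#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_histogram labs theme_minimal scale_color_manual
NULL

#' Manhattan plot of a selection scan
#'
#' @param object An `sds_tbl` from [sds_scan()].
#' @param layout Optional [genome_layout()] for true genomic spacing;
#'   otherwise variants are spaced by rank.
#' @param sig_threshold Significance line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot sds_tbl
autoplot.sds_tbl <- function(object, layout = NULL, sig_threshold = 5e-8,
                             ...) {
  df <- as_tibble(object)
  if (!is.null(layout)) {
    df$x <- to_global(layout, df$chrom, df$pos)
  } else {
    df <- arrange(df, .data$chrom, .data$pos)
    df$x <- seq_len(nrow(df))
  }
  ggplot(df, aes(x = .data$x, y = -log10(.data$p), color = .data$chrom)) +
    geom_point(size = 0.6, show.legend = FALSE) +
    geom_hline(yintercept = -log10(sig_threshold), linetype = "dashed",
               color = "grey40") +
    labs(x = "genomic position", y = expression(-log[10](italic(P))),
         title = "Singleton-density selection scan") +
    theme_minimal()
}

#' Null distribution of a rotation permutation
#'
#' @param object A [rotation_permutation()] result.
#' @param ... Unused.
#' @return A ggplot: histogram of null mean z with the observed mean marked.
#' @export
#' @method autoplot rotation_permutation
autoplot.rotation_permutation <- function(object, ...) {
  ggplot(tibble(m = object$null_means), aes(x = .data$m)) +
    geom_histogram(bins = 60, fill = "grey70") +
    geom_vline(xintercept = object$observed_mean, color = "red") +
    labs(
      x = "null mean z (rotated tracts)", y = "rotations",
      title = paste0(
        object$tract_set, ": two-sided P = ", signif(object$p_value, 3)
      )
    ) +
    theme_minimal()
}

#' Trait-enrichment overview plot
#'
#' Inflation of the selection chi-square statistic against enrichment
#' -log10(P) per trait, with the Bonferroni line.
#'
#' @param object An `enrich_tbl` from [trait_enrichment_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot enrich_tbl
autoplot.enrich_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$p), ]
  thr <- df$bonferroni_threshold[1]
  ggplot(df, aes(x = .data$inflation, y = -log10(.data$p),
                 color = .data$category)) +
    geom_point() +
    geom_hline(yintercept = -log10(thr), linetype = "dashed",
               color = "grey40") +
    labs(x = expression("inflation " * Sigma * z^2 / k),
         y = expression(-log[10](italic(P))),
         title = "Selection-signature enrichment in trait variant sets") +
    theme_minimal()
}

#' Heterogeneity of focal variants against the scored pool
#'
#' @param object A `het_tbl` from [daf_heterogeneity_test()].
#' @param pool Optional scored pool (`daf`, `h`) plotted as background.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot het_tbl
autoplot.het_tbl <- function(object, pool = NULL, ...) {
  p <- ggplot()
  if (!is.null(pool)) {
    p <- p + geom_point(
      data = as_tibble(pool), aes(x = .data$daf, y = .data$h),
      color = "steelblue", alpha = 0.25, size = 0.5
    )
  }
  p +
    geom_point(
      data = as_tibble(object), aes(x = .data$daf, y = .data$h),
      color = "red", size = 2
    ) +
    labs(x = "pooled derived allele frequency",
         y = expression(chi^2 / N ~ "heterogeneity index"),
         title = "DAF heterogeneity across subpopulations") +
    theme_minimal()
}
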