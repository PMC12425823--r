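#' Plot intratumor versus intertumor methylation distances
#'
#' Boxplots of pairwise ITMD values by scope; expects the row-bound output
#' of [compute_itmd()] runs with `scope = "intra"` and `"inter"`.
#'
#' @param pairs ITMD pair tibble (any rows with `scope` and `distance`).
#' @return A ggplot object.
#' @export
plot_itmd <- function(pairs) {
  assert_columns(pairs, c("scope", "distance"))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$scope, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "1 - Pearson r (methylation)",
                  title = "Methylation heterogeneity by scope") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a driver ranking
#'
#' Observed-over-expected promoter DHcR against the combined q-value for
#' each gene, highlighting genes below the recorded FDR.
#'
#' @param object A `"methsig"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methsig <- function(object, ...) {
  df <- object$results |>
    mutate(excess = .data$observed_dhcr - .data$expected_dhcr,
           significant = .data$q < object$fdr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$excess,
                                   y = -log10(pmax(.data$q, 1e-15)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "observed - expected DHcR", y = "-log10 q",
                  colour = paste0("q < ", object$fdr)) +
    ggplot2::theme_minimal()
}

#' Plot per-gene regulatory-selection ratios
#'
#' Log2 M_R/M_N ratios of calculable genes, colored by deviation class
#' when [test_mrmn_deviation()] has been applied.
#'
#' @param object An `"mrmn"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrmn <- function(object, ...) {
  df <- filter(tidy.mrmn(object), .data$calculable)
  df$class <- if ("class" %in% names(df)) df$class else "ns"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 (MR / MN)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot the dosage-compensation scan
#'
#' Methylation difference between amplified and non-amplified regions per
#' gene against its expression class; the 0.2 flag threshold is marked.
#'
#' @param calls Output of [dosage_compensation_scan()].
#' @return A ggplot object.
#' @export
plot_dosage_compensation <- function(calls) {
  assert_columns(calls, c("gene_id", "delta_median_meth", "expression_class"))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$expression_class,
                                      y = .data$delta_median_meth)) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = NULL,
                  y = "median promoter methylation (amplified - not)") +
    ggplot2::theme_minimal()
}
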