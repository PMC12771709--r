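#' Volcano plot of a differential-expression table
#'
#' @param table A `de_table` (see [poisson_de()]); flagged tables colour the
#'   significant genes.
#' @param lfc_min,alpha Guide lines (defaults 0.1 and 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(table, lfc_min = 0.1, alpha = 0.05) {
  df <- mutate(as_tibble(table),
               neglog10p = -log10(pmax(.data$p_nominal, 1e-300)),
               sig = !is.na(.data$significant) & .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC, .data$neglog10p,
                                   colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (disease vs control)",
                  y = "-log10 nominal p") +
    ggplot2::theme_minimal()
}

#' Composition bar plot
#'
#' @param object A `composition_test` (see [composition_test()]).
#' @param ... Unused.
#' @return A ggplot object: per-cluster condition proportions.
#' @export
autoplot.composition_test <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$table))
  names(df) <- c("condition", "cluster", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$n, fill = .data$condition)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(y = "proportion of cells", x = NULL,
                  subtitle = sprintf("X2 = %.2f, df = %d, p = %.2g",
                                     object$chi2, object$df, object$p)) +
    ggplot2::theme_minimal()
}

#' Silhouette scan plot
#'
#' @param object A `clustering_result` (see [cluster_cells()]).
#' @param ... Unused.
#' @return A ggplot object: mean silhouette versus candidate k.
#' @export
autoplot.clustering_result <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "candidate k", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Cross-study fold-change plot coloured by category
#'
#' @param table A `category_table` (see [categorize_degs()]).
#' @return A ggplot object: study A vs study B log2 fold changes.
#' @export
plot_categories <- function(table) {
  df <- filter(as_tibble(table), !is.na(.data$log2FC_A), !is.na(.data$log2FC_B))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC_A, .data$log2FC_B,
                                   colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "log2FC, study A", y = "log2FC, study B") +
    ggplot2::theme_minimal()
}

#' Top enriched pathways plot
#'
#' @param table An `enrichment_table` (see [ora()]).
#' @param n Number of sets shown (default 10).
#' @return A ggplot object: -log10 adjusted p per set.
#' @export
plot_enrichment <- function(table, n = 10) {
  df <- head(as_tibble(table), n)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(-log10(pmax(.data$p_adj, 1e-300)), .data$set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}
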