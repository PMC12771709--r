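#' Cross-study gene categorization
#'
#' Classifies every gene tested in both studies into one of five mutually
#' exclusive categories:
#'
#' * `shared` — significant in both studies with the same fold-change sign;
#' * `contrasting` — significant in both with opposite signs;
#' * `specific_A` / `specific_B` — significant in exactly one study while
#'   the other study's nominal p-value exceeds `ns_threshold` (not
#'   approaching significance);
#' * `unclassified` — everything else, including genes significant in one
#'   study whose nominal p in the other sits in the gap
#'   `[alpha, ns_threshold]`, genes with a zero fold change (sign
#'   undefined), and genes tested in one study only.
#'
#' Significance here means `p_adj < alpha & |log2FC| > lfc_min`, recomputed
#' from the table columns so both studies use identical thresholds.
#'
#' @param table_A,table_B `de_table`s (see [poisson_de()]) indexed by gene
#'   symbol.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Absolute log2FC threshold (default 0.1).
#' @param ns_threshold Nominal-p floor for calling the other study clearly
#'   non-significant (default 0.5).
#' @return A `category_table` tibble: `gene`, `category`, per-study `log2FC`,
#'   `p_adj`, `p_nominal`, and a `developmental` flag (all `FALSE` until
#'   [flag_developmental()]).
#' @export
categorize_degs <- function(table_A, table_B, alpha = 0.05, lfc_min = 0.1,
                            ns_threshold = 0.5) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (ns_threshold < 0 || ns_threshold > 1) abort("`ns_threshold` must be in [0, 1].")
  need <- c("gene", "log2FC", "p_nominal", "p_adj")
  for (nm in need) {
    if (!nm %in% names(table_A) || !nm %in% names(table_B))
      abort(sprintf("Both tables must carry `%s`.", nm))
  }
  common <- intersect(table_A$gene, table_B$gene)
  if (length(common) == 0) abort("No gene was tested in both studies.")
  only <- length(union(table_A$gene, table_B$gene)) - length(common)
  if (only > 0)
    inform(sprintf("categorize_degs: %d gene(s) tested in one study only -> unclassified.", only))

  a <- rename(select(as_tibble(table_A), dplyr::all_of(need)),
              log2FC_A = "log2FC", p_nominal_A = "p_nominal", p_adj_A = "p_adj")
  b <- rename(select(as_tibble(table_B), dplyr::all_of(need)),
              log2FC_B = "log2FC", p_nominal_B = "p_nominal", p_adj_B = "p_adj")
  tab <- dplyr::full_join(a, b, by = "gene")

  sig_A <- !is.na(tab$p_adj_A) & tab$p_adj_A < alpha & abs(tab$log2FC_A) > lfc_min
  sig_B <- !is.na(tab$p_adj_B) & tab$p_adj_B < alpha & abs(tab$log2FC_B) > lfc_min
  sgn_A <- sign(tab$log2FC_A); sgn_B <- sign(tab$log2FC_B)
  ns_A <- !is.na(tab$p_nominal_A) & tab$p_nominal_A > ns_threshold
  ns_B <- !is.na(tab$p_nominal_B) & tab$p_nominal_B > ns_threshold

  category <- dplyr::case_when(
    sig_A & sig_B & sgn_A != 0 & sgn_A == sgn_B ~ "shared",
    sig_A & sig_B & sgn_A != 0 & sgn_B != 0 & sgn_A == -sgn_B ~ "contrasting",
    sig_A & !sig_B & ns_B ~ "specific_A",
    sig_B & !sig_A & ns_A ~ "specific_B",
    .default = "unclassified"
  )
  out <- mutate(tab, category = category, developmental = FALSE,
                .after = "gene")
  class(out) <- c("category_table", class(out))
  attr(out, "thresholds") <- c(alpha = alpha, lfc_min = lfc_min,
                               ns_threshold = ns_threshold)
  out
}

#' Flag developmental genes in a category table
#'
#' Marks genes appearing in a developmental gene list (exact uppercase symbol
#' match); categories are unchanged. In rendered reports flagged genes carry
#' an asterisk, signalling that cross-study differences for these genes may
#' reflect differences in developmental stage rather than disease.
#'
#' @param table A `category_table` from [categorize_degs()].
#' @param dev_genes Non-empty character vector of developmental gene symbols.
#' @return The table with the `developmental` column set.
#' @export
flag_developmental <- function(table, dev_genes) {
  if (length(dev_genes) == 0) abort("`dev_genes` must be non-empty.")
  table$developmental <- table$gene %in% dev_genes
  table
}

#' Render a category table for human reading
#'
#' @param table A `category_table`.
#' @return A tibble where flagged developmental genes carry a `*` suffix in
#'   `gene_label` (the machine `developmental` column is kept).
#' @export
render_category_table <- function(table) {
  mutate(as_tibble(table),
         gene_label = paste0(.data$gene, ifelse(.data$developmental, "*", "")),
         .after = "gene")
}
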