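#' Coverage of a query gene set by a reference
#'
#' `Coverage (%) = 100 * |query intersect reference| / |query|`, the
#' cross-system overlap metric used to ask what fraction of the organoid
#' differentially expressed genes reappear in a post-mortem reference.
#' `coverage_pct` holds full precision; `coverage_pct_printed` rounds
#' half-up to 1 decimal place, the convention of printed reports.
#'
#' @param query Non-empty character vector (e.g. organoid DEGs).
#' @param reference Character vector (e.g. post-mortem DEGs).
#' @return A one-row tibble: `n_query`, `n_reference`, `n_intersect`,
#'   `coverage_pct`, `coverage_pct_printed`, `genes` (list-column).
#' @export
overlap_coverage <- function(query, reference) {
  query <- unique(query); reference <- unique(reference)
  if (length(query) == 0) abort("`query` must be non-empty.")
  hit <- intersect(query, reference)
  pct <- 100 * length(hit) / length(query)
  tibble(
    n_query = length(query), n_reference = length(reference),
    n_intersect = length(hit),
    coverage_pct = pct,
    coverage_pct_printed = round_half_up(pct, 1),
    genes = list(sort(hit))
  )
}

#' Directional concordance of intersecting genes
#'
#' Splits the genes present in both tables by log2 fold-change sign
#' agreement. Genes with a zero fold change in either table have no defined
#' direction and are excluded (logged).
#'
#' @param query_table,reference_table Data frames with `gene` and `log2FC`.
#' @return A one-row tibble: `n_intersect`, `n_concordant`, `n_discordant`,
#'   `n_excluded`, `concordant_pct`, `concordant` / `discordant`
#'   list-columns.
#' @export
directional_concordance <- function(query_table, reference_table) {
  for (tab in list(query_table, reference_table)) {
    if (!all(c("gene", "log2FC") %in% names(tab)))
      abort("Both tables must carry `gene` and `log2FC`.")
  }
  m <- inner_join(select(as_tibble(query_table), "gene", q = "log2FC"),
                  select(as_tibble(reference_table), "gene", r = "log2FC"),
                  by = "gene")
  zero <- sign(m$q) == 0 | sign(m$r) == 0
  if (any(zero))
    inform(sprintf("directional_concordance: %d gene(s) with zero log2FC excluded.",
                   sum(zero)))
  m2 <- m[!zero, , drop = FALSE]
  conc <- sign(m2$q) == sign(m2$r)
  tibble(
    n_intersect = nrow(m), n_concordant = sum(conc),
    n_discordant = sum(!conc), n_excluded = sum(zero),
    concordant_pct = if (nrow(m2)) 100 * sum(conc) / nrow(m2) else NA_real_,
    concordant = list(sort(m2$gene[conc])),
    discordant = list(sort(m2$gene[!conc]))
  )
}

#' One-sided Fisher overlap test
#'
#' Tests enrichment of the query/reference overlap within the universe: the
#' upper-tail hypergeometric p-value of the 2x2 table implied by
#' `(universe, query, reference, intersection)`, i.e. Fisher's exact test
#' with `alternative = "greater"`. Symmetric in query and reference.
#'
#' @param query,reference Gene sets, both subsets of `universe`.
#' @param universe Background gene universe.
#' @return The p-value.
#' @export
overlap_fisher <- function(query, reference, universe) {
  query <- unique(query); reference <- unique(reference)
  universe <- unique(universe)
  for (nm in c("query", "reference")) {
    off <- setdiff(get(nm), universe)
    if (length(off))
      abort(paste0("`", nm, "` genes outside the universe: ",
                   paste(head(off, 10), collapse = ", "),
                   if (length(off) > 10) ", ..." else ""))
  }
  x <- length(intersect(query, reference))
  tab <- matrix(c(x, length(reference) - x,
                  length(query) - x,
                  length(universe) - length(query) - length(reference) + x),
                nrow = 2)
  fisher.test(tab, alternative = "greater")$p.value
}

#' Full overlap report against a reference table
#'
#' Combines [overlap_coverage()], [directional_concordance()] and
#' [overlap_fisher()] for a query differential-expression table against a
#' reference table within a universe.
#'
#' @param query_table Data frame with `gene`, `log2FC` and (if `significant`
#'   present) the flags selecting the query DEGs; otherwise all genes are
#'   the query.
#' @param reference_table Data frame with `gene`, `log2FC`.
#' @param universe Background universe (default: genes of the query table).
#' @return A one-row tibble combining the three statistics
#'   (`fisher_p`, `universe_size`, coverage and concordance columns).
#' @export
overlap_report <- function(query_table, reference_table, universe = NULL) {
  q <- as_tibble(query_table)
  if ("significant" %in% names(q)) q <- q[!is.na(q$significant) & q$significant, ]
  universe <- unique(universe %||% query_table$gene)
  cov <- overlap_coverage(q$gene, reference_table$gene)
  conc <- directional_concordance(q, reference_table)
  fp <- overlap_fisher(intersect(q$gene, universe),
                       intersect(unique(reference_table$gene), universe),
                       universe)
  bind_cols(cov, select(conc, -"n_intersect"),
            tibble(fisher_p = fp, universe_size = length(universe)))
}

#' GWAS overlap analysis
#'
#' Intersects the significant DEGs of a differential-expression table with a
#' GWAS gene list by exact uppercase symbol matching. The background
#' universe is the intersection of the genes tested for differential
#' expression with the GWAS study's gene universe, and both query and
#' reference are restricted to it before coverage and the one-sided Fisher
#' test.
#'
#' @param de_table A flagged `de_table` (see [adjust_and_flag()]).
#' @param gwas_genes Character vector of genome-wide significant genes.
#' @param universe Background universe; default is the tested genes
#'   (i.e. the GWAS list is assumed genome-wide).
#' @return A one-row tibble: coverage columns plus `fisher_p` and
#'   `universe_size`; zero-row query yields a warning and an empty report.
#' @export
gwas_overlap <- function(de_table, gwas_genes, universe = NULL) {
  if (!"significant" %in% names(de_table) || all(is.na(de_table$significant)))
    abort("`de_table` must be flagged; run adjust_and_flag() first.")
  universe <- unique(universe %||% de_table$gene)
  universe <- intersect(universe, de_table$gene)
  if (length(universe) == 0) abort("Universe does not intersect the tested genes.")
  query <- intersect(de_table$gene[de_table$significant], universe)
  reference <- intersect(toupper(gwas_genes), universe)
  if (length(query) == 0) {
    warn("No significant DEG lies in the universe; empty GWAS overlap.")
    return(tibble(n_query = 0L, n_reference = length(reference),
                  n_intersect = 0L, coverage_pct = NA_real_,
                  coverage_pct_printed = NA_real_, genes = list(character(0)),
                  fisher_p = NA_real_, universe_size = length(universe)))
  }
  cov <- overlap_coverage(query, reference)
  bind_cols(cov, tibble(fisher_p = overlap_fisher(query, reference, universe),
                        universe_size = length(universe)))
}
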