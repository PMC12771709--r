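#' Detection-fraction expression filter
#'
#' Returns the genes detected (raw count > 0) in strictly more than
#' `min_fraction` of cells — the "more than 10% of cells" rule used before
#' ligand-activity analysis, so a gene at exactly the threshold is excluded.
#'
#' @param data A [cell_dataset()].
#' @param min_fraction Detection-fraction threshold in `[0, 1)` (default 0.1).
#' @return Character vector of gene symbols.
#' @export
expression_filter <- function(data, min_fraction = 0.1) {
  stopifnot(is(data, "cell_dataset"))
  if (min_fraction < 0 || min_fraction >= 1)
    abort("`min_fraction` must be in [0, 1).")
  frac <- Matrix::rowSums(data$counts > 0) / n_cells(data)
  rownames(data$counts)[frac > min_fraction]
}

#' Read a ligand-activity table
#'
#' TSV schema: `ligand`, `activity`, `targets` (comma-separated gene
#' symbols), the output format of upstream ligand-activity prediction.
#'
#' @param path File path.
#' @return A tibble with a `targets` list-column.
#' @export
read_ligand_activity <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("ligand", "activity", "targets") %in% names(tab)))
    abort("Ligand table needs columns ligand, activity, targets.")
  tab$targets <- strsplit(as.character(tab$targets), ",", fixed = TRUE)
  tab$targets <- lapply(tab$targets, trimws)
  as_tibble(tab)
}

#' Read a ligand-receptor pair table
#'
#' TSV schema: `ligand`, `receptor`, `pathway`, `significant` (0/1 or
#' logical), the output format of upstream communication-network inference.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_lr_pairs <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("ligand", "receptor", "pathway", "significant") %in% names(tab)))
    abort("LR table needs columns ligand, receptor, pathway, significant.")
  tab$significant <- as.logical(as.integer(as.logical(tab$significant)))
  as_tibble(tab)
}

#' Intersect top-ligand targets with significant ligand-receptor genes
#'
#' Builds the gene set feeding communication-level enrichment: `T`, the
#' union of target genes of the `top_n_ligands` highest-activity ligands,
#' intersected with `L`, the genes of the significant ligand-receptor pairs.
#' In the default `"strict"` mode `L` is the ligand and receptor symbols
#' themselves; in `"augmented"` mode `L` additionally includes the targets
#' of significant-pair ligands that appear in the activity table, since the
#' upstream description ("target genes ... and the significantly altered
#' ligand-receptor pairs") is ambiguous between the two readings.
#'
#' @param ligands Ligand-activity tibble (see [read_ligand_activity()]).
#' @param pairs LR-pair tibble (see [read_lr_pairs()]).
#' @param top_n_ligands Ligands kept by activity score (default 20).
#' @param mode `"strict"` (default) or `"augmented"`.
#' @return Character vector of genes; attribute `mode` records the variant.
#' @export
intersect_targets <- function(ligands, pairs, top_n_ligands = 20,
                              mode = c("strict", "augmented")) {
  mode <- match.arg(mode)
  sig <- pairs[pairs$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    warn("No significant ligand-receptor pairs; intersection is empty.")
    return(structure(character(0), mode = mode))
  }
  top <- head(arrange(ligands, dplyr::desc(.data$activity)), top_n_ligands)
  tset <- unique(unlist(top$targets))
  lset <- unique(c(sig$ligand, sig$receptor))
  if (mode == "augmented") {
    lig_rows <- ligands[ligands$ligand %in% sig$ligand, , drop = FALSE]
    lset <- unique(c(lset, unlist(lig_rows$targets)))
  }
  structure(sort(intersect(tset, lset)), mode = mode)
}

#' Pathways significantly enriched in both studies
#'
#' Intersects the set names significant (`p_adj < alpha`) in both
#' enrichment tables and ranks the intersection by the worse of the two
#' adjusted p-values (`max(p_adj_A, p_adj_B)` ascending, ties by set name);
#' the head of that ranking is the conventional "top shared pathways" list.
#' Symmetric in A and B.
#'
#' @param enrich_A,enrich_B `enrichment_table`s (BH-adjusted; see [ora()]).
#' @param alpha Significance threshold (default 0.05).
#' @param top_n Rows to return (default 5); `Inf` for all.
#' @return A tibble: `set`, `p_adj_A`, `p_adj_B`, `n_genes_A`, `n_genes_B`,
#'   `rank_key`.
#' @export
shared_significant_pathways <- function(enrich_A, enrich_B, alpha = 0.05,
                                        top_n = 5) {
  sa <- enrich_A[enrich_A$p_adj < alpha, , drop = FALSE]
  sb <- enrich_B[enrich_B$p_adj < alpha, , drop = FALSE]
  shared <- intersect(sa$set, sb$set)
  if (length(shared) == 0) {
    inform("No pathway is significant in both studies.")
    return(tibble(set = character(0), p_adj_A = numeric(0), p_adj_B = numeric(0),
                  n_genes_A = integer(0), n_genes_B = integer(0),
                  rank_key = numeric(0)))
  }
  a <- sa[match(shared, sa$set), ]
  b <- sb[match(shared, sb$set), ]
  out <- tibble(
    set = shared,
    p_adj_A = a$p_adj, p_adj_B = b$p_adj,
    n_genes_A = a$overlap, n_genes_B = b$overlap,
    rank_key = pmax(a$p_adj, b$p_adj)
  )
  out <- arrange(out, .data$rank_key, .data$set)
  head(out, top_n)
}
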