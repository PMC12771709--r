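#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes. The
#' reader returns a named list of uppercase gene vectors with the
#' descriptions as an attribute.
#'
#' @param path File path.
#' @return For `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) abort("GMT lines must have at least 3 tab-separated fields.")
  sets <- lapply(parts, function(p) toupper(unique(p[-(1:2)])))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- setNames(vapply(parts, `[`, character(1), 2),
                                        names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    abort("`sets` must be a named list.")
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query genes within the
#' universe: `p = P(X >= x)` for `X ~ Hypergeometric(N = |universe|,
#' K = |set within universe|, n = |query|)` with `x` the observed overlap.
#' Sets overlapping fewer than `min_mapped` query genes are dropped before
#' Benjamini-Hochberg adjustment across the collection. Rows are ordered by
#' adjusted then nominal p, ties broken by set name.
#'
#' @param query Character vector of query genes (must lie inside `universe`).
#' @param universe Background gene universe (conventionally the genes tested
#'   for differential expression).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param min_mapped Minimum query genes mapped to a set (default 3).
#' @param alpha Significance threshold recorded on the result (default 0.05).
#' @param lfc Optional named log2FC vector over genes; adds a
#'   `mean_direction` column (`up` / `down` / `mixed`) with `mixed` meaning
#'   the mean |log2FC| of the overlapping genes is below 0.1.
#'
#' @return An `enrichment_table` tibble: `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `p_adj`, `significant`, `genes`
#'   (list-column), and `mean_direction` when `lfc` is given.
#' @export
ora <- function(query, universe, collection, min_mapped = 3, alpha = 0.05,
                lfc = NULL) {
  query <- unique(query); universe <- unique(universe)
  missing <- setdiff(query, universe)
  if (length(missing))
    abort(paste0("Query genes outside the universe: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else ""))
  N <- length(universe); n <- length(query)
  rows <- purrr::imap(collection, function(genes, nm) {
    K_genes <- intersect(genes, universe)
    hit <- intersect(query, K_genes)
    tibble(set = nm, overlap = length(hit), set_size = length(K_genes),
           query_size = n, universe_size = N,
           p = phyper(length(hit) - 1, length(K_genes), N - length(K_genes),
                      n, lower.tail = FALSE),
           genes = list(sort(hit)))
  })
  tab <- bind_rows(rows)
  tab <- tab[tab$overlap >= min_mapped, , drop = FALSE]
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p_adj < alpha
  if (!is.null(lfc)) {
    mfc <- vapply(tab$genes, function(g) {
      v <- lfc[intersect(g, names(lfc))]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    tab$mean_direction <- dplyr::case_when(
      is.na(mfc) | abs(mfc) < 0.1 ~ "mixed",
      mfc > 0 ~ "up",
      .default = "down"
    )
  }
  tab <- arrange(tab, .data$p_adj, .data$p, .data$set)
  tab <- select(tab, "set", "overlap", "set_size", "query_size",
                "universe_size", "p", "p_adj", "significant",
                dplyr::any_of("mean_direction"), "genes")
  class(tab) <- c("enrichment_table", class(tab))
  attr(tab, "alpha") <- alpha
  attr(tab, "min_mapped") <- min_mapped
  tab
}

#' Top pathways of an enrichment table
#'
#' First `n` rows by `(p_adj, p, set name)`; deterministic under ties.
#'
#' @param table An `enrichment_table` (see [ora()]).
#' @param n Number of rows (default 100, the conventional per-database cut).
#' @return The head of the re-sorted table.
#' @export
top_pathways <- function(table, n = 100) {
  table <- arrange(table, .data$p_adj, .data$p, .data$set)
  head(table, n)
}
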