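#' Mean silhouette width of a clustering
#'
#' For each point `i`, `s(i) = (b - a) / max(a, b)` where `a` is the mean
#' Euclidean distance to the other members of its cluster and `b` the
#' smallest mean distance to the points of any other cluster. Singleton
#' clusters contribute `s = 0` for their point. The returned value is the
#' mean of `s(i)` over all points.
#'
#' @param embedding Numeric matrix, one row per point (e.g. a PCA embedding).
#' @param labels Cluster labels, one per row.
#' @return Mean silhouette width in `[-1, 1]`.
#' @seealso [silhouette_scores()] for the per-point values.
#' @export
silhouette_width <- function(embedding, labels) {
  mean(silhouette_scores(embedding, labels)$silhouette)
}

#' @rdname silhouette_width
#' @return For `silhouette_scores()`: a tibble with `point`, `cluster`,
#'   `silhouette`.
#' @export
silhouette_scores <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  if (nrow(embedding) != length(labels))
    abort("`labels` must have one entry per row of `embedding`.")
  if (length(unique(labels)) < 2)
    abort("Silhouette analysis needs at least 2 clusters.")
  d <- as.matrix(dist(embedding))
  sizes <- table(labels)
  s <- vapply(seq_along(labels), function(i) {
    li <- labels[i]
    if (sizes[[li]] == 1) return(0)
    a <- sum(d[i, labels == li]) / (sizes[[li]] - 1)
    b <- min(vapply(setdiff(names(sizes), li),
                    function(lj) mean(d[i, labels == lj]), numeric(1)))
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  tibble(point = seq_along(labels), cluster = labels, silhouette = s)
}

#' PCA + k-means clustering scan with silhouette selection
#'
#' Projects the normalized layer onto its top principal components, runs
#' k-means for each candidate number of clusters, scores each partition by
#' mean silhouette width on the PCA embedding, and keeps the candidate with
#' the largest mean silhouette (ties broken toward the smaller k).
#'
#' @param data A [cell_dataset()] with a normalized layer (see
#'   [normalize_counts()]).
#' @param n_pcs Number of principal components (default 20).
#' @param k_candidates Candidate cluster numbers, each in `[2, n_cells - 1]`.
#' @param seed Integer seed for the k-means starts.
#'
#' @return A `clustering_result`: per-cell labels (`cluster` column also
#'   written into `data$cells` is left to the caller), the silhouette scan,
#'   the chosen k and the embedding. Supports [tidy()] / [glance()].
#' @export
cluster_cells <- function(data, n_pcs = 20, k_candidates = 2:6, seed = 1L) {
  stopifnot(is(data, "cell_dataset"))
  if (is.null(data$normalized))
    abort("No normalized layer; run normalize_counts() first.")
  if (n_pcs >= min(n_cells(data), n_genes(data)))
    abort("`n_pcs` must be below min(n_cells, n_genes).")
  if (any(k_candidates < 2) || any(k_candidates > n_cells(data) - 1))
    abort("Each k candidate must be in [2, n_cells - 1].")
  x <- t(as.matrix(data$normalized))
  keep <- matrixStats_colVars(x) > 0
  pca <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                rank. = n_pcs)
  emb <- pca$x
  scan <- purrr::map_dfr(sort(unique(k_candidates)), function(k) {
    km <- with_seed(seed + k, kmeans(emb, centers = k, nstart = 10, iter.max = 50))
    tibble(k = k, mean_silhouette = silhouette_width(emb, km$cluster),
           labels = list(as.character(km$cluster)))
  })
  best <- scan[order(-scan$mean_silhouette, scan$k), ][1, ]
  structure(
    list(labels = setNames(best$labels[[1]], colnames(data$counts)),
         chosen_k = best$k,
         scan = select(scan, "k", "mean_silhouette"),
         embedding = emb),
    class = "clustering_result"
  )
}

# column variances without a matrixStats dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d (mean silhouette %.3f) over candidates {%s}\n",
              x$chosen_k,
              x$scan$mean_silhouette[x$scan$k == x$chosen_k],
              paste(x$scan$k, collapse = ", ")))
  invisible(x)
}

#' Tidy a clustering result
#' @param x A `clustering_result`.
#' @param ... Unused.
#' @return One row per cell: `barcode`, `cluster`.
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble(barcode = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.clustering_result
#' @return For `glance()`: the silhouette scan with a `chosen` flag.
#' @export
glance.clustering_result <- function(x, ...) {
  mutate(x$scan, chosen = .data$k == x$chosen_k)
}

#' Marker-based cluster annotation
#'
#' Scores each cluster against each candidate cell type using
#' specificity-weighted marker z-scores: for cell `c`,
#' `score(type) = sum over positive markers of w_g z_g(c) - sum over negative
#' markers of w_g z_g(c)`, where `z_g` is the gene-wise z-score of normalized
#' expression across cells (clipped to \[-10, 10\]) and `w_g = 1 / (number of
#' cell types listing g)`. A cluster is assigned the type with the highest
#' mean score over its member cells; exact ties give `"Unknown"`.
#'
#' @param data A [cell_dataset()] with a normalized layer.
#' @param labels Cluster label per cell.
#' @param markers Named list: cell type -> character vector of positive
#'   markers, or a list with `positive` / `negative` vectors.
#' @return A tibble: `cluster`, `cell_type`, `score`.
#' @export
annotate_clusters <- function(data, labels, markers) {
  stopifnot(is(data, "cell_dataset"))
  if (is.null(data$normalized))
    abort("No normalized layer; run normalize_counts() first.")
  labels <- as.character(labels)
  get_set <- function(m, which) {
    if (is.list(m) && !is.null(m[[which]])) m[[which]]
    else if (which == "positive" && is.character(m)) m
    else character(0)
  }
  all_used <- unique(unlist(lapply(markers, function(m)
    c(get_set(m, "positive"), get_set(m, "negative")))))
  present <- intersect(all_used, rownames(data$counts))
  if (length(present) == 0) abort("No marker gene is present in the dataset.")
  # specificity weights: shared markers count less
  listing <- table(unlist(lapply(markers, function(m)
    unique(c(get_set(m, "positive"), get_set(m, "negative"))))))
  w <- 1 / as.numeric(listing[present])
  names(w) <- present

  x <- as.matrix(data$normalized[present, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[] <- pmin(pmax(z, -10), 10)

  cell_scores <- vapply(names(markers), function(tp) {
    pos <- intersect(get_set(markers[[tp]], "positive"), present)
    neg <- intersect(get_set(markers[[tp]], "negative"), present)
    sc <- rep(0, ncol(x))
    if (length(pos)) sc <- sc + colSums(z[pos, , drop = FALSE] * w[pos])
    if (length(neg)) sc <- sc - colSums(z[neg, , drop = FALSE] * w[neg])
    sc
  }, numeric(ncol(x)))

  purrr::map_dfr(sort(unique(labels)), function(cl) {
    m <- colMeans(cell_scores[labels == cl, , drop = FALSE])
    top <- max(m)
    winner <- names(m)[m == top]
    tibble(cluster = cl,
           cell_type = if (length(winner) == 1) winner else "Unknown",
           score = top)
  })
}

#' Merge fine cell-type labels into broad categories
#'
#' Replaces labels per the mapping; labels absent from the map pass through
#' unchanged with a warning. Total cell counts are conserved.
#'
#' @param labels Character vector of fine labels.
#' @param merge_map Named character vector or two-column data frame
#'   (`fine`, `broad`).
#' @return Character vector of broad labels, same length as `labels`.
#' @export
merge_cell_types <- function(labels, merge_map) {
  if (is.data.frame(merge_map)) {
    merge_map <- setNames(as.character(merge_map[[2]]), as.character(merge_map[[1]]))
  }
  labels <- as.character(labels)
  unmapped <- setdiff(unique(labels), names(merge_map))
  if (length(unmapped))
    warn(paste0("Labels passed through unmapped: ", paste(unmapped, collapse = ", ")))
  out <- merge_map[labels]
  out[is.na(out)] <- labels[is.na(out)]
  unname(out)
}
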