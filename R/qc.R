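#' Filter cells on detected genes and mitochondrial percentage
#'
#' Retains cells with `min_genes <= detected genes <= max_genes` and
#' mitochondrial percentage strictly below `max_mito_pct` (the conventional
#' "below 5%" rule, so a cell at exactly the threshold is removed). Detected
#' genes are genes with raw count > 0; the mitochondrial percentage is
#' computed on raw counts. The gene set is unchanged.
#'
#' @param data A [cell_dataset()].
#' @param min_genes,max_genes Detected-gene bounds (defaults 200 and 8000).
#' @param max_mito_pct Mitochondrial percentage upper bound (default 5).
#' @param verbose Report cell counts before/after.
#'
#' @return The filtered [cell_dataset()], with a `qc_log` attribute recording
#'   counts before/after and the per-threshold removals.
#' @export
filter_cells <- function(data, min_genes = 200, max_genes = 8000,
                         max_mito_pct = 5.0, verbose = TRUE) {
  stopifnot(is(data, "cell_dataset"))
  if (min_genes >= max_genes) abort("`min_genes` must be below `max_genes`.")
  if (max_mito_pct < 0 || max_mito_pct > 100)
    abort("`max_mito_pct` must be a percentage in [0, 100].")
  qc <- per_cell_qc(data)
  low <- qc$n_detected < min_genes
  high <- qc$n_detected > max_genes
  mito <- qc$mito_pct >= max_mito_pct
  keep <- !(low | high | mito)
  if (!any(keep)) {
    binding <- c(sprintf("min_genes (%d cells below %d)", sum(low), min_genes),
                 sprintf("max_genes (%d cells above %d)", sum(high), max_genes),
                 sprintf("max_mito_pct (%d cells at/above %.1f%%)", sum(mito), max_mito_pct))
    abort(paste0("No cells survive filtering; binding thresholds: ",
                 paste(binding[c(sum(low), sum(high), sum(mito)) > 0], collapse = "; ")))
  }
  out <- subset_cells(data, keep)
  log <- tibble(
    n_before = nrow(qc), n_after = sum(keep),
    removed_low_genes = sum(low), removed_high_genes = sum(high),
    removed_mito = sum(mito)
  )
  if (verbose)
    inform(sprintf("filter_cells: %d -> %d cells (%d low-gene, %d high-gene, %d high-mito removed)",
                   log$n_before, log$n_after, log$removed_low_genes,
                   log$removed_high_genes, log$removed_mito))
  attr(out, "qc_log") <- log
  out
}

#' Library-size normalization with log1p transform
#'
#' Scales each cell's counts to a common total (`target_sum`) and stores
#' `log1p` of the scaled values as the `normalized` layer. Raw counts are
#' preserved; downstream differential expression uses raw counts with
#' library-size offsets and is unaffected by this layer.
#'
#' @param data A [cell_dataset()].
#' @param target_sum Per-cell total after scaling (default 10000).
#' @return The dataset with a `normalized` layer attached.
#' @export
normalize_counts <- function(data, target_sum = 1e4) {
  stopifnot(is(data, "cell_dataset"))
  totals <- Matrix::colSums(data$counts)
  if (any(totals == 0)) {
    abort(sprintf("%d cell(s) have zero total counts; filter before normalizing.",
                  sum(totals == 0)))
  }
  scaled <- data$counts %*% Matrix::Diagonal(x = target_sum / totals)
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(data$counts)
  data$normalized <- methods::as(norm, "CsparseMatrix")
  data
}

#' Condition-by-cluster composition test
#'
#' Cross-tabulates cells by condition and cluster (or cell type) and applies
#' the Pearson chi-squared test of homogeneity without continuity correction,
#' with `df = (rows - 1)(cols - 1)`. Per-cluster disease/control ratios and
#' per-condition percentages of the dataset total are reported alongside.
#'
#' @param data A [cell_dataset()], or a 2-row matrix/table
#'   (disease row first) to test a pre-tabulated composition directly.
#' @param condition_field,cluster_field Column names in `data$cells`.
#' @param disease_level Level of the condition column treated as disease for
#'   the ratio; defaults to the last level alphabetically (`"disease"` in
#'   synthetic data).
#'
#' @return A `composition_test` object; see [tidy.composition_test()] and
#'   [glance.composition_test()].
#' @export
composition_test <- function(data, condition_field = "condition",
                             cluster_field = "cell_type",
                             disease_level = NULL) {
  if (is(data, "cell_dataset")) {
    cells <- data$cells
    for (f in c(condition_field, cluster_field)) {
      if (!f %in% names(cells)) abort(sprintf("Column `%s` not found in cell annotations.", f))
      if (anyNA(cells[[f]])) abort(sprintf("Column `%s` has unlabelled cells.", f))
    }
    tab <- table(cells[[condition_field]], cells[[cluster_field]])
  } else {
    tab <- as.table(as.matrix(data))
    if (is.null(rownames(tab))) rownames(tab) <- c("disease", "control")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    abort("Need at least 2 conditions and 2 clusters.")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) abort("A cell of the table has expected count 0.")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (is.null(disease_level)) {
    cand <- intersect(c("disease", "PD", "AD", "treated"), rownames(tab))
    disease_level <- if (length(cand)) cand[1] else rownames(tab)[1]
  }
  other <- setdiff(rownames(tab), disease_level)[1]
  ratios <- as.numeric(tab[disease_level, ]) / as.numeric(tab[other, ])
  structure(
    list(table = tab, chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value,
         ratios = setNames(ratios, colnames(tab)),
         disease_level = disease_level, control_level = other),
    class = "composition_test"
  )
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("Composition chi-squared: X2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  cat(sprintf("%s / %s ratios: %s\n", x$disease_level, x$control_level,
              paste(sprintf("%s %.2f", names(x$ratios), x$ratios), collapse = ", ")))
  invisible(x)
}

#' Tidy a composition test
#'
#' @param x A `composition_test`.
#' @param ... Unused.
#' @return One row per cluster: counts by condition, disease/control ratio,
#'   and each condition's percentage of its dataset total.
#' @export
tidy.composition_test <- function(x, ...) {
  tab <- x$table
  tibble(
    cluster = colnames(tab),
    n_disease = as.integer(tab[x$disease_level, ]),
    n_control = as.integer(tab[x$control_level, ]),
    ratio = unname(x$ratios),
    pct_of_disease = 100 * as.numeric(tab[x$disease_level, ]) / sum(tab[x$disease_level, ]),
    pct_of_control = 100 * as.numeric(tab[x$control_level, ]) / sum(tab[x$control_level, ])
  )
}

#' @rdname tidy.composition_test
#' @return For `glance()`: a one-row tibble with `chi2`, `df`, `p.value`,
#'   `n_cells`.
#' @export
glance.composition_test <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p.value = x$p, n_cells = sum(x$table))
}
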