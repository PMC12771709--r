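# Small deterministic fixtures built in code.

# counts matrix with prescribed per-cell detected-gene counts and mito
# percentages; gene 1 is mitochondrial
qc_fixture <- function(detected, mito_pct, n_genes = max(detected) + 1) {
  stopifnot(length(detected) == length(mito_pct))
  n <- length(detected)
  m <- Matrix::Matrix(0, nrow = n_genes, ncol = n, sparse = TRUE,
                      dimnames = list(c("MT-G001", sprintf("GENE%04d", seq_len(n_genes - 1))),
                                      sprintf("cell%02d", seq_len(n))))
  for (j in seq_len(n)) {
    # non-mito genes get 1 count each; mito count set to hit the target pct
    k <- detected[j] - (mito_pct[j] > 0)
    m[1 + seq_len(k), j] <- 1
    if (mito_pct[j] > 0)
      m[1, j] <- max(1, round(mito_pct[j] / (100 - mito_pct[j]) * k))
  }
  cell_dataset(m, data.frame(barcode = colnames(m),
                             condition = rep(c("control", "disease"), length.out = n)))
}

# dataset with two clearly separated expression programs for clustering tests
separated_populations <- function(n_per = 30, n_genes = 60, shift = 8, seed = 42) {
  set.seed(seed)
  base <- matrix(rpois(n_genes * 2 * n_per, 2), nrow = n_genes)
  base[1:15, seq_len(n_per)] <- base[1:15, seq_len(n_per)] + shift
  base[16:30, n_per + seq_len(n_per)] <- base[16:30, n_per + seq_len(n_per)] + shift
  dimnames(base) <- list(sprintf("GENE%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(2 * n_per)))
  cd <- cell_dataset(base, data.frame(barcode = colnames(base),
                                      condition = "control",
                                      truth = rep(c("P1", "P2"), each = n_per)))
  normalize_counts(cd, 1e4)
}

# hand-built DE tables for categorization tests
de_row <- function(gene, lfc, p, padj = p) {
  tibble::tibble(gene = gene, log2FC = lfc, p_nominal = p, p_adj = padj,
                 pct_disease = 0.5, pct_control = 0.5, significant = NA)
}
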