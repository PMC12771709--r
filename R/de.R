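#' Poisson likelihood-ratio differential expression
#'
#' Per gene, compares a Poisson model with a condition term against an
#' intercept-only model, both with a `log(per-cell total counts)` offset, and
#' takes the deviance difference to a chi-squared distribution with 1 df.
#' Under this model the maximum-likelihood rates are the group count totals
#' divided by the group exposure totals, so the likelihood-ratio statistic
#' has the closed form `2 * sum_groups Y_g log(mu_g / mu_0)` and is computed
#' vectorized over genes; it is identical to a per-gene
#' `glm(y ~ group + offset(log(total)), family = poisson)` fit.
#'
#' The log2 fold change is `log2((m_d + 1) / (m_c + 1))` on group means of
#' linear normalized expression (counts scaled to `target_sum` per cell), the
#' convention of the single-cell toolchain this test mirrors. Genes detected
#' in at most `min_pct` of cells in both groups are not tested; all-zero
#' genes are excluded.
#'
#' @param data A [cell_dataset()].
#' @param condition_field Column of `data$cells` holding the two conditions.
#' @param cell_type If given, restrict to cells whose `cell_type_field`
#'   equals this value.
#' @param cell_type_field Column holding cell types (default `"cell_type"`).
#' @param disease_level,control_level Condition levels; default `"disease"`
#'   vs `"control"`, falling back to last/first sorted level.
#' @param min_pct Detection-fraction filter: test genes expressed in more
#'   than `min_pct` of cells in at least one group (default 0.1).
#' @param target_sum Scaling total for the fold-change means (default 10000).
#'
#' @return A `de_table` tibble: `gene`, `log2FC`, `p_nominal`, `p_adj`
#'   (`NA` until [adjust_and_flag()]), `pct_disease`, `pct_control`,
#'   `significant`.
#' @export
poisson_de <- function(data, condition_field = "condition", cell_type = NULL,
                       cell_type_field = "cell_type",
                       disease_level = NULL, control_level = NULL,
                       min_pct = 0.1, target_sum = 1e4) {
  stopifnot(is(data, "cell_dataset"))
  if (!is.null(cell_type)) {
    if (!cell_type_field %in% names(data$cells))
      abort(sprintf("Column `%s` not found in cell annotations.", cell_type_field))
    data <- subset_cells(data, data$cells[[cell_type_field]] == cell_type)
  }
  cond <- as.character(data$cells[[condition_field]])
  lev <- sort(unique(cond))
  if (is.null(disease_level))
    disease_level <- if ("disease" %in% lev) "disease" else lev[length(lev)]
  if (is.null(control_level))
    control_level <- if ("control" %in% lev) "control" else setdiff(lev, disease_level)[1]
  for (l in c(disease_level, control_level)) {
    if (sum(cond == l) < 2)
      abort(sprintf("Condition `%s` has fewer than 2 cells.", l))
  }
  use <- cond %in% c(disease_level, control_level)
  data <- subset_cells(data, use)
  cond <- cond[use]
  dis <- cond == disease_level

  counts <- data$counts
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    keep <- lib > 0
    data <- subset_cells(data, keep); counts <- data$counts
    dis <- dis[keep]; lib <- lib[keep]
  }

  Y1 <- Matrix::rowSums(counts[, dis, drop = FALSE])
  Y0 <- Matrix::rowSums(counts[, !dis, drop = FALSE])
  T1 <- sum(lib[dis]); T0 <- sum(lib[!dis])
  pct1 <- Matrix::rowSums(counts[, dis, drop = FALSE] > 0) / sum(dis)
  pct0 <- Matrix::rowSums(counts[, !dis, drop = FALSE] > 0) / sum(!dis)

  tested <- (Y1 + Y0) > 0 & (pct1 > min_pct | pct0 > min_pct)
  n_allzero <- sum((Y1 + Y0) == 0)
  if (n_allzero > 0)
    inform(sprintf("poisson_de: %d all-zero gene(s) excluded.", n_allzero))

  mu1 <- Y1 / T1; mu0g <- Y0 / T0; mu0 <- (Y1 + Y0) / (T1 + T0)
  xlogy <- function(x, r) ifelse(x > 0, x * log(r), 0)
  lrt <- 2 * (xlogy(Y1, mu1 / mu0) + xlogy(Y0, mu0g / mu0))
  p <- pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)

  # fold change on linear normalized means with pseudocount 1
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / lib)
  m1 <- Matrix::rowSums(scaled[, dis, drop = FALSE]) / sum(dis)
  m0 <- Matrix::rowSums(scaled[, !dis, drop = FALSE]) / sum(!dis)
  lfc <- log2((m1 + 1) / (m0 + 1))

  out <- tibble(
    gene = rownames(counts),
    log2FC = unname(lfc),
    p_nominal = unname(p),
    p_adj = NA_real_,
    pct_disease = unname(pct1),
    pct_control = unname(pct0),
    significant = NA
  )[tested, ]
  class(out) <- c("de_table", class(out))
  attr(out, "groups") <- c(disease = disease_level, control = control_level)
  out
}

#' Multiple-testing adjustment and significance flags
#'
#' Adjusts nominal p-values across the tested genes (Bonferroni
#' `min(1, p * m)` by default, or Benjamini-Hochberg) and sets the
#' significance flag `p_adj < alpha & |log2FC| > lfc_min`.
#'
#' @param table A `de_table` from [poisson_de()] (any tibble with
#'   `p_nominal` and `log2FC` works).
#' @param alpha Adjusted-p threshold in (0, 1) (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.1),
#'   exceeded strictly.
#' @param method `"bonferroni"` (default) or `"bh"`.
#' @return The table with `p_adj` and `significant` filled in.
#' @export
adjust_and_flag <- function(table, alpha = 0.05, lfc_min = 0.1,
                            method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("`alpha` must be in (0, 1).")
  if (!all(c("p_nominal", "log2FC") %in% names(table)))
    abort("`table` must carry `p_nominal` and `log2FC`.")
  table$p_adj <- p.adjust(table$p_nominal,
                          method = if (method == "bh") "BH" else "bonferroni")
  table$significant <- table$p_adj < alpha & abs(table$log2FC) > lfc_min
  attr(table, "alpha") <- alpha
  attr(table, "lfc_min") <- lfc_min
  attr(table, "adjust_method") <- method
  table
}
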