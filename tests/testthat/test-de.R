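# small cell_dataset from an explicit counts vector, one gene of interest
# plus a filler gene so per-cell totals can be controlled
de_fixture <- function(y_disease, y_control, lib = NULL) {
  # `lib` is in the same order as c(y_control, y_disease)
  y <- c(y_control, y_disease)
  n <- length(y)
  if (is.null(lib)) lib <- rep(sum(y) %/% n + 10, n)
  filler <- lib - y
  stopifnot(all(filler >= 0))
  m <- rbind(GENE1 = y, FILLER = filler)
  colnames(m) <- sprintf("c%02d", seq_len(n))
  cell_dataset(m, data.frame(
    barcode = colnames(m),
    condition = rep(c("control", "disease"), c(length(y_control), length(y_disease)))
  ))
}

test_that("equal group means with equal libraries give p = 1 and log2FC = 0", {
  cd <- de_fixture(y_disease = c(2, 3, 4), y_control = c(3, 2, 4), lib = rep(20, 6))
  de <- poisson_de(cd, min_pct = 0)
  g <- de[de$gene == "GENE1", ]
  expect_equal(g$p_nominal, 1)
  expect_equal(g$log2FC, 0)
})

test_that("the likelihood-ratio statistic matches the closed-form deviance example", {
  cd <- de_fixture(y_disease = c(3, 4, 5, 4), y_control = c(0, 1, 2, 1),
                   lib = rep(10, 8))
  de <- poisson_de(cd, min_pct = 0)
  g <- de[de$gene == "GENE1", ]
  # group means 4 and 1, grand mean 2.5
  lrt <- qchisq(g$p_nominal, df = 1, lower.tail = FALSE)
  expect_equal(round(lrt, 2), 7.71)
  expect_equal(signif(g$p_nominal, 2), 0.0055)
})

test_that("the statistic equals a Poisson glm likelihood-ratio fit", {
  for (seed in 1:20) {
    set.seed(seed)
    n_dis <- sample(2:5, 1); n_ctrl <- sample(2:5, 1)
    lib_ctrl <- sample(10:40, n_ctrl, replace = TRUE)
    lib_dis <- sample(10:40, n_dis, replace = TRUE)
    rate <- runif(1, 0.05, 0.3)
    y_ctrl <- rpois(n_ctrl, lib_ctrl * rate)
    y_dis <- rpois(n_dis, lib_dis * rate * runif(1, 0.5, 2))
    if (sum(y_ctrl, y_dis) == 0 || any(y_ctrl > lib_ctrl) || any(y_dis > lib_dis)) next
    cd <- de_fixture(y_dis, y_ctrl, lib = c(lib_ctrl, lib_dis))
    de <- poisson_de(cd, min_pct = 0)
    g <- de[de$gene == "GENE1", ]
    lrt <- qchisq(g$p_nominal, df = 1, lower.tail = FALSE)
    grp <- rep(c("c", "d"), c(n_ctrl, n_dis))
    expect_equal(lrt,
                 oracle_poisson_glm(c(y_ctrl, y_dis), grp, c(lib_ctrl, lib_dis)),
                 tolerance = 1e-8)
  }
})

test_that("the offset makes the test invariant to sequencing-depth units", {
  base <- list(y_disease = c(4, 6, 5), y_control = c(1, 2, 1))
  p_of <- function(lib) {
    de <- poisson_de(de_fixture(base$y_disease, base$y_control, lib = lib),
                     min_pct = 0)
    de$p_nominal[de$gene == "GENE1"]
  }
  # rescaling every cell's library by a constant changes nothing
  expect_equal(p_of(rep(20, 6)), p_of(rep(60, 6)), tolerance = 1e-12)
  # redistributing depth among cells within a group (same totals) changes nothing
  expect_equal(p_of(c(10, 20, 30, 15, 25, 20)), p_of(c(30, 20, 10, 20, 20, 20)),
               tolerance = 1e-12)
})

test_that("detection filter and degenerate inputs behave as specified", {
  m <- rbind(ALLZERO = c(0, 0, 0, 0), RARE = c(1, 0, 0, 0),
             OK = c(5, 6, 1, 2))
  colnames(m) <- paste0("c", 1:4)
  cd <- cell_dataset(m, data.frame(barcode = colnames(m),
                                   condition = rep(c("disease", "control"), each = 2)))
  expect_message(de <- poisson_de(cd, min_pct = 0.6), "all-zero")
  expect_false("ALLZERO" %in% de$gene)
  expect_false("RARE" %in% de$gene)   # detected in 50% of disease cells only
  expect_true("OK" %in% de$gene)

  one <- cell_dataset(m[, 1, drop = FALSE],
                      data.frame(barcode = "c1", condition = "disease"))
  expect_error(poisson_de(one), "fewer than 2 cells")
})

test_that("adjustment and flagging follow Bonferroni / BH conventions", {
  tab <- de_row(paste0("G", 1:10), lfc = rep(0.5, 10),
                p = c(0.001, 0.2, rep(0.9, 8)))
  bon <- adjust_and_flag(tab, method = "bonferroni")
  expect_equal(bon$p_adj[1], 0.01)
  expect_equal(bon$p_adj[2], 1)      # capped at 1
  expect_true(bon$significant[1])
  expect_false(bon$significant[2])

  bh <- adjust_and_flag(de_row(paste0("G", 1:4), lfc = rep(1, 4),
                               p = c(0.01, 0.02, 0.03, 0.04)), method = "bh")
  expect_equal(bh$p_adj, rep(0.04, 4))

  # the fold-change gate is strict
  gate <- adjust_and_flag(de_row(c("A", "B"), lfc = c(0.1, 0.11),
                                 p = c(1e-6, 1e-6)))
  expect_false(gate$significant[1])
  expect_true(gate$significant[2])
  expect_error(adjust_and_flag(tab, alpha = 1.5), "alpha")
  expect_true(all(bon$p_adj >= bon$p_nominal))
})

test_that("planted effects at |lfc| = 1 are recovered with correct signs", {
  cfg <- sim_config(n_genes = 800, cell_types = list(T1 = 300),
                    n_shared = 20, n_contrasting = 20,
                    n_specific_A = 10, n_specific_B = 10, seed = 41)
  sim <- simulate_study(cfg, "A")
  de <- adjust_and_flag(poisson_de(sim$data))
  planted <- sim$truth$genes[sim$truth$genes$sign_A != 0, ]
  hit <- de[match(planted$gene, de$gene), ]
  expect_gte(mean(hit$significant, na.rm = TRUE), 0.9)
  rec <- hit[!is.na(hit$significant) & hit$significant, ]
  sgn_truth <- planted$sign_A[match(rec$gene, planted$gene)]
  expect_gte(mean(sign(rec$log2FC) == sgn_truth), 0.95)
})
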