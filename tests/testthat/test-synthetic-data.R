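base_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400, cell_types = list(T1 = 100), n_shared = 20,
         n_contrasting = 20, n_specific_A = 10, n_specific_B = 10, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("config is validated with the offending field named", {
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(mito_gene_fraction = 1.5), "mito_gene_fraction")
  expect_error(sim_config(baseline_mean = 0), "baseline_mean")
  expect_error(sim_config(cell_types = list(50)), "cell_types")
  expect_error(sim_config(n_genes = 50, n_shared = 200), "n_genes")
})

test_that("ground truth echoes the planted design and forms a partition", {
  out <- simulate_study(base_cfg(), "A")
  tr <- out$truth$genes
  expect_equal(sum(tr$category == "shared"), 20)
  expect_equal(sum(tr$category == "contrasting"), 20)
  expect_equal(sum(tr$category == "specific_A"), 10)
  expect_equal(anyDuplicated(tr$gene), 0L)
  # cross-study sign structure
  expect_true(all(tr$sign_A[tr$category == "shared"] ==
                    tr$sign_B[tr$category == "shared"]))
  expect_true(all(tr$sign_A[tr$category == "contrasting"] ==
                    -tr$sign_B[tr$category == "contrasting"]))
  expect_true(all(tr$sign_B[tr$category == "specific_A"] == 0))
  expect_true(all(tr$sign_A[tr$category == "specific_B"] == 0))
})

test_that("generation is deterministic under a fixed seed", {
  a1 <- simulate_study(base_cfg(), "A")
  a2 <- simulate_study(base_cfg(), "A")
  expect_identical(a1, a2)
  b <- simulate_study(base_cfg(), "B")
  expect_false(identical(a1$data$counts, b$data$counts))
  expect_identical(a1$truth$genes$gene, b$truth$genes$gene)
})

test_that("counts are non-negative integers with MT- named mito genes", {
  d <- simulate_study(base_cfg(), "A")$data
  expect_true(all(d$counts@x >= 0))
  expect_true(all(d$counts@x == round(d$counts@x)))
  expect_identical(d$genes$mito, startsWith(d$genes$gene, "MT-"))
  expect_gt(sum(d$genes$mito), 0)
})

test_that("planted up-genes show the planted fold change empirically", {
  # Monte-Carlo over NB sampling at 500 cells/group, seeds 21, 22, 23
  for (seed in 21:23) {
    cfg <- base_cfg(cell_types = list(T1 = 500), n_genes = 600, seed = seed)
    out <- simulate_study(cfg, "A")
    up <- out$truth$genes$gene[out$truth$genes$sign_A == 1]
    dis <- out$data$cells$condition == "disease"
    m1 <- Matrix::rowMeans(out$data$counts[up, dis, drop = FALSE])
    m0 <- Matrix::rowMeans(out$data$counts[up, !dis, drop = FALSE])
    ratio <- mean(m1 / m0)
    expect_gt(ratio, 1.7)
    expect_lt(ratio, 2.3)
  }
})

test_that("mitochondrial library share matches the configured fraction", {
  cfg <- base_cfg(cell_types = list(T1 = 500), seed = 31)
  d <- simulate_study(cfg, "A")$data
  expect_lt(abs(mean(per_cell_qc(d)$mito_pct) / 100 - 0.04), 0.015)
})

test_that("signed-network generator plants a uniquely top regulator", {
  for (seed in 1:5) {
    net <- simulate_signed_network(6, 0.5, seed = seed)
    oracle <- oracle_perturbagen(net$graph, net$observed)
    expect_identical(oracle$node[1], net$truth$node[1])
    expect_equal(oracle$score[1], net$truth$score[1])
    # uniqueness of the top score
    expect_gt(oracle$score[1], max(oracle$score[oracle$node != net$truth$node[1]]))
  }
})

test_that("signed-network generator edge cases", {
  expect_error(simulate_signed_network(2, 0, seed = 1), "zero edges")
  n1 <- simulate_signed_network(8, 0.3, seed = 9)
  n2 <- simulate_signed_network(8, 0.3, seed = 9)
  expect_identical(n1$graph$edges, n2$graph$edges)
  expect_identical(n1$observed, n2$observed)
})

test_that("reference lists control overlap and sign agreement", {
  truth <- simulate_study(base_cfg(), "A")$truth
  planted_A <- truth$genes$gene[truth$genes$sign_A != 0]

  r0 <- suppressWarnings(simulate_reference_lists(truth, overlap_fraction = 0,
                                                  seed = 2))
  expect_length(intersect(r0$post_mortem$gene, planted_A), 0)

  r1 <- simulate_reference_lists(truth, overlap_fraction = 1,
                                 sign_agreement = 1, seed = 2)
  expect_setequal(intersect(r1$post_mortem$gene, planted_A), planted_A)
  # full sign agreement: concordance of planted genes is 100%
  q <- tibble::tibble(gene = truth$genes$gene,
                      log2FC = truth$genes$sign_A * truth$planted_lfc)
  conc <- directional_concordance(q[q$log2FC != 0, ], r1$post_mortem)
  expect_equal(conc$n_discordant, 0L)
  expect_equal(conc$concordant_pct, 100)

  rh <- simulate_reference_lists(truth, overlap_fraction = 0.5, seed = 2)
  expect_equal(length(intersect(rh$post_mortem$gene, planted_A)),
               round(0.5 * length(planted_A)))
  expect_true("PLANTED_SET" %in% names(rh$gene_sets))
})
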