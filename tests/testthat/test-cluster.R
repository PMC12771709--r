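test_that("silhouette width matches hand evaluation on the two-pair instance", {
  emb <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c("a", "a", "b", "b")
  expect_equal(round(silhouette_width(emb, lab), 3), 0.990)
  expect_equal(silhouette_width(emb, lab), oracle_silhouette(emb, lab))
})

test_that("silhouette of randomly labelled duplicated clusters is near zero", {
  # two identical point clouds, labels assigned independently of position
  emb <- matrix(rep(c(0, 1, 2, 3), 2), ncol = 1)
  lab <- rep(c("a", "b"), 4)
  s <- silhouette_width(emb, lab)
  expect_equal(s, oracle_silhouette(emb, lab))
  expect_lt(abs(s), 0.15)
})

test_that("silhouette approaches 1 for widely separated equal pair clusters", {
  for (sep in c(1e3, 1e6)) {
    emb <- matrix(c(0, 1, sep, sep + 1), ncol = 1)
    expect_gt(silhouette_width(emb, c("a", "a", "b", "b")), 1 - 4 / sep)
  }
})

test_that("silhouette agrees with the brute-force formula on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:20, 1)
    emb <- matrix(rnorm(n * 2), ncol = 2)
    lab <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- silhouette_scores(emb, lab)$silhouette
    expect_true(all(s >= -1 & s <= 1))
    expect_equal(silhouette_width(emb, lab), oracle_silhouette(emb, lab),
                 tolerance = 1e-12)
  }
})

test_that("silhouette rejects a single cluster", {
  expect_error(silhouette_width(matrix(1:4, ncol = 1), rep("a", 4)), "2 clusters")
})

test_that("the k scan picks k = 2 for two well-separated populations", {
  cd <- separated_populations()
  res <- cluster_cells(cd, n_pcs = 5, k_candidates = c(2, 3, 4), seed = 1)
  expect_equal(res$chosen_k, 2)
  # each cluster is pure in one planted population
  purity <- apply(table(res$labels, cd$cells$truth), 1, function(r) sum(r > 0))
  expect_true(all(purity == 1))
  res2 <- cluster_cells(cd, n_pcs = 5, k_candidates = c(2, 3, 4), seed = 1)
  expect_identical(res$labels, res2$labels)
  only2 <- cluster_cells(cd, n_pcs = 5, k_candidates = 2, seed = 1)
  expect_equal(only2$chosen_k, 2)
})

test_that("clustering input is validated", {
  cd <- separated_populations(n_per = 10)
  expect_error(cluster_cells(cd, n_pcs = 1000), "n_pcs")
  expect_error(cluster_cells(cd, n_pcs = 5, k_candidates = c(1, 2)), "candidate")
  raw <- cell_dataset(matrix(1:4, 2, dimnames = list(c("A", "B"), c("c1", "c2"))),
                      data.frame(barcode = c("c1", "c2")))
  expect_error(cluster_cells(raw, n_pcs = 1), "normalized")
})

test_that("marker annotation assigns the expressing type and weights shared markers", {
  cd <- separated_populations()
  labels <- rep(c("1", "2"), each = 30)
  markers <- list(TypeA = rownames(cd$counts)[1:15],
                  TypeB = rownames(cd$counts)[16:30])
  ann <- annotate_clusters(cd, labels, markers)
  expect_equal(ann$cell_type[ann$cluster == "1"], "TypeA")
  expect_equal(ann$cell_type[ann$cluster == "2"], "TypeB")

  # a marker listed by both types contributes with half weight: adding it to
  # both does not change the ranking
  markers2 <- list(TypeA = c(markers$TypeA, "GENE040"),
                   TypeB = c(markers$TypeB, "GENE040"))
  ann2 <- annotate_clusters(cd, labels, markers2)
  expect_identical(ann2$cell_type, ann$cell_type)
  expect_error(annotate_clusters(cd, labels, list(X = "NOT_A_GENE")), "marker")
})

test_that("annotation recovers planted types in a three-type simulation", {
  cfg <- sim_config(n_genes = 300, cell_types = list(TA = 40, TB = 40, TC = 40),
                    n_shared = 5, n_contrasting = 5, n_specific_A = 2,
                    n_specific_B = 2, seed = 17)
  sim <- simulate_study(cfg, "A")
  d <- normalize_counts(filter_cells(sim$data, min_genes = 10, verbose = FALSE))
  res <- cluster_cells(d, n_pcs = 10, k_candidates = 3, seed = 2)
  ann <- annotate_clusters(d, res$labels, sim$truth$markers)
  # map clusters to their majority true type; at least 2/3 annotated correctly
  majority <- vapply(sort(unique(res$labels)), function(cl) {
    names(which.max(table(d$cells$cell_type[res$labels == cl])))
  }, character(1))
  expect_gte(sum(ann$cell_type == majority[ann$cluster]), 2)
})

test_that("cell-type merging conserves counts and passes unmapped labels through", {
  lab <- c("Neuron_1", "Neuron_2", "Astro", "Neuron_1")
  out <- merge_cell_types(lab, c(Neuron_1 = "Neurons", Neuron_2 = "Neurons",
                                 Astro = "Astrocytes"))
  expect_equal(out, c("Neurons", "Neurons", "Astrocytes", "Neurons"))
  expect_length(out, length(lab))
  expect_warning(merge_cell_types(c("A", "Other"), c(A = "B")), "Other")
  expect_equal(suppressWarnings(merge_cell_types(c("A", "Other"), c(A = "B"))),
               c("B", "Other"))
  expect_equal(merge_cell_types(lab, c(Neuron_1 = "Neuron_1", Neuron_2 = "Neuron_2",
                                       Astro = "Astro")), lab)
  # two-column data frame form
  out2 <- merge_cell_types(lab, data.frame(fine = c("Neuron_1", "Neuron_2", "Astro"),
                                           broad = c("N", "N", "A")))
  expect_equal(table(out2)[["N"]], 3)
})
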