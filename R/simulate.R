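#' Configuration for the paired-study synthetic-data generator
#'
#' Defines the statistical conditions under which the two synthetic
#' two-condition studies are drawn: negative-binomial counts with
#' log-normally varying per-gene baseline means and per-cell library sizes,
#' marker-gene blocks that make cell types separable, a mitochondrial gene
#' block occupying a fixed expected share of each library, and planted
#' differential-expression effects whose cross-study structure (shared /
#' contrasting / study-specific) is the recovery target of the pipeline.
#'
#' @param n_genes Total number of genes.
#' @param cell_types Named list or vector giving, per cell type, the number
#'   of cells per condition (a scalar, or a length-2 `c(control, disease)`).
#' @param baseline_mean Mean of the per-gene baseline expression distribution
#'   (log-normal across genes), in counts per cell.
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param n_shared,n_contrasting,n_specific_A,n_specific_B Numbers of planted
#'   differentially expressed genes per cross-study category.
#' @param planted_lfc Absolute planted log2 fold change (disease vs control).
#' @param min_planted_mean Baseline-mean floor (counts per cell) for genes
#'   eligible to carry a planted effect, so that the planted truth concerns
#'   genes that are detectable in principle.
#' @param mito_gene_fraction Fraction of genes that are mitochondrial
#'   (named with the `MT-` prefix).
#' @param mito_expr_mean_frac Expected fraction of each cell's library
#'   contributed by mitochondrial genes.
#' @param libsize_cv Coefficient of variation of the log-normal per-cell
#'   library-size factor.
#' @param n_markers_per_type Marker genes planted per cell type.
#' @param marker_log2fc log2 elevation of marker genes in their own type.
#' @param seed Integer seed; fixes the gene plan and all draws.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       cell_types = list(Neurons = 300, Astrocytes = 300),
                       baseline_mean = 0.5,
                       dispersion = 2,
                       n_shared = 50,
                       n_contrasting = 50,
                       n_specific_A = 25,
                       n_specific_B = 25,
                       planted_lfc = 1.0,
                       min_planted_mean = 0.5,
                       mito_gene_fraction = 0.02,
                       mito_expr_mean_frac = 0.04,
                       libsize_cv = 0.3,
                       n_markers_per_type = 20,
                       marker_log2fc = 2,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      abort(sprintf("`%s` must be a single integer >= %d.", nm, min))
  }
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      abort(sprintf("`%s` must be a proportion in [0, 1].", nm))
  }
  chk_count(n_genes, "n_genes", 1)
  chk_count(n_shared, "n_shared"); chk_count(n_contrasting, "n_contrasting")
  chk_count(n_specific_A, "n_specific_A"); chk_count(n_specific_B, "n_specific_B")
  chk_count(seed, "seed")
  chk_prop(mito_gene_fraction, "mito_gene_fraction")
  chk_prop(mito_expr_mean_frac, "mito_expr_mean_frac")
  chk_prop(libsize_cv, "libsize_cv")
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    abort("`baseline_mean` must be a positive real.")
  if (!is.numeric(dispersion) || dispersion <= 0)
    abort("`dispersion` must be a positive real (Inf allowed).")
  if (!is.numeric(planted_lfc) || length(planted_lfc) != 1)
    abort("`planted_lfc` must be a single real (log2 units).")
  if (length(cell_types) < 1 || is.null(names(cell_types)) || any(names(cell_types) == ""))
    abort("`cell_types` must be a named list of per-condition cell counts.")
  ct <- lapply(cell_types, function(x) {
    x <- as.integer(x)
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || any(is.na(x)) || any(x < 1))
      abort("`cell_types` entries must be 1 or 2 positive counts (control, disease).")
    x
  })
  n_planted <- n_shared + n_contrasting + n_specific_A + n_specific_B
  n_mito <- max(1L, round(mito_gene_fraction * n_genes))
  n_marker <- n_markers_per_type * length(ct)
  if (n_planted + n_mito + n_marker > n_genes)
    abort("`n_genes` too small for the planted DEG, mitochondrial and marker blocks.")
  structure(
    list(n_genes = as.integer(n_genes), cell_types = ct,
         baseline_mean = baseline_mean, dispersion = dispersion,
         n_shared = as.integer(n_shared), n_contrasting = as.integer(n_contrasting),
         n_specific_A = as.integer(n_specific_A), n_specific_B = as.integer(n_specific_B),
         planted_lfc = planted_lfc, min_planted_mean = min_planted_mean,
         mito_gene_fraction = mito_gene_fraction,
         mito_expr_mean_frac = mito_expr_mean_frac, libsize_cv = libsize_cv,
         n_markers_per_type = as.integer(n_markers_per_type),
         marker_log2fc = marker_log2fc, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# study-invariant gene plan: names, baseline means, mito/marker blocks and
# planted categories with per-study effect signs; deterministic in the seed
plan_genes <- function(config) {
  with_seed(config$seed, {
    n <- config$n_genes
    n_mito <- max(1L, round(config$mito_gene_fraction * n))
    gene <- sprintf("GENE%05d", seq_len(n))
    gene[seq_len(n_mito)] <- sprintf("MT-G%03d", seq_len(n_mito))
    mu <- rlnorm(n, meanlog = log(config$baseline_mean) - 0.5, sdlog = 1)
    # give the mito block a fixed expected share of the library
    f <- config$mito_expr_mean_frac
    mito <- seq_len(n_mito)
    mu[mito] <- mu[mito] * (f / (1 - f)) * sum(mu[-mito]) / sum(mu[mito])

    types <- names(config$cell_types)
    pool <- setdiff(seq_len(n), mito)
    markers <- list()
    for (tp in types) {
      markers[[tp]] <- sort(sample(pool, config$n_markers_per_type))
      pool <- setdiff(pool, markers[[tp]])
    }
    n_cat <- c(shared = config$n_shared, contrasting = config$n_contrasting,
               specific_A = config$n_specific_A, specific_B = config$n_specific_B)
    eligible <- pool[mu[pool] >= config$min_planted_mean]
    if (length(eligible) < sum(n_cat))
      abort("Too few genes above `min_planted_mean` to host the planted DEGs; increase `n_genes` or lower the floor.")
    planted_idx <- sample(eligible, sum(n_cat))
    category <- rep(names(n_cat), n_cat)
    base_sign <- sample(c(-1, 1), sum(n_cat), replace = TRUE)
    sign_A <- ifelse(category == "specific_B", 0, base_sign)
    sign_B <- dplyr::case_when(
      category == "shared" ~ base_sign,
      category == "contrasting" ~ -base_sign,
      category == "specific_A" ~ 0,
      category == "specific_B" ~ base_sign
    )
    list(
      gene = gene, mu = mu, mito_idx = mito,
      markers = lapply(markers, function(i) gene[i]),
      marker_idx = markers,
      plan = tibble(gene = gene[planted_idx], category = category,
                    sign_A = sign_A, sign_B = sign_B)
    )
  })
}

#' Simulate one two-condition single-cell study
#'
#' Draws a sparse negative-binomial count matrix for one arm of a paired
#' cross-study design. Calling it twice with the same configuration and
#' `study = "A"` / `study = "B"` yields two studies whose planted effects
#' follow the cross-study plan: shared genes shifted in the same direction in
#' both studies, contrasting genes in opposite directions, and
#' study-specific genes shifted in one study only.
#'
#' @param config A [sim_config()].
#' @param study `"A"` or `"B"`; selects the planted effect signs.
#' @param study_label Label stored on the dataset (defaults to `study`).
#'
#' @return A list with `data` (a [cell_dataset()]) and `truth` (gene plan,
#'   marker sets, mitochondrial genes).
#' @export
simulate_study <- function(config, study = c("A", "B"), study_label = NULL) {
  if (!is(config, "sim_config")) abort("`config` must be a sim_config object.")
  study <- match.arg(study)
  study_label <- study_label %||% study
  pg <- plan_genes(config)
  sgn <- if (study == "A") pg$plan$sign_A else pg$plan$sign_B

  counts <- with_seed(config$seed + 101L + 7L * (study == "B"), {
    types <- names(config$cell_types)
    n_ctrl <- vapply(config$cell_types, `[`, integer(1), 1)
    n_dis <- vapply(config$cell_types, `[`, integer(1), 2)
    cell_type <- rep(rep(types, 2), c(n_ctrl, n_dis))
    condition <- rep(c("control", "disease"), c(sum(n_ctrl), sum(n_dis)))
    nc <- length(cell_type)
    sdlog <- sqrt(log(1 + config$libsize_cv^2))
    libf <- rlnorm(nc, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    mu <- matrix(pg$mu, nrow = config$n_genes, ncol = nc)
    for (tp in types) {
      mu[pg$marker_idx[[tp]], cell_type == tp] <-
        mu[pg$marker_idx[[tp]], cell_type == tp] * 2^config$marker_log2fc
    }
    planted_idx <- match(pg$plan$gene, pg$gene)
    dis <- condition == "disease"
    mu[planted_idx, dis] <- mu[planted_idx, dis] * 2^(sgn * config$planted_lfc)
    mu <- sweep(mu, 2, libf, `*`)
    y <- if (is.finite(config$dispersion)) {
      rnbinom(length(mu), size = config$dispersion, mu = mu)
    } else {
      rpois(length(mu), lambda = mu)
    }
    list(y = matrix(y, nrow = config$n_genes), cell_type = cell_type,
         condition = condition)
  })

  nc <- length(counts$cell_type)
  barcode <- sprintf("%s_%s_%05d", study_label, counts$condition, seq_len(nc))
  # two biological replicates per condition, as in a two-sample two-control design
  rep_id <- stats::ave(seq_len(nc), counts$condition,
                       FUN = function(i) 1L + (seq_along(i) > length(i) / 2))
  m <- counts$y
  dimnames(m) <- list(pg$gene, barcode)
  cells <- tibble(
    barcode = barcode,
    condition = counts$condition,
    sample = paste0(study_label, "_", counts$condition, "_s", rep_id),
    cell_type = counts$cell_type
  )
  data <- cell_dataset(m, cells, study = study_label)
  truth <- list(
    genes = pg$plan,
    markers = pg$markers,
    mito_genes = pg$gene[pg$mito_idx],
    planted_lfc = config$planted_lfc,
    study = study
  )
  list(data = data, truth = truth)
}

#' Simulate a signed regulatory network with a planted perturbagen
#'
#' Builds a structurally balanced acyclic signed digraph: each node carries a
#' latent polarity and every edge sign is the product of its endpoint
#' polarities, so all path-sign products are path-independent and sign
#' propagation is free of ambiguity. The first planted regulator is wired as
#' a source reaching every other node, and observed per-node change signs
#' are set so that perturbing it reverts all of them (its exhaustive
#' reversion score is `n_nodes - 1`, strictly above any other node, which
#' can revert at most `n_nodes - 2`). Ground-truth scores are computed in
#' closed form from the polarities, independently of [perturbagen_score()].
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edge_density Probability of each feasible (acyclic) background
#'   edge; the regulator's spokes are added on top.
#' @param n_regulators Number of planted regulators recorded in the truth
#'   (the first is the wired source; the rest are the highest-reach
#'   background nodes).
#' @param seed Integer seed.
#'
#' @return A list with `graph` (a [signed_graph()]), `observed` (named sign
#'   vector over all non-regulator nodes) and `truth` (tibble of planted
#'   regulators with their best directions and scores).
#' @export
simulate_signed_network <- function(n_nodes, edge_density, n_regulators = 1,
                                    seed = 1L) {
  if (n_nodes < 2) abort("`n_nodes` must be >= 2.")
  if (edge_density < 0 || edge_density > 1) abort("`edge_density` must be in [0, 1].")
  with_seed(seed, {
    nodes <- sprintf("N%03d", seq_len(n_nodes))
    sigma <- setNames(sample(c(-1, 1), n_nodes, replace = TRUE), nodes)
    from <- integer(0); to <- integer(0)
    for (i in setdiff(seq_len(n_nodes - 1), 1L)) {
      j <- which(runif(n_nodes - i) < edge_density) + i
      from <- c(from, rep(i, length(j))); to <- c(to, j)
    }
    if (n_nodes > 2 && length(from) == 0)
      abort("`edge_density` produced zero edges; increase it.")
    if (n_nodes == 2 && edge_density == 0)
      abort("`edge_density` produced zero edges; increase it.")
    # regulator spokes: node 1 reaches everything directly
    from <- c(rep(1L, n_nodes - 1), from)
    to <- c(2:n_nodes, to)
    esign <- unname(sigma[from] * sigma[to])
    edges <- tibble(from = nodes[from], to = nodes[to], sign = esign)
    g <- signed_graph(edges, nodes = nodes)

    # descendant counts on the DAG (upper-triangular, so a simple sweep)
    reach <- vector("list", n_nodes)
    for (i in rev(seq_len(n_nodes))) {
      kids <- to[from == i]
      reach[[i]] <- sort(unique(c(kids, unlist(reach[kids]))))
    }
    regs_extra <- order(-lengths(reach[-1]), nodes[-1])[seq_len(
      max(0, min(n_regulators - 1, n_nodes - 1)))] + 1L
    regs <- c(1L, regs_extra)

    # observed = polarity for everything the source reverts; the source is
    # excluded from the observed map
    observed <- sigma[nodes[-1]]

    truth <- purrr::map_dfr(regs, function(r) {
      # path sign r -> x is sigma[r] * sigma[x]; direction d reverts x iff
      # d * sigma[r] * sigma[x] == -observed[x]
      xs <- intersect(nodes[reach[[r]]], names(observed))
      scores <- vapply(c(down = -1, up = 1), function(d) {
        sum(d * sigma[[nodes[r]]] * sigma[xs] == -observed[xs])
      }, numeric(1))
      tibble(node = nodes[r], direction = names(scores)[which.max(scores)],
             score = as.integer(max(scores)))
    })
    list(graph = g, observed = observed, truth = truth, polarity = sigma)
  })
}

#' Simulate reference gene lists with controlled overlap
#'
#' Fabricates the external validation inputs consumed by the overlap module:
#' a post-mortem differential-expression reference table, a GWAS gene list,
#' and a gene-set (GMT) collection containing one set enriched for the
#' planted differentially expressed genes plus null sets.
#'
#' @param truth The `truth` element returned by [simulate_study()].
#' @param overlap_fraction Fraction of planted organoid DEGs present in the
#'   post-mortem reference (and in the GWAS list).
#' @param sign_agreement Probability that an overlapping gene's reference
#'   log2 fold change keeps the planted sign.
#' @param universe_size Size of the decoy gene universe the references draw
#'   from (includes the planted genes).
#' @param n_decoys Reference genes added from outside the planted set.
#' @param study `"A"` or `"B"`: which study's planted signs the reference
#'   log2 fold changes follow.
#' @param seed Integer seed.
#'
#' @return A list with `post_mortem` (tibble: gene, log2FC, p_adj), `gwas`
#'   (character vector), `gene_sets` (named list of gene vectors, the first
#'   enriched for planted DEGs), `universe` and `overlap_genes`.
#' @export
simulate_reference_lists <- function(truth, overlap_fraction = 0.5,
                                     sign_agreement = 1, universe_size = 2000,
                                     n_decoys = 100, study = "A", seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort("`overlap_fraction` must be in [0, 1].")
  planted <- truth$genes
  sgn <- if (study == "A") planted$sign_A else planted$sign_B
  planted <- planted[sgn != 0, ]
  sgn <- sgn[sgn != 0]
  n_overlap <- round(overlap_fraction * nrow(planted))
  if (overlap_fraction > 0 && n_overlap < 1)
    warn("`overlap_fraction` selects no genes; reference overlap is empty.")
  with_seed(seed, {
    extra_needed <- max(0, universe_size - nrow(truth$genes))
    decoy_pool <- sprintf("REF%05d", seq_len(extra_needed))
    universe <- c(truth$genes$gene, decoy_pool)
    take <- sample(nrow(planted), n_overlap)
    keep_sign <- runif(n_overlap) < sign_agreement
    ref_lfc <- sgn[take] * ifelse(keep_sign, 1, -1) * abs(truth$planted_lfc)
    decoys <- sample(decoy_pool, min(n_decoys, length(decoy_pool)))
    post_mortem <- tibble(
      gene = c(planted$gene[take], decoys),
      log2FC = c(ref_lfc, sample(c(-1, 1), length(decoys), TRUE) * runif(length(decoys), 0.2, 2)),
      p_adj = runif(n_overlap + length(decoys), 0, 0.05)
    )
    gwas <- unique(c(planted$gene[sample(nrow(planted), n_overlap)],
                     sample(decoy_pool, min(n_decoys, length(decoy_pool)))))
    enriched <- c(sample(planted$gene, min(30, nrow(planted))),
                  sample(decoy_pool, 5))
    nulls <- lapply(1:4, function(i) sample(universe, 25))
    names(nulls) <- paste0("NULL_SET_", 1:4)
    gene_sets <- c(list(PLANTED_SET = enriched), nulls)
    list(post_mortem = post_mortem, gwas = gwas, gene_sets = gene_sets,
         universe = universe, overlap_genes = planted$gene[take])
  })
}

#' Fabricate upstream cell-cell-communication output tables
#'
#' Produces the two external tables the communication-integration module
#' consumes: a ligand-activity table (ligand, activity score, target genes)
#' and a ligand-receptor pair table with significance flags. The top-ranked
#' ligand's targets are taken from `target_genes`, so that downstream
#' intersection and enrichment can be checked against a planted gene set.
#'
#' @param target_genes Genes used as the top ligand's target set.
#' @param n_ligands Number of ligands in the activity table.
#' @param n_pairs Number of ligand-receptor pairs.
#' @param seed Integer seed.
#'
#' @return A list with `ligand_activity` (tibble: ligand, activity, targets
#'   list-column) and `lr_pairs` (tibble: ligand, receptor, pathway,
#'   significant).
#' @export
simulate_ccc_tables <- function(target_genes, n_ligands = 10, n_pairs = 15,
                                seed = 1L) {
  with_seed(seed, {
    ligs <- sprintf("LIG%02d", seq_len(n_ligands))
    activity <- sort(runif(n_ligands, 0.1, 0.9), decreasing = TRUE)
    targets <- c(list(target_genes),
                 lapply(seq_len(n_ligands - 1),
                        function(i) sprintf("TGT%02d_%02d", i, 1:5)))
    recs <- sprintf("REC%02d", seq_len(n_pairs))
    pair_lig <- c(ligs[1], sample(ligs, n_pairs - 1, replace = TRUE))
    lr <- tibble(
      ligand = pair_lig, receptor = recs,
      pathway = paste0(pair_lig, "_PATH"),
      significant = c(TRUE, runif(n_pairs - 1) < 0.5)
    )
    list(
      ligand_activity = tibble(ligand = ligs, activity = activity, targets = targets),
      lr_pairs = lr
    )
  })
}
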