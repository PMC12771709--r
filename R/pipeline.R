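#' Pipeline configuration
#'
#' Assembles, validates and defaults the per-stage parameter blocks of
#' [run_pipeline()]. Unknown keys are rejected, every numeric field is
#' range-checked, and the seed is propagated to every stochastic stage.
#'
#' @param ... Named blocks overriding the defaults. Top-level keys:
#'   `seed`, `outdir`, `input` (paths `study_A` / `study_B` of MatrixMarket
#'   triplet directories, or `NULL` to simulate), `sim` (arguments of
#'   [sim_config()]), `qc` (`min_genes`, `max_genes`, `max_mito_pct`,
#'   `target_sum`), `cluster` (`n_pcs`, `k_candidates`), `de` (`alpha`,
#'   `lfc_min`, `adjust`, `min_pct`), `compare` (`ns_threshold`),
#'   `enrich` (`min_mapped`, `alpha`, `top_n`), `network` (`n_nodes`,
#'   `edge_density`, `hub_quantile`), `ccc` (`min_fraction`,
#'   `top_n_ligands`, `alpha`, `top_n`, `mode`), `overlap`
#'   (`overlap_fraction`, `sign_agreement`, `universe_size`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defaults <- list(
    seed = 1L,
    outdir = tempfile("scdiverge_run_"),
    input = list(study_A = NULL, study_B = NULL),
    sim = list(),
    qc = list(min_genes = 200, max_genes = 8000, max_mito_pct = 5.0,
              target_sum = 1e4),
    cluster = list(n_pcs = 20, k_candidates = 2:4),
    de = list(alpha = 0.05, lfc_min = 0.1, adjust = "bonferroni", min_pct = 0.1),
    compare = list(ns_threshold = 0.5),
    enrich = list(min_mapped = 3, alpha = 0.05, top_n = 100),
    network = list(n_nodes = 40, edge_density = 0.12, hub_quantile = 0.9),
    ccc = list(min_fraction = 0.1, top_n_ligands = 20, alpha = 0.05,
               top_n = 5, mode = "strict"),
    overlap = list(overlap_fraction = 0.5, sign_agreement = 1,
                   universe_size = 2000)
  )
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && k != "cluster") {
      bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad) && k != "sim")
        abort(paste0("Unknown key(s) in `", k, "`: ", paste(bad, collapse = ", ")))
      cfg[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else if (is.list(defaults[[k]])) {
      cfg[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg <- structure(cfg, class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Type- and range-checks every field, verifies referenced input paths
#' exist, and aggregates all problems into one error.
#'
#' @param config A `pipeline_config` (or plain named list of blocks).
#' @return `TRUE` invisibly; errors list every offending field.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 && x < 1
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    bad("seed: must be an integer")
  with(config$qc, {
    if (min_genes >= max_genes) bad("qc$min_genes: must be below qc$max_genes")
    if (max_mito_pct < 0 || max_mito_pct > 100) bad("qc$max_mito_pct: must be in [0, 100]")
    if (target_sum <= 0) bad("qc$target_sum: must be positive")
  })
  if (any(config$cluster$k_candidates < 2)) bad("cluster$k_candidates: each k must be >= 2")
  if (config$cluster$n_pcs < 1) bad("cluster$n_pcs: must be >= 1")
  if (!in01(config$de$alpha)) bad("de$alpha: must be in (0, 1)")
  if (config$de$lfc_min < 0) bad("de$lfc_min: must be non-negative")
  if (!config$de$adjust %in% c("bonferroni", "bh")) bad("de$adjust: must be bonferroni or bh")
  if (config$de$min_pct < 0 || config$de$min_pct >= 1) bad("de$min_pct: must be in [0, 1)")
  if (config$compare$ns_threshold < 0 || config$compare$ns_threshold > 1)
    bad("compare$ns_threshold: must be in [0, 1]")
  if (!in01(config$enrich$alpha)) bad("enrich$alpha: must be in (0, 1)")
  if (config$enrich$min_mapped < 0) bad("enrich$min_mapped: must be non-negative")
  if (config$network$edge_density < 0 || config$network$edge_density > 1)
    bad("network$edge_density: must be in [0, 1]")
  if (config$network$hub_quantile < 0 || config$network$hub_quantile > 1)
    bad("network$hub_quantile: must be in [0, 1]")
  if (config$ccc$min_fraction < 0 || config$ccc$min_fraction >= 1)
    bad("ccc$min_fraction: must be in [0, 1)")
  if (!in01(config$ccc$alpha)) bad("ccc$alpha: must be in (0, 1)")
  if (!config$ccc$mode %in% c("strict", "augmented"))
    bad("ccc$mode: must be strict or augmented")
  if (config$overlap$overlap_fraction < 0 || config$overlap$overlap_fraction > 1)
    bad("overlap$overlap_fraction: must be in [0, 1]")
  for (s in c("study_A", "study_B")) {
    p <- config$input[[s]]
    if (!is.null(p) && !dir.exists(p))
      bad(sprintf("input$%s: path does not exist (%s)", s, p))
  }
  if (length(errs))
    abort(paste0("Invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - ")))
  invisible(TRUE)
}

write_stage <- function(outdir, name, tab) {
  # list-columns are collapsed for the on-disk TSV
  tab <- mutate(as_tibble(tab), across(dplyr::where(is.list),
                                       ~ vapply(.x, paste, character(1), collapse = ",")))
  readr::write_tsv(tab, file.path(outdir, paste0(name, ".tsv")))
}

#' Run the full multi-level comparison pipeline
#'
#' Executes the stages in order qc, cluster, de (per study and cell type),
#' compare, enrich, network, ccc, overlap on two paired studies — either
#' simulated from `config$sim` or read from MatrixMarket triplet directories
#' given in `config$input`. Every stage writes its tables as TSV under
#' `config$outdir`, and a `provenance.json` records parameters, the seed and
#' input hashes. A stage failure aborts with the stage name; tables already
#' written are retained.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: per-stage summaries, category counts,
#'   top pathways, top perturbagens and overlap reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    stages_done <<- c(stages_done, name)
    res
  }
  report <- list(stages = character(0))

  # ---- inputs -------------------------------------------------------------
  simulated <- is.null(config$input$study_A)
  if (simulated) {
    sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim_A <- simulate_study(sc, "A"); sim_B <- simulate_study(sc, "B")
    studies <- list(A = sim_A$data, B = sim_B$data)
    truth <- sim_A$truth
  } else {
    studies <- list(A = read_cell_dataset(config$input$study_A, "A"),
                    B = read_cell_dataset(config$input$study_B, "B"))
    truth <- NULL
  }
  hashes <- if (!simulated) {
    vapply(c(config$input$study_A, config$input$study_B), function(d) {
      paste(unname(tools::md5sum(list.files(d, full.names = TRUE))), collapse = ",")
    }, character(1))
  } else NULL

  # ---- qc -----------------------------------------------------------------
  studies <- stage("qc", {
    out <- lapply(studies, function(s) {
      normalize_counts(filter_cells(
        s, config$qc$min_genes, config$qc$max_genes, config$qc$max_mito_pct,
        verbose = FALSE), config$qc$target_sum)
    })
    qc_log <- bind_rows(lapply(out, function(s) attr(s, "qc_log")), .id = "study")
    write_stage(config$outdir, "qc_summary", qc_log)
    report$qc <- qc_log
    out
  })

  # ---- cluster ------------------------------------------------------------
  stage("cluster", {
    for (nm in names(studies)) {
      cl <- cluster_cells(studies[[nm]], n_pcs = min(config$cluster$n_pcs,
                                                     n_cells(studies[[nm]]) - 1),
                          k_candidates = config$cluster$k_candidates,
                          seed = config$seed)
      studies[[nm]]$cells$cluster <- unname(cl$labels)
      if (!is.null(truth)) {
        ann <- annotate_clusters(studies[[nm]], cl$labels, truth$markers)
        map <- setNames(ann$cell_type, ann$cluster)
        studies[[nm]]$cells$cell_type_pred <- unname(map[cl$labels])
      }
      cells_nm <- studies[[nm]]$cells
      comp_field <- if ("cell_type" %in% names(cells_nm) &&
                        length(unique(cells_nm$cell_type)) >= 2) "cell_type" else "cluster"
      comp <- composition_test(studies[[nm]], "condition", comp_field)
      write_stage(config$outdir, paste0("composition_", nm), tidy(comp))
      report$composition[[nm]] <- glance(comp)
      report$silhouette[[nm]] <- glance(cl)
    }
    invisible(NULL)
  })

  # ---- de -----------------------------------------------------------------
  type_col <- function(s) if ("cell_type" %in% names(s$cells)) s$cells$cell_type else s$cells$cluster
  cell_types <- intersect(unique(type_col(studies$A)), unique(type_col(studies$B)))
  de_tables <- stage("de", {
    out <- list()
    for (ct in cell_types) {
      for (nm in names(studies)) {
        de <- adjust_and_flag(
          poisson_de(studies[[nm]], cell_type = ct, min_pct = config$de$min_pct,
                     target_sum = config$qc$target_sum),
          alpha = config$de$alpha, lfc_min = config$de$lfc_min,
          method = config$de$adjust)
        out[[ct]][[nm]] <- de
        write_stage(config$outdir, sprintf("de_%s_%s", nm, ct),
                    select(de, -dplyr::any_of("genes")))
      }
    }
    out
  })

  # ---- compare ------------------------------------------------------------
  categories <- stage("compare", {
    out <- list()
    for (ct in cell_types) {
      cat_tab <- categorize_degs(de_tables[[ct]]$A, de_tables[[ct]]$B,
                                 alpha = config$de$alpha,
                                 lfc_min = config$de$lfc_min,
                                 ns_threshold = config$compare$ns_threshold)
      if (!is.null(truth)) {
        dev <- truth$genes$gene[seq_len(min(10, nrow(truth$genes)))]
        cat_tab <- flag_developmental(cat_tab, dev)
      }
      out[[ct]] <- cat_tab
      write_stage(config$outdir, paste0("categories_", ct),
                  render_category_table(cat_tab))
      report$category_counts[[ct]] <- dplyr::count(cat_tab, .data$category)
    }
    out
  })

  # ---- references (synthetic validation inputs) ---------------------------
  refs <- if (!is.null(truth)) {
    simulate_reference_lists(truth,
                             overlap_fraction = config$overlap$overlap_fraction,
                             sign_agreement = config$overlap$sign_agreement,
                             universe_size = config$overlap$universe_size,
                             seed = config$seed + 11L)
  } else NULL

  # ---- enrich -------------------------------------------------------------
  enrichments <- stage("enrich", if (is.null(refs)) NULL else {
    out <- list()
    for (ct in cell_types) {
      ctab <- categories[[ct]]
      universe <- ctab$gene
      for (nm in names(studies)) {
        de <- de_tables[[ct]][[nm]]
        q <- intersect(de$gene[de$significant], universe)
        et <- ora(q, universe, refs$gene_sets,
                  min_mapped = config$enrich$min_mapped,
                  alpha = config$enrich$alpha,
                  lfc = setNames(de$log2FC, de$gene))
        out[[ct]][[nm]] <- et
        write_stage(config$outdir, sprintf("enrichment_%s_%s", nm, ct),
                    top_pathways(et, config$enrich$top_n))
      }
    }
    out
  })

  # ---- network ------------------------------------------------------------
  stage("network", {
    net <- simulate_signed_network(config$network$n_nodes,
                                   config$network$edge_density,
                                   seed = config$seed + 23L)
    ranks <- perturbagen_score(net$graph, net$observed)
    roles <- topology_roles(net$graph, config$network$hub_quantile)
    write_stage(config$outdir, "perturbagens", ranks)
    write_stage(config$outdir, "network_roles", roles)
    report$top_perturbagens <- head(select(ranks, "node", "direction", "score"), 5)
    report$network_truth <- net$truth
  })

  # ---- ccc ----------------------------------------------------------------
  stage("ccc", if (is.null(refs)) NULL else {
    ccc_in <- simulate_ccc_tables(refs$gene_sets$PLANTED_SET,
                                  seed = config$seed + 31L)
    expressed <- expression_filter(studies$A, config$ccc$min_fraction)
    genes <- intersect_targets(ccc_in$ligand_activity, ccc_in$lr_pairs,
                               top_n_ligands = config$ccc$top_n_ligands,
                               mode = config$ccc$mode)
    ct <- cell_types[1]
    shared <- shared_significant_pathways(enrichments[[ct]]$A,
                                          enrichments[[ct]]$B,
                                          alpha = config$ccc$alpha,
                                          top_n = config$ccc$top_n)
    write_stage(config$outdir, "ccc_shared_pathways", shared)
    report$ccc <- list(n_expressed = length(expressed),
                        n_intersected = length(genes),
                        shared_pathways = shared)
  })

  # ---- overlap ------------------------------------------------------------
  stage("overlap", if (is.null(refs)) NULL else {
    out <- list()
    for (ct in cell_types) {
      for (nm in names(studies)) {
        rep_tab <- overlap_report(de_tables[[ct]][[nm]], refs$post_mortem,
                                  universe = refs$universe)
        out[[paste(nm, ct, sep = "_")]] <- rep_tab
      }
      gw <- gwas_overlap(de_tables[[ct]]$A, refs$gwas, universe = refs$universe)
      out[[paste0("gwas_A_", ct)]] <- gw
    }
    ov <- bind_rows(out, .id = "comparison")
    write_stage(config$outdir, "overlap_reports", ov)
    report$overlap <- ov
  })

  # ---- provenance & report ------------------------------------------------
  prov <- list(
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    simulated = simulated,
    input_hashes = hashes,
    stages = stages_done
  )
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  report$stages <- stages_done
  report$outdir <- config$outdir
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$category_counts)) {
    for (ct in names(x$category_counts)) {
      cc <- x$category_counts[[ct]]
      cat(sprintf("  %s: %s\n", ct,
                  paste(sprintf("%s=%d", cc$category, cc$n), collapse = ", ")))
    }
  }
  cat("  outputs in:", x$outdir, "\n")
  invisible(x)
}
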