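#' Signed directed graph
#'
#' A directed graph whose edges carry an activation (+1) or inhibition (-1)
#' sign, the structure used for regulatory-network sign propagation.
#' Duplicate edges with conflicting signs are rejected.
#'
#' @param edges Data frame with columns `from`, `to`, `sign`. Signs may be
#'   given as +1/-1 or as the words `"activates"` / `"inhibits"`.
#' @param nodes Optional node names beyond those appearing in edges.
#' @param observed Optional named vector of observed change signs (+1/-1)
#'   attached to nodes.
#' @return A `signed_graph` object.
#' @export
signed_graph <- function(edges, nodes = NULL, observed = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to", "sign") %in% names(edges)))
    abort("`edges` needs columns from, to, sign.")
  s <- edges$sign
  if (is.character(s)) {
    s <- dplyr::case_match(tolower(s), "activates" ~ 1, "activation" ~ 1,
                           "+" ~ 1, "+1" ~ 1, "1" ~ 1,
                           "inhibits" ~ -1, "inhibition" ~ -1,
                           "-" ~ -1, "-1" ~ -1, .default = NA_real_)
  }
  s <- as.numeric(s)
  if (anyNA(s) || !all(s %in% c(-1, 1)))
    abort("Edge signs must be +1/-1 (or activates/inhibits).")
  edges$sign <- s
  key <- paste(edges$from, edges$to)
  conf <- tapply(edges$sign, key, function(v) length(unique(v)) > 1)
  if (any(conf))
    abort(paste0("Conflicting duplicate edges: ",
                 paste(names(conf)[conf], collapse = "; ")))
  edges <- distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  nodes <- union(nodes %||% character(0), union(edges$from, edges$to))
  structure(list(edges = edges, nodes = nodes, observed = observed),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf("<signed_graph> %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

#' Read a signed edge list
#'
#' Three-column TSV (`from`, `to`, `sign`), header optional; the SIF dialect
#' `source<TAB>relation<TAB>target` with relations `activates` / `inhibits`
#' is also accepted.
#'
#' @param path File path.
#' @return A [signed_graph()].
#' @export
read_signed_graph <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 3) abort("Edge list needs 3 tab-separated columns.")
  first <- as.character(unlist(tab[1, ]))
  if (all(tolower(first[1:3]) %in% c("from", "to", "sign", "source", "target", "relation")))
    tab <- tab[-1, ]
  mid <- as.character(tab[[2]])
  if (all(tolower(mid) %in% c("activates", "inhibits", "activation", "inhibition"))) {
    edges <- tibble(from = as.character(tab[[1]]), to = as.character(tab[[3]]),
                    sign = mid)
  } else {
    edges <- tibble(from = as.character(tab[[1]]), to = as.character(tab[[2]]),
                    sign = as.character(tab[[3]]))
  }
  signed_graph(edges)
}

# adjacency list: node -> tibble(to, sign)
adjacency <- function(graph) {
  split(graph$edges[c("to", "sign")], factor(graph$edges$from, levels = graph$nodes))
}

# For every node reachable from `source`, the set of sign products achievable
# over simple paths: named list of numeric vectors (subsets of {-1, +1}).
# Simple paths only, so traversal terminates on cyclic graphs.
path_sign_sets <- function(graph, source) {
  adj <- adjacency(graph)
  reach <- new.env(parent = emptyenv())
  visit <- function(node, prod, on_path) {
    nb <- adj[[node]]
    if (is.null(nb) || nrow(nb) == 0) return()
    for (i in seq_len(nrow(nb))) {
      tgt <- nb$to[i]
      if (on_path[[tgt]] %||% FALSE) next
      p <- prod * nb$sign[i]
      cur <- reach[[tgt]]
      if (is.null(cur) || !(p %in% cur)) assign(tgt, union(cur, p), envir = reach)
      on_path[[tgt]] <- TRUE
      visit(tgt, p, on_path)
      on_path[[tgt]] <- FALSE
    }
  }
  on_path <- new.env(parent = emptyenv())
  on_path[[source]] <- TRUE
  visit(source, 1, on_path)
  as.list(reach)
}

#' Propagate a perturbation sign through a signed network
#'
#' Starting from `source` perturbed in the given direction, the predicted
#' sign at a reachable node is the direction sign multiplied by the product
#' of edge signs along the path. When distinct simple paths yield
#' conflicting products the node is `ambiguous`. The source itself is not
#' reported.
#'
#' @param graph A [signed_graph()].
#' @param source Node to perturb.
#' @param direction `"up"` (+1) or `"down"` (-1).
#' @return A tibble: `node`, `predicted` (+1 / -1 / NA), `ambiguous`.
#' @export
propagate_sign <- function(graph, source, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!source %in% graph$nodes) abort(sprintf("Node `%s` not in graph.", source))
  d <- if (direction == "up") 1 else -1
  sets <- path_sign_sets(graph, source)
  if (length(sets) == 0)
    return(tibble(node = character(0), predicted = numeric(0), ambiguous = logical(0)))
  amb <- lengths(sets) > 1
  tibble(
    node = names(sets),
    predicted = unname(ifelse(amb, NA_real_, d * vapply(sets, `[`, numeric(1), 1))),
    ambiguous = unname(amb)
  ) |> arrange(.data$node)
}

#' Perturbagen scoring: rank nodes by reverted observed changes
#'
#' For every node and both perturbation directions, counts the
#' observed-change nodes it reaches whose propagated sign is *opposite* to
#' the observed sign (i.e. the perturbation reverts them); ambiguous nodes
#' are excluded from the count. Each node reports its better direction;
#' ranking is by score descending with ties broken by node name.
#'
#' @param graph A [signed_graph()].
#' @param observed Named vector of observed change signs (+1/-1) per gene;
#'   defaults to the signs stored on the graph.
#' @return A `perturbagen_table` tibble: `node`, `direction`, `score`,
#'   `reverted` and `ambiguous` list-columns.
#' @export
perturbagen_score <- function(graph, observed = NULL) {
  observed <- observed %||% graph$observed
  if (is.null(observed) || length(observed) == 0)
    abort("`observed` signs are required (named +1/-1 vector).")
  if (!all(observed %in% c(-1, 1))) abort("Observed signs must be +1/-1.")
  obs <- observed[names(observed) %in% graph$nodes]
  rows <- purrr::map(graph$nodes, function(v) {
    sets <- path_sign_sets(graph, v)
    sets <- sets[names(sets) %in% names(obs)]
    amb <- names(sets)[lengths(sets) > 1]
    una <- setdiff(names(sets), amb)
    base <- vapply(sets[una], `[`, numeric(1), 1)
    # direction d reverts x iff d * pathsign(x) == -observed(x)
    rev_up <- una[base == -obs[una]]
    rev_down <- una[-base == -obs[una]]
    if (length(rev_down) > length(rev_up)) {
      tibble(node = v, direction = "down", score = length(rev_down),
             reverted = list(sort(rev_down)), ambiguous = list(sort(amb)))
    } else {
      tibble(node = v, direction = "up", score = length(rev_up),
             reverted = list(sort(rev_up)), ambiguous = list(sort(amb)))
    }
  })
  out <- arrange(bind_rows(rows), dplyr::desc(.data$score), .data$node)
  out$score <- as.integer(out$score)
  class(out) <- c("perturbagen_table", class(out))
  out
}

#' Topological role classification
#'
#' Flags three node roles on the unsigned directed skeleton:
#' * `hub` — total degree at or above the `hub_quantile` quantile of degrees;
#' * `central` — normalized directed betweenness centrality
#'   (normalization `1 / ((n-1)(n-2))`) at or above the same quantile;
#' * `attractor` — no incoming edges (no parent nodes).
#'
#' @param graph A [signed_graph()].
#' @param hub_quantile Degree/betweenness quantile for the hub and central
#'   flags (default 0.9).
#' @return A tibble: `node`, `degree`, `in_degree`, `out_degree`,
#'   `betweenness`, `hub`, `central`, `attractor`.
#' @export
topology_roles <- function(graph, hub_quantile = 0.9) {
  if (length(graph$nodes) == 0) abort("Graph is empty.")
  g <- igraph::graph_from_data_frame(graph$edges[c("from", "to")],
                                     vertices = graph$nodes, directed = TRUE)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  deg <- indeg + outdeg
  tibble(
    node = graph$nodes,
    degree = as.integer(deg[graph$nodes]),
    in_degree = as.integer(indeg[graph$nodes]),
    out_degree = as.integer(outdeg[graph$nodes]),
    betweenness = unname(btw[graph$nodes]),
    hub = deg[graph$nodes] >= quantile(deg, hub_quantile),
    central = btw[graph$nodes] >= quantile(btw, hub_quantile),
    attractor = indeg[graph$nodes] == 0
  )
}
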