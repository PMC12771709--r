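# Independent oracles used to pin down the package's implementations.
# Each is a deliberately naive, literal evaluation of the definition and
# shares no code with the functions it checks.

# per-point silhouette by literal loops over the formula
oracle_silhouette <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(sapply(same, function(j) sqrt(sum((embedding[i, ] - embedding[j, ])^2))))
    b <- Inf
    for (lab in setdiff(unique(labels), labels[i])) {
      others <- which(labels == lab)
      d <- mean(sapply(others, function(j) sqrt(sum((embedding[i, ] - embedding[j, ])^2))))
      b <- min(b, d)
    }
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# hypergeometric upper tail by enumerating all n-subsets of the universe
oracle_hyper_enum <- function(N, K, n, x) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # elements 1..K are the "set" genes
  mean(hits >= x)
}

# one-sided Fisher by enumerating all query-sized subsets of the universe
oracle_fisher_enum <- function(universe, query, reference) {
  obs <- length(intersect(query, reference))
  subsets <- utils::combn(length(universe), length(query))
  ref_idx <- which(universe %in% reference)
  mean(apply(subsets, 2, function(s) sum(s %in% ref_idx)) >= obs)
}

# Poisson LRT via glm with offset, per gene
oracle_poisson_glm <- function(y, group, lib) {
  full <- stats::glm(y ~ group + offset(log(lib)), family = stats::poisson())
  null <- stats::glm(y ~ 1 + offset(log(lib)), family = stats::poisson())
  as.numeric(null$deviance - full$deviance)
}

# perturbagen scores via igraph simple-path enumeration, both directions
oracle_perturbagen <- function(graph, observed) {
  g <- igraph::graph_from_data_frame(graph$edges[c("from", "to")],
                                     vertices = graph$nodes, directed = TRUE)
  esign <- graph$edges$sign
  names(esign) <- paste(graph$edges$from, graph$edges$to)
  score_one <- function(v) {
    best <- c(up = 0L, down = 0L)
    rev_sets <- list(up = character(0), down = character(0))
    for (tgt in names(observed)) {
      if (tgt == v) next
      paths <- igraph::all_simple_paths(g, from = v, to = tgt, mode = "out")
      if (length(paths) == 0) next
      prods <- unique(vapply(paths, function(p) {
        nm <- igraph::as_ids(p)
        prod(esign[paste(nm[-length(nm)], nm[-1])])
      }, numeric(1)))
      if (length(prods) != 1) next  # ambiguous
      if (1 * prods == -observed[[tgt]]) {
        best["up"] <- best["up"] + 1L
        rev_sets$up <- c(rev_sets$up, tgt)
      }
      if (-1 * prods == -observed[[tgt]]) {
        best["down"] <- best["down"] + 1L
        rev_sets$down <- c(rev_sets$down, tgt)
      }
    }
    dir <- if (best["down"] > best["up"]) "down" else "up"
    list(node = v, direction = dir, score = unname(best[dir]),
         reverted = sort(rev_sets[[dir]]))
  }
  res <- lapply(graph$nodes, score_one)
  out <- data.frame(node = sapply(res, `[[`, "node"),
                    direction = sapply(res, `[[`, "direction"),
                    score = sapply(res, `[[`, "score"))
  out[order(-out$score, out$node), ]
}

# random signed digraph (possibly cyclic) for oracle-equivalence sweeps
random_signed_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, ]
  if (nrow(pairs) == 0) pairs <- data.frame(from = nodes[1], to = nodes[2])
  pairs$sign <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
  signed_graph(pairs, nodes = nodes)
}
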