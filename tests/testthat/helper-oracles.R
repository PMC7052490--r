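# Independent oracles and small graph builders shared across the suite.
# Everything here deliberately avoids the package's own DFS/ranking code
# paths so that agreement between the two is informative.

# Build a metabolic_graph directly from an edge table (weights = means).
graph_from_edges <- function(edges, measure = "mean") {
  if (!"mean_weight" %in% names(edges)) edges$mean_weight <- edges$weight
  edges <- edges[, c("source", "target", "reaction_id", "gene",
                     "weight", "mean_weight")]
  structure(
    list(nodes = sort(unique(c(edges$source, edges$target))),
         edges = edges, currency = character(0),
         weight_measure = measure, n_candidates = nrow(edges)),
    class = "metabolic_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random simple directed weighted graph: distinct ordered pairs only.
random_graph <- function(seed, n_nodes = 10, n_edges = 25) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  all_pairs <- expand.grid(source = nodes, target = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  picked <- all_pairs[sample(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ]
  edges <- tibble::tibble(
    source = picked$source, target = picked$target,
    reaction_id = sprintf("R%03d", seq_len(nrow(picked))),
    gene = sprintf("G%03d", seq_len(nrow(picked))),
    weight = round(runif(nrow(picked), 0.5, 20), 3)
  )
  graph_from_edges(edges)
}

# Literal permutation-enumeration oracle: generate every ordered selection of
# intermediate nodes and keep chains whose consecutive edges all exist.
ordered_selections <- function(pool, k) {
  if (k == 0) return(list(character(0)))
  out <- list()
  for (i in seq_along(pool)) {
    for (rest in ordered_selections(pool[-i], k - 1)) {
      out[[length(out) + 1]] <- c(pool[i], rest)
    }
  }
  out
}

brute_force_chains <- function(graph, start, end, max_reactions) {
  edge_key <- paste(graph$edges$source, graph$edges$target, sep = "\r")
  has_edge <- function(a, b) paste(a, b, sep = "\r") %in% edge_key
  pool <- setdiff(graph$nodes, c(start, end))
  chains <- list()
  for (len in seq_len(max_reactions)) {
    for (mid in ordered_selections(pool, len - 1)) {
      chain <- c(start, mid, end)
      ok <- all(vapply(seq_len(len),
                       function(i) has_edge(chain[i], chain[i + 1]), TRUE))
      if (ok) chains[[length(chains) + 1]] <- chain
    }
  }
  chains
}

# igraph-based exhaustive oracle (independent C implementation).
igraph_chains <- function(graph, start, end, max_reactions) {
  g <- metaroutr::as_igraph(graph)
  paths <- igraph::all_simple_paths(g, from = start, to = end,
                                    mode = "out", cutoff = max_reactions)
  lapply(paths, function(p) igraph::V(g)$name[as.integer(p)])
}

chain_strings <- function(chains) {
  sort(vapply(chains, paste, "", collapse = " -> "))
}

route_chain_strings <- function(routes) {
  sort(vapply(routes$compounds, paste, "", collapse = " -> "))
}

# Independent ranking oracle: full sort then truncate.
rank_oracle <- function(routes, criterion, top_k) {
  score <- vapply(routes$weights, function(w) {
    if (criterion == "bottleneck") min(w)
    else if (length(w) == 1) 0 else sd(w)
  }, 1.0)
  chain <- vapply(routes$compounds, paste, "", collapse = " -> ")
  key <- if (criterion == "bottleneck") -score else score
  ord <- order(key, lengths(routes$weights), chain)
  list(score = score[ord][seq_len(min(top_k, length(ord)))],
       chain = chain[ord][seq_len(min(top_k, length(ord)))])
}

# Handcrafted six-reaction table exercising every construction rule:
# a currency intermediate, a sub-threshold gene, a parallel pair and a
# reversible reaction.
audit_reactions <- function() {
  tibble::tibble(
    reaction_id = c("R1", "R2", "R3", "R4", "R5", "R6"),
    substrates = list("A", "A", "B", c("C", "ATP"), "D", "A"),
    products = list("B", "B", "C", "D", "E", "F"),
    genes = list("G1", "G2", "G3", "G4", "G5", "GLOW"),
    reversible = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

audit_expression <- function() {
  # means: G1 3, G2 9, G3 4, G4 6, G5 2, GLOW 0.5
  tibble::tibble(
    gene = c("G1", "G2", "G3", "G4", "G5", "GLOW"),
    s1 = c(2, 8, 4, 5, 2, 0.4),
    s2 = c(4, 10, 4, 7, 2, 0.6)
  )
}

audit_graph <- function(measure = "mean") {
  weights <- filter_unexpressed(summarize_expression(audit_expression()))
  build_graph(audit_reactions(), weights, measure = measure)
}
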