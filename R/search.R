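#' Enumerate simple routes between two compounds
#'
#' Depth-first enumeration of every simple directed path (no compound
#' visited twice) from `start` to `end` using at most `max_reactions` edges.
#' Enumeration is complete — no heuristic pruning — and the result is
#' unscored; see [rank_routes()] and [find_routes()].
#'
#' @param graph A `metabolic_graph` from [build_graph()].
#' @param start,end Compound names; both must be nodes of the graph and must
#'   differ.
#' @param max_reactions Maximum number of reactions (edges) per route
#'   (default 8).
#' @return A tibble with one row per route and columns `compounds`,
#'   `reaction_ids`, `genes`, `weights` (list-columns, in route order) and
#'   `n_reactions`. Zero rows when no route exists.
#' @export
enumerate_routes <- function(graph, start, end, max_reactions = 8) {
  idx <- dfs_routes(graph, start, end, max_reactions)
  routes_from_indices(graph, idx)
}

dfs_routes <- function(graph, start, end, max_reactions,
                       top_k = NULL, prune = FALSE) {
  stopifnot(inherits(graph, "metabolic_graph"))
  check_positive_int(max_reactions, "max_reactions")
  if (!is.character(start) || !is.character(end) || start == end) {
    abort("start and end must be distinct compound names",
          class = "metaroutr_config_error")
  }
  for (cpd in c(start, end)) {
    if (!cpd %in% graph$nodes) {
      abort(paste0("compound not in network: ", cpd),
            class = "metaroutr_compound_error")
    }
  }
  edges <- graph$edges
  out_edges <- split(seq_len(nrow(edges)), factor(edges$source,
                                                  levels = graph$nodes))
  found <- list()
  n_found <- 0L
  # pruning state: the K best completed bottleneck scores so far
  best <- numeric(0)

  recurse <- function(node, visited, path, running_min) {
    for (e in out_edges[[node]]) {
      tgt <- edges$target[e]
      new_min <- min(running_min, edges$weight[e])
      if (prune && length(best) >= top_k && new_min < best[top_k]) next
      if (tgt == end) {
        n_found <<- n_found + 1L
        found[[n_found]] <<- c(path, e)
        if (prune) {
          best <<- sort(c(best, new_min), decreasing = TRUE)
          if (length(best) > top_k) best <<- best[seq_len(top_k)]
        }
      } else if (!(tgt %in% visited) && length(path) + 1L < max_reactions) {
        recurse(tgt, c(visited, tgt), c(path, e), new_min)
      }
    }
  }
  recurse(start, start, integer(0), Inf)
  found
}

routes_from_indices <- function(graph, idx) {
  edges <- graph$edges
  tibble::tibble(
    compounds = lapply(idx, function(p) c(edges$source[p[1]], edges$target[p])),
    reaction_ids = lapply(idx, function(p) edges$reaction_id[p]),
    genes = lapply(idx, function(p) edges$gene[p]),
    weights = lapply(idx, function(p) edges$weight[p]),
    n_reactions = vapply(idx, length, 1L)
  )
}

#' Bottleneck score of a route
#'
#' The bottleneck criterion scores a route by its weakest step: the minimum
#' edge weight along the route (the expression of the rate-limiting enzyme).
#' Higher is better — a good route keeps its "short slab" as high as
#' possible.
#'
#' @param weights Numeric vector of the route's edge weights (nonempty).
#' @return The minimum weight.
#' @export
bottleneck_score <- function(weights) {
  stopifnot(length(weights) >= 1)
  min(weights)
}

#' Stability score of a route
#'
#' The stability criterion scores a route by the standard deviation of its
#' edge weights (sample form, n-1; a single-edge route scores 0). Lower is
#' better — a stable route uses enzymes expressed at similar levels.
#'
#' @param weights Numeric vector of the route's edge weights (nonempty).
#' @return The standard deviation of the weights.
#' @export
stability_score <- function(weights) {
  stopifnot(length(weights) >= 1)
  if (length(weights) == 1) 0 else sd(weights)
}

#' Score and rank enumerated routes
#'
#' Scores every route under the chosen criterion and returns the top `top_k`:
#' bottleneck routes in descending score order (higher minimum is better),
#' stability routes ascending (lower spread is better). Ties are broken by
#' fewer reactions first, then by the lexicographic order of the compound
#' chain, so ranking is fully deterministic.
#'
#' @param routes Route tibble from [enumerate_routes()].
#' @param criterion `"bottleneck"` or `"stability"`.
#' @param top_k Maximum number of routes returned (default 10).
#' @return The ranked tibble with added columns `score`, `criterion` and
#'   `rank`, at most `top_k` rows.
#' @export
rank_routes <- function(routes, criterion = c("bottleneck", "stability"),
                        top_k = 10) {
  criterion <- match.arg(criterion)
  check_positive_int(top_k, "top_k")
  scorer <- if (criterion == "bottleneck") bottleneck_score else stability_score
  routes$score <- vapply(routes$weights, scorer, 1.0)
  routes$criterion <- rep(criterion, nrow(routes))
  key <- if (criterion == "bottleneck") -routes$score else routes$score
  chain <- vapply(routes$compounds, paste, "", collapse = " -> ")
  ord <- order(key, routes$n_reactions, chain)
  out <- routes[head(ord, top_k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank", "criterion", "score")
}

#' Search for top-K metabolic routes
#'
#' End-to-end route search on a built graph: enumerate all simple routes from
#' `start` to `end` with at most `max_reactions` edges, score them under the
#' chosen criterion, and return the top `top_k` (defaults: 8 reactions,
#' 10 routes). When a fold-change annotation is supplied, each route gains a
#' `regulation` list-column marking its enzymes `red` (up-regulated in the
#' user cohort), `green` (down-regulated) or `""`.
#'
#' With `prune = TRUE` (bottleneck criterion only) the depth-first search
#' abandons a branch as soon as its running minimum weight falls strictly
#' below the current K-th best completed bottleneck — an admissible bound, so
#' the result is identical to full enumeration, just faster on dense graphs.
#'
#' @inheritParams enumerate_routes
#' @inheritParams rank_routes
#' @param annotation Optional `fold_change_tbl` from [compute_fold_changes()].
#' @param prune Use the admissible bottleneck branch-and-bound (default
#'   `FALSE`; full enumeration).
#' @return A `route_ranking` tibble (columns `rank`, `criterion`, `score`,
#'   `compounds`, `reaction_ids`, `genes`, `weights`, `n_reactions`, and
#'   `regulation` when annotated). Search settings are recorded in the
#'   `search_config` attribute and shown by [glance()].
#' @examples
#' rx <- tibble::tibble(reaction_id = "R1", substrates = list("A"),
#'                      products = list("B"), genes = list("G1"),
#'                      reversible = FALSE)
#' w <- summarize_expression(tibble::tibble(gene = "G1", s1 = 5))
#' g <- build_graph(rx, w)
#' find_routes(g, "A", "B")
#' @export
find_routes <- function(graph, start, end, max_reactions = 8, top_k = 10,
                        criterion = c("bottleneck", "stability"),
                        annotation = NULL, prune = FALSE) {
  criterion <- match.arg(criterion)
  check_positive_int(top_k, "top_k")
  if (prune && criterion != "bottleneck") {
    abort("pruned search is only available for the bottleneck criterion",
          class = "metaroutr_config_error")
  }
  idx <- dfs_routes(graph, start, end, max_reactions,
                    top_k = top_k, prune = prune)
  routes <- routes_from_indices(graph, idx)
  n_enumerated <- nrow(routes)
  ranked <- rank_routes(routes, criterion, top_k)
  if (!is.null(annotation)) {
    cls <- stats::setNames(annotation$class, annotation$gene)
    ranked$regulation <- lapply(ranked$genes, function(gs) {
      k <- unname(cls[gs])
      regulation_colour(ifelse(is.na(k), "", k))
    })
  }
  attr(ranked, "search_config") <- list(
    start = start, end = end, max_reactions = max_reactions, top_k = top_k,
    criterion = criterion, weight_measure = graph$weight_measure,
    pruned = prune, n_routes_enumerated = n_enumerated
  )
  class(ranked) <- c("route_ranking", class(ranked))
  ranked
}

#' @exportS3Method
glance.route_ranking <- function(x, ...) {
  cfg <- attr(x, "search_config")
  tibble::tibble(
    start = cfg$start, end = cfg$end,
    max_reactions = cfg$max_reactions, top_k = cfg$top_k,
    criterion = cfg$criterion, weight_measure = cfg$weight_measure,
    pruned = cfg$pruned,
    n_routes_enumerated = cfg$n_routes_enumerated,
    n_routes_returned = nrow(x)
  )
}

#' @exportS3Method
tidy.route_ranking <- function(x, ...) {
  tibble::tibble(
    rank = x$rank,
    score = x$score,
    n_reactions = x$n_reactions,
    compounds = vapply(x$compounds, paste, "", collapse = " -> "),
    genes = vapply(x$genes, paste, "", collapse = ";")
  )
}

#' @exportS3Method
autoplot.route_ranking <- function(object, ...) {
  cfg <- attr(object, "search_config")
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$rank), y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "rank", y = paste0(cfg$criterion, " score"),
      title = paste0(cfg$start, " → ", cfg$end,
                     " (", cfg$criterion, ", ", cfg$weight_measure, ")"))
}

#' List compound names, optionally by prefix
#'
#' Case-insensitive prefix lookup over every compound appearing in a reaction
#' table, supporting interactive query construction (the offline counterpart
#' of an auto-completion box). An empty prefix lists all compounds.
#'
#' @param reactions Reaction tibble from [read_reaction_table()].
#' @param prefix Case-insensitive prefix (default `""`).
#' @return Sorted character vector of matching compound names.
#' @export
list_compounds <- function(reactions, prefix = "") {
  all <- sort(unique(c(unlist(reactions$substrates),
                       unlist(reactions$products))))
  if (nchar(prefix) == 0) return(all)
  all[startsWith(tolower(all), tolower(prefix))]
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(paste0(name, " must be a positive integer"),
          class = "metaroutr_config_error")
  }
}
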