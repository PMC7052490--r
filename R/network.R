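#' Default currency-metabolite set
#'
#' Ubiquitous compounds (water, protons, nucleotide cofactors, ...) connect
#' to a large fraction of the network and would create biologically
#' meaningless shortcuts if allowed as route intermediates, so they are
#' excluded as nodes by default. The list is deliberately overridable per
#' run: cofactors such as coenzyme A or NADH are legitimate start or end
#' compounds for some queries (fatty-acid oxidation, the electron transport
#' chain), so currency membership is a query-time choice, not a constant.
#'
#' @return Character vector of compound names treated as currency metabolites.
#' @export
default_currency_set <- function() {
  c("H2O", "H+", "ATP", "ADP", "NAD+", "NADH", "NADP+", "NADPH",
    "phosphate", "diphosphate", "CO2", "coenzyme A")
}

#' Build the expression-weighted metabolic graph
#'
#' Constructs a directed graph with compounds as nodes and enzyme-catalysed
#' reactions as edges. Four rules are applied:
#'
#' 1. **Currency exclusion** — substrate/product pairs touching a compound in
#'    `currency` yield no edge (unless that compound is listed in `retain`).
#' 2. **Expression weighting** — for each reaction, each (substrate, product)
#'    ordered pair and each catalysing gene present in `weights`, a candidate
#'    edge is created whose weight is the selected measure (`mean`, `median`
#'    or `sv`) of that gene. Reversible reactions also yield the mirrored
#'    pairs. Reactions with no surviving gene yield nothing.
#' 3. **Unexpressed-gene removal** — `weights` is expected to be already
#'    filtered with [filter_unexpressed()]; genes absent from it contribute
#'    no edges.
#' 4. **Parallel-edge collapse** — at most one edge survives per ordered
#'    compound pair: the candidate whose gene has the highest *mean*
#'    expression (always the mean, whatever measure weights the edges); see
#'    [collapse_parallel_edges()].
#'
#' Self-pairs (a compound appearing as both substrate and product of the same
#' reaction) never yield edges. Compounds left without any edge are dropped,
#' except those explicitly named in `retain`, which are kept as nodes even if
#' isolated.
#'
#' @param reactions Reaction tibble from [read_reaction_table()] or
#'   [generate_reaction_table()].
#' @param weights A `weight_tbl`, already filtered by [filter_unexpressed()].
#' @param currency Compound names excluded as intermediates
#'   (default [default_currency_set()]).
#' @param measure Edge-weight measure: `"mean"`, `"median"` or `"sv"`.
#' @param retain Compounds kept as nodes regardless of currency status or
#'   degree — typically the query's start and end compounds.
#' @return A `metabolic_graph`: list with elements `nodes` (character),
#'   `edges` (tibble `source`, `target`, `reaction_id`, `gene`, `weight`,
#'   `mean_weight`), `currency`, `weight_measure` and `n_candidates` (number
#'   of candidate edges before collapse, for auditing).
#' @examples
#' rx <- tibble::tibble(reaction_id = "R1", substrates = list(c("A", "ATP")),
#'                      products = list("B"), genes = list("G1"),
#'                      reversible = FALSE)
#' w <- summarize_expression(tibble::tibble(gene = "G1", s1 = 7, s2 = 7))
#' build_graph(rx, w)
#' @export
build_graph <- function(reactions, weights,
                        currency = default_currency_set(),
                        measure = c("mean", "median", "sv"),
                        retain = character()) {
  measure <- tryCatch(match.arg(measure), error = function(e) {
    abort(paste0("unknown weight measure: ", measure[1],
                 " (expected mean, median or sv)"),
          class = "metaroutr_config_error")
  })
  excluded <- setdiff(currency, retain)
  sel_w <- stats::setNames(weights[[measure]], weights$gene)
  mean_w <- stats::setNames(weights$mean, weights$gene)

  candidates <- purrr::pmap(
    list(reactions$reaction_id, reactions$substrates, reactions$products,
         reactions$genes, reactions$reversible),
    function(rid, subs, prods, genes, rev) {
      genes <- intersect(genes, names(sel_w))
      if (length(genes) == 0) return(NULL)
      pairs <- expand.grid(source = setdiff(subs, excluded),
                           target = setdiff(prods, excluded),
                           stringsAsFactors = FALSE)
      if (rev) {
        pairs <- rbind(pairs, data.frame(source = pairs$target,
                                         target = pairs$source))
      }
      pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
      if (nrow(pairs) == 0) return(NULL)
      tidyr::crossing(pairs, gene = genes) |>
        dplyr::mutate(reaction_id = rid, weight = unname(sel_w[.data$gene]),
                      mean_weight = unname(mean_w[.data$gene]))
    }
  )
  candidates <- dplyr::bind_rows(candidates)
  if (nrow(candidates) == 0) {
    candidates <- empty_edge_tbl()
  } else {
    candidates <- candidates[, c("source", "target", "reaction_id", "gene",
                                 "weight", "mean_weight")]
  }
  edges <- collapse_parallel_edges(candidates)
  nodes <- sort(unique(c(edges$source, edges$target, retain)))
  structure(
    list(nodes = nodes, edges = edges, currency = excluded,
         weight_measure = measure, n_candidates = nrow(candidates)),
    class = "metabolic_graph"
  )
}

#' Collapse parallel edges to the highest-mean enzyme
#'
#' When several reactions (or several isozymes of one reaction) connect the
#' same ordered compound pair, only one edge survives: the candidate whose
#' gene has the highest mean expression over the cohort. The comparison is
#' always on the mean, even when the search weights edges by median or sv.
#' The winner keeps its own reaction id, gene and selected-measure weight.
#' Ties are broken deterministically by the lexicographically smallest
#' (reaction_id, gene) pair. The result is sorted by (source, target), so the
#' collapsed edge list does not depend on the input row order.
#'
#' @param candidates Edge tibble with columns `source`, `target`,
#'   `reaction_id`, `gene`, `weight`, `mean_weight`.
#' @return The collapsed edge tibble: exactly one row per ordered
#'   (source, target) pair.
#' @export
collapse_parallel_edges <- function(candidates) {
  if (nrow(candidates) == 0) return(empty_edge_tbl())
  candidates |>
    dplyr::arrange(.data$source, .data$target, dplyr::desc(.data$mean_weight),
                   .data$reaction_id, .data$gene) |>
    dplyr::distinct(.data$source, .data$target, .keep_all = TRUE)
}

empty_edge_tbl <- function() {
  tibble::tibble(source = character(), target = character(),
                 reaction_id = character(), gene = character(),
                 weight = double(), mean_weight = double())
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf(
    "<metabolic_graph> %d compounds, %d edges (measure: %s, %d currency compounds excluded)\n",
    length(x$nodes), nrow(x$edges), x$weight_measure, length(x$currency)))
  print(x$edges, n = 5)
  invisible(x)
}

#' @exportS3Method
tidy.metabolic_graph <- function(x, ...) {
  x$edges
}

#' @exportS3Method
glance.metabolic_graph <- function(x, ...) {
  tibble::tibble(
    n_compounds = length(x$nodes),
    n_edges = nrow(x$edges),
    n_candidate_edges = x$n_candidates,
    n_collapsed = x$n_candidates - nrow(x$edges),
    weight_measure = x$weight_measure,
    n_currency_excluded = length(x$currency)
  )
}

#' @exportS3Method
autoplot.metabolic_graph <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(nodes, by = c(source = "name")) |>
    dplyr::left_join(nodes, by = c(target = "name"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = paste0("edge weight (", object$weight_measure, ")"))
}
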