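#' Read a reaction table
#'
#' Parses a delimited text file describing enzymatic reactions, one per row.
#' The header must name the columns `reaction_id`, `substrates`, `products`
#' and `genes`; a `reversible` column is optional and defaults to `FALSE`
#' (directions are never invented). Substrates, products and genes are
#' within-cell lists separated by `list_sep`. Compound names are trimmed of
#' surrounding whitespace and matched case-sensitively; gene symbols are
#' trimmed and uppercased.
#'
#' @param path Path to a CSV or TSV file. The field delimiter is autodetected
#'   from the extension (`.tsv`/`.tab`/`.txt` are tab-separated, anything else
#'   comma-separated) unless `delim` is given.
#' @param delim Optional field delimiter overriding autodetection.
#' @param list_sep Delimiter used inside substrate/product/gene cells
#'   (default `";"`).
#' @return A tibble with one row per reaction and columns `reaction_id`
#'   (character), `substrates`, `products`, `genes` (list-columns of character
#'   vectors) and `reversible` (logical), in file order.
#' @seealso [write_reaction_table()], [build_graph()]
#' @export
read_reaction_table <- function(path, delim = NULL, list_sep = ";") {
  raw <- read_delimited(path, delim)
  required <- c("reaction_id", "substrates", "products", "genes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("reaction table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "metaroutr_format_error"
    )
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      reaction_id = character(), substrates = list(), products = list(),
      genes = list(), reversible = logical()
    ))
  }

  ids <- stringr::str_trim(raw$reaction_id)
  if (any(ids == "" | is.na(ids))) {
    abort("reaction_id must be nonempty for every row",
          class = "metaroutr_validation_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate reaction_id: ", paste(dup, collapse = ", ")),
          class = "metaroutr_validation_error")
  }

  subs  <- split_cells(raw$substrates, list_sep)
  prods <- split_cells(raw$products, list_sep)
  genes <- lapply(split_cells(raw$genes, list_sep), toupper)
  # line number = data row + header row
  for (i in seq_along(ids)) {
    for (side in c("substrates", "products")) {
      vals <- if (side == "substrates") subs[[i]] else prods[[i]]
      if (length(vals) == 0) {
        abort(
          sprintf("reaction %s (line %d): empty %s cell", ids[i], i + 1L, side),
          class = "metaroutr_validation_error"
        )
      }
    }
  }

  reversible <- if ("reversible" %in% names(raw)) {
    parse_logical_cell(raw$reversible, ids)
  } else {
    rep(FALSE, length(ids))
  }

  tibble::tibble(
    reaction_id = ids,
    substrates = subs,
    products = prods,
    genes = genes,
    reversible = reversible
  )
}

#' Write a reaction table
#'
#' Inverse of [read_reaction_table()]: list-columns are joined with
#' `list_sep`, and the result round-trips through [read_reaction_table()].
#'
#' @param reactions Reaction tibble as returned by [read_reaction_table()].
#' @inheritParams read_reaction_table
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(reactions, path, delim = NULL, list_sep = ";") {
  out <- tibble::tibble(
    reaction_id = reactions$reaction_id,
    substrates = join_cells(reactions$substrates, list_sep),
    products = join_cells(reactions$products, list_sep),
    genes = join_cells(reactions$genes, list_sep),
    reversible = tolower(as.character(reactions$reversible))
  )
  readr::write_delim(out, path, delim = delim %||% delim_for(path))
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Reads a genes-by-samples table of non-negative expression values (for
#' example RNA-seq quantifications). The first column holds gene symbols
#' (uppercased on ingest, duplicates are an error); every remaining column is
#' one sample and must be numeric, finite and non-negative.
#'
#' @inheritParams read_reaction_table
#' @return A tibble whose first column is `gene` followed by one numeric
#'   column per sample.
#' @export
read_expression_matrix <- function(path, delim = NULL) {
  raw <- read_delimited(path, delim)
  if (ncol(raw) < 2) {
    abort("expression matrix needs a gene column plus at least one sample",
          class = "metaroutr_format_error")
  }
  genes <- toupper(stringr::str_trim(raw[[1]]))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene row(s): ", paste(dup, collapse = ", ")),
          class = "metaroutr_validation_error")
  }
  samples <- names(raw)[-1]
  vals <- lapply(samples, function(s) {
    x <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(x) | !is.finite(x) | x < 0)
    if (length(bad) > 0) {
      abort(
        sprintf("invalid expression value for gene %s, sample %s",
                genes[bad[1]], s),
        class = "metaroutr_validation_error"
      )
    }
    x
  })
  names(vals) <- samples
  tibble::tibble(gene = genes, !!!vals)
}

#' Write a gene-expression matrix
#'
#' Values are serialized as fixed six-decimal text so that write/read/write
#' cycles are byte-identical.
#'
#' @param expression Expression tibble as returned by [read_expression_matrix()].
#' @inheritParams read_reaction_table
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expression, path, delim = NULL) {
  out <- expression
  for (s in names(out)[-1]) out[[s]] <- sprintf("%.6f", out[[s]])
  readr::write_delim(out, path, delim = delim %||% delim_for(path))
  invisible(path)
}

#' Read a two-column user cohort file
#'
#' A user cohort is a two-column CSV of gene symbol and a single non-negative
#' expression value, used to flag up-/down-regulated enzymes by fold change
#' against the reference cohort. A header row is autodetected: if the second
#' field of the first row is non-numeric the row is treated as a header.
#'
#' @inheritParams read_reaction_table
#' @return A tibble with columns `gene` (uppercased symbol) and `value`.
#' @seealso [compute_fold_changes()]
#' @export
read_user_cohort <- function(path, delim = NULL) {
  delim <- delim %||% delim_for(path)
  lines <- readr::read_lines(path)
  lines <- lines[stringr::str_trim(lines) != ""]
  if (length(lines) == 0) {
    return(tibble::tibble(gene = character(), value = double()))
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 2)) {
    abort(sprintf("user cohort file must have exactly two columns (line %d has %d)",
                  which(n_fields != 2)[1], n_fields[n_fields != 2][1]),
          class = "metaroutr_format_error")
  }
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) fields <- fields[-1] # header row
  if (length(fields) == 0) {
    return(tibble::tibble(gene = character(), value = double()))
  }
  genes <- toupper(stringr::str_trim(vapply(fields, `[`, "", 1)))
  values <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  bad <- which(is.na(values) | !is.finite(values) | values < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid expression value for gene %s", genes[bad[1]]),
          class = "metaroutr_validation_error")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene symbol(s): ", paste(dup, collapse = ", ")),
          class = "metaroutr_validation_error")
  }
  tibble::tibble(gene = genes, value = values)
}

#' Write a two-column user cohort file
#'
#' @param cohort Tibble with columns `gene` and `value`.
#' @inheritParams read_reaction_table
#' @return `path`, invisibly.
#' @export
write_user_cohort <- function(cohort, path, delim = NULL) {
  out <- tibble::tibble(gene = cohort$gene,
                        value = sprintf("%.6f", cohort$value))
  readr::write_delim(out, path, delim = delim %||% delim_for(path),
                     col_names = FALSE)
  invisible(path)
}

#' Write a ranked route table
#'
#' Serializes a ranked route set (see [find_routes()]) as CSV/TSV: one row per
#' route with its rank, criterion, score (six significant digits), compound
#' chain joined by `" -> "`, reaction ids, enzyme gene symbols and — when the
#' search carried a user-cohort annotation — the per-enzyme regulation class
#' (`red` for up, `green` for down, empty otherwise), all `;`-joined.
#' An empty route set yields a header-only file.
#'
#' @param routes A `route_ranking` tibble from [find_routes()] or
#'   [rank_routes()].
#' @inheritParams read_reaction_table
#' @return `path`, invisibly.
#' @export
write_route_table <- function(routes, path, delim = NULL) {
  annotated <- "regulation" %in% names(routes)
  out <- tibble::tibble(
    rank = as.character(routes$rank %||% seq_len(nrow(routes))),
    criterion = as.character(routes$criterion),
    score = format_score(routes$score),
    compounds = vapply(routes$compounds, paste, "", collapse = " -> "),
    reactions = join_cells(routes$reaction_ids, ";"),
    genes = join_cells(routes$genes, ";")
  )
  if (annotated) out$regulation <- join_cells(routes$regulation, ";")
  if (nrow(out) == 0) {
    out$rank <- character() # keep a typed empty frame; header still written
  }
  readr::write_delim(out, path, delim = delim %||% delim_for(path))
  invisible(path)
}

#' Read back a ranked route table
#'
#' Parses a file written by [write_route_table()] into a tibble with the
#' list-columns restored. Mainly useful for checking and post-processing
#' saved results.
#'
#' @inheritParams read_reaction_table
#' @return A tibble with columns `rank`, `criterion`, `score`, `compounds`,
#'   `reaction_ids`, `genes` and, if present, `regulation`.
#' @export
read_route_table <- function(path, delim = NULL) {
  raw <- read_delimited(path, delim)
  out <- tibble::tibble(
    rank = as.integer(raw$rank),
    criterion = raw$criterion,
    score = as.numeric(raw$score),
    compounds = strsplit(raw$compounds, " -> ", fixed = TRUE),
    reaction_ids = split_cells(raw$reactions, ";"),
    genes = split_cells(raw$genes, ";")
  )
  if ("regulation" %in% names(raw)) {
    out$regulation <- lapply(strsplit(ifelse(is.na(raw$regulation), "",
                                             raw$regulation), ";", fixed = TRUE),
                             function(x) x)
  }
  out
}

#' Export a metabolic graph as GraphML
#'
#' Writes the graph in GraphML with a node attribute `compound` and edge
#' attributes `reaction_id`, `gene` and `weight`, consumable by standard
#' graph viewers (Cytoscape, Gephi) and by any generic GraphML reader.
#'
#' @param graph A `metabolic_graph` from [build_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a metabolic graph to an igraph object
#'
#' @param graph A `metabolic_graph` from [build_graph()].
#' @return A directed [igraph::igraph] with vertex attributes `name` and
#'   `compound` and edge attributes `reaction_id`, `gene`, `weight`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "metabolic_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  if (length(graph$nodes) > 0) {
    g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes,
                              compound = graph$nodes)
  }
  if (nrow(graph$edges) > 0) {
    idx <- rbind(match(graph$edges$source, graph$nodes),
                 match(graph$edges$target, graph$nodes))
    g <- igraph::add_edges(g, as.vector(idx),
                           reaction_id = graph$edges$reaction_id,
                           gene = graph$edges$gene,
                           weight = graph$edges$weight)
  }
  g
}

# --- internal helpers -------------------------------------------------------

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_delimited <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "metaroutr_io_error")
  }
  readr::read_delim(
    path, delim = delim %||% delim_for(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE
  )
}

split_cells <- function(x, sep) {
  lapply(x, function(cell) {
    if (is.na(cell)) return(character())
    parts <- stringr::str_trim(strsplit(cell, sep, fixed = TRUE)[[1]])
    parts[parts != ""]
  })
}

join_cells <- function(x, sep) {
  vapply(x, paste, "", collapse = sep)
}

parse_logical_cell <- function(x, ids) {
  norm <- tolower(stringr::str_trim(ifelse(is.na(x), "false", x)))
  out <- norm %in% c("true", "t", "1", "yes")
  bad <- !norm %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "")
  if (any(bad)) {
    abort(sprintf("reaction %s: unrecognized reversible value '%s'",
                  ids[which(bad)[1]], x[which(bad)[1]]),
          class = "metaroutr_validation_error")
  }
  out
}

format_score <- function(x) {
  vapply(x, function(v) format(signif(v, 6), scientific = FALSE, trim = TRUE), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
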