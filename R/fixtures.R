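#' Specification for a synthetic fixture
#'
#' Bundles the parameters of the synthetic-data generator: a random directed
#' reaction network containing designated currency metabolites, and a
#' log-normal expression matrix mimicking the positivity and right skew of
#' RNA-seq quantifications. Defaults give a mid-sized benchmark instance:
#' 30 compounds, 40 reactions, 3 currency compounds, 1-3 isozymes per
#' reaction, 20% reversible reactions, 10 samples, and 10% of genes forced
#' below the mean-expression threshold of 1 so the unexpressed-gene filter is
#' always exercised.
#'
#' @param n_compounds,n_reactions Network size (positive integers).
#' @param n_currency Number of currency metabolites woven into reactions
#'   (taken from the head of [default_currency_set()]; must not exceed its
#'   length or `n_compounds`).
#' @param genes_per_reaction Length-2 integer range; each reaction draws its
#'   gene count uniformly from it.
#' @param reversible_fraction Probability that a reaction is reversible.
#' @param meanlog,sdlog Log-normal location and scale for expression values.
#' @param n_samples Number of cohort samples.
#' @param unexpressed_fraction Fraction of genes rescaled to mean below 1.
#' @param seed Integer seed; generation is fully deterministic for a fixed `fixture_spec`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_compounds = 30, n_reactions = 40, n_currency = 3,
                         genes_per_reaction = c(1, 3),
                         reversible_fraction = 0.2,
                         meanlog = 1, sdlog = 1, n_samples = 10,
                         unexpressed_fraction = 0.1, seed = 1L) {
  stopifnot(n_compounds >= 1, n_reactions >= 0, n_currency >= 0,
            length(genes_per_reaction) == 2,
            genes_per_reaction[1] >= 1,
            genes_per_reaction[2] >= genes_per_reaction[1],
            reversible_fraction >= 0, reversible_fraction <= 1,
            sdlog >= 0, n_samples >= 1,
            unexpressed_fraction >= 0, unexpressed_fraction <= 1)
  if (n_currency > length(default_currency_set()) ||
      n_currency > n_compounds) {
    abort("n_currency exceeds available compounds",
          class = "metaroutr_config_error")
  }
  structure(
    list(n_compounds = n_compounds, n_reactions = n_reactions,
         n_currency = n_currency, genes_per_reaction = genes_per_reaction,
         reversible_fraction = reversible_fraction,
         meanlog = meanlog, sdlog = sdlog, n_samples = n_samples,
         unexpressed_fraction = unexpressed_fraction, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a random reaction table
#'
#' Draws `n_reactions` reactions over `n_compounds` ordinary compounds plus
#' `n_currency` currency metabolites. Currency compounds are attached to
#' reactions with elevated frequency (they are the "common compounds" of a
#' real network). Every reaction has at least one catalysing gene; gene
#' counts are drawn from `genes_per_reaction`. With the default spec the
#' table is guaranteed to exercise every construction rule: it contains at
#' least one reversible reaction and at least one parallel pair of reactions
#' over the same ordered compound pair.
#'
#' @param spec A [fixture_spec()].
#' @return A reaction tibble in the schema of [read_reaction_table()].
#' @export
generate_reaction_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  if (spec$n_reactions == 0) {
    return(tibble::tibble(reaction_id = character(), substrates = list(),
                          products = list(), genes = list(),
                          reversible = logical()))
  }
  compounds <- sprintf("C%03d", seq_len(spec$n_compounds))
  currency <- head(default_currency_set(), spec$n_currency)
  gene_pool <- sprintf("G%04d", seq_len(max(2L, spec$n_reactions * 2L)))

  one_side <- function() {
    side <- sample(compounds, sample(1:2, 1))
    if (spec$n_currency > 0 && runif(1) < 0.6) {
      side <- c(side, sample(currency, 1))
    }
    side
  }
  rows <- lapply(seq_len(spec$n_reactions), function(i) {
    list(
      reaction_id = sprintf("R%03d", i),
      substrates = one_side(),
      products = one_side(),
      genes = sample(gene_pool, sample(spec$genes_per_reaction[1]:
                                         spec$genes_per_reaction[2], 1)),
      reversible = runif(1) < spec$reversible_fraction
    )
  })
  tab <- tibble::tibble(
    reaction_id = vapply(rows, `[[`, "", "reaction_id"),
    substrates = lapply(rows, `[[`, "substrates"),
    products = lapply(rows, `[[`, "products"),
    genes = lapply(rows, `[[`, "genes"),
    reversible = vapply(rows, `[[`, TRUE, "reversible")
  )
  if (spec$reversible_fraction > 0 && !any(tab$reversible)) {
    tab$reversible[1] <- TRUE
  }
  if (spec$n_reactions >= 2) {
    # guarantee a parallel pair: last reaction repeats the first reaction's
    # compounds under a different enzyme
    n <- spec$n_reactions
    tab$substrates[[n]] <- tab$substrates[[1]]
    tab$products[[n]] <- tab$products[[1]]
    unused <- setdiff(gene_pool, tab$genes[[1]])
    tab$genes[[n]] <- unused[seq_len(min(length(tab$genes[[n]]),
                                         length(unused)))]
  }
  tab
}

#' Generate a random expression matrix
#'
#' Draws a genes-by-samples matrix of independent log-normal values with the
#' spec's location and scale. A `unexpressed_fraction` share of genes (the
#' leading rows) is rescaled to a mean drawn uniformly from (0.1, 0.9), below
#' the default expression threshold of 1, so downstream filtering always has
#' work to do. `sdlog = 0` degenerates to the constant `exp(meanlog)`.
#'
#' @param spec A [fixture_spec()].
#' @param genes Character vector of gene symbols (one row each).
#' @return An expression tibble (`gene` plus sample columns `S1`, `S2`, ...).
#' @export
generate_expression <- function(spec, genes) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  n_genes <- length(genes)
  vals <- matrix(rlnorm(n_genes * spec$n_samples, spec$meanlog, spec$sdlog),
                 nrow = n_genes)
  n_low <- floor(spec$unexpressed_fraction * n_genes)
  if (n_low > 0) {
    target <- runif(n_low, 0.1, 0.9)
    for (i in seq_len(n_low)) {
      vals[i, ] <- vals[i, ] * target[i] / mean(vals[i, ])
    }
  }
  colnames(vals) <- sprintf("S%d", seq_len(spec$n_samples))
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(vals))
}

#' Plant a high-expression pathway into a fixture
#'
#' Inserts reactions linking consecutive compounds of `chain`, each catalysed
#' by a fresh gene whose expression is constant at `floor` across samples
#' (mean `floor`, zero spread). `floor` must strictly exceed the highest mean
#' expression among all pre-existing genes; this is checked, and it
#' guarantees by construction that the planted route's bottleneck score
#' exceeds the bottleneck of every competing route, so a correct search must
#' rank the planted route first under the bottleneck criterion.
#'
#' @param reactions Reaction tibble to extend.
#' @param expression Expression tibble to extend.
#' @param chain Character vector of at least two compound names; compounds
#'   need not pre-exist in `reactions`.
#' @param floor Positive constant expression given to the planted genes.
#' @return A list with elements `reactions`, `expression` (both extended),
#'   `chain`, and `genes` (the planted gene symbols).
#' @export
plant_pathway <- function(reactions, expression, chain, floor) {
  stopifnot(length(chain) >= 2, is.numeric(floor), floor > 0)
  background <- as.matrix(expression[, -1, drop = FALSE])
  if (nrow(background) > 0) {
    bg_max <- max(rowMeans(background))
    if (floor <= bg_max) {
      abort(sprintf(
        "floor (%g) must strictly exceed the maximum background mean (%g); the rank-1 guarantee is impossible otherwise",
        floor, bg_max), class = "metaroutr_config_error")
    }
  }
  n_links <- length(chain) - 1
  genes <- sprintf("PLANTED%02d", seq_len(n_links))
  planted_rx <- tibble::tibble(
    reaction_id = sprintf("PLNT%02d", seq_len(n_links)),
    substrates = as.list(chain[-length(chain)]),
    products = as.list(chain[-1]),
    genes = as.list(genes),
    reversible = FALSE
  )
  n_samples <- ncol(expression) - 1
  planted_expr <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(matrix(floor, nrow = n_links, ncol = n_samples,
                             dimnames = list(NULL, names(expression)[-1])))
  )
  list(
    reactions = dplyr::bind_rows(reactions, planted_rx),
    expression = dplyr::bind_rows(expression, planted_expr),
    chain = chain,
    genes = genes
  )
}

#' Generate a synthetic user cohort
#'
#' Samples genes from a reference weight table and perturbs their means by
#' log-uniform factors spanning both fold-change thresholds, so the
#' resulting cohort contains up-, down- and unregulated genes.
#'
#' @param spec A [fixture_spec()] (its seed, offset, drives the draw).
#' @param weights A `weight_tbl` for the reference cohort.
#' @param n_genes Number of genes to include (capped at the table size).
#' @return A cohort tibble (`gene`, `value`).
#' @export
generate_user_cohort <- function(spec, weights, n_genes = 30) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  n <- min(n_genes, nrow(weights))
  picked <- weights[sample(nrow(weights), n), ]
  factor <- exp(runif(n, log(0.1), log(10)))
  tibble::tibble(gene = picked$gene, value = picked$mean * factor)
}

#' Write a complete fixture instance to a directory
#'
#' Materialises one synthetic instance as the three files a search run
#' consumes — `reactions.csv`, `expression.csv` and `cohort.csv` — optionally
#' with a planted high-expression pathway.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param chain Optional compound chain to plant via [plant_pathway()].
#' @param floor Planted expression level (default 1000, far above the
#'   log-normal background).
#' @return Invisibly, a list of the three file paths (and the planted chain
#'   if any).
#' @export
simulate_fixture <- function(spec, dir, chain = NULL, floor = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reactions <- generate_reaction_table(spec)
  genes <- sort(unique(unlist(reactions$genes)))
  expression <- generate_expression(spec, genes)
  if (!is.null(chain)) {
    planted <- plant_pathway(reactions, expression, chain, floor)
    reactions <- planted$reactions
    expression <- planted$expression
  }
  cohort <- generate_user_cohort(spec, summarize_expression(expression))
  paths <- list(
    reactions = file.path(dir, "reactions.csv"),
    expression = file.path(dir, "expression.csv"),
    cohort = file.path(dir, "cohort.csv")
  )
  write_reaction_table(reactions, paths$reactions)
  write_expression_matrix(expression, paths$expression)
  write_user_cohort(cohort, paths$cohort)
  if (!is.null(chain)) paths$chain <- chain
  invisible(paths)
}
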