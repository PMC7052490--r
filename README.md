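# metaroutr

Expression-weighted metabolic route search in R.

Cancer cells systematically rewire their metabolism (the Warburg effect is
the textbook case), and a recurring question for cancer researchers is:
*given two compounds, which chain of enzymatic reactions most plausibly
connects them in this tissue, according to its gene-expression profile?*
`metaroutr` answers that question for anyone with a reaction table
(a HumanCyc-style export of substrates, products and catalysing genes) and a
gene-expression cohort (e.g. RNA-seq quantifications of tumor samples).

## The model

The metabolic network is a directed graph with **compounds as nodes and
reactions as edges**. Each edge carries the expression of its catalysing
enzyme, summarised over the cohort by a chosen *weight measure*:
the mean, the median, or SV (the standard deviation of the gene's expression
vector). Four rules shape the graph:

1. **Currency exclusion** — ubiquitous compounds (H2O, H+, ATP, ADP, ...)
   are not allowed as intermediates; their hub-like connectivity would create
   meaningless shortcuts. The list is fully overridable per query, because
   cofactors such as coenzyme A or NADH are legitimate route endpoints.
2. **Unexpressed-gene removal** — genes with cohort mean expression < 1 are
   removed and contribute no edges.
3. **One edge per compound pair** — when several reactions or isozymes
   connect the same ordered pair, only the one whose gene has the highest
   *mean* expression is kept.
4. **Direction** — reversible reactions yield both directed edges;
   irreversible ones only the forward edge.

A *route* from start compound *s* to end compound *t* is a simple directed
path `P` of at most *N* reactions (default *N* = 8). All routes are
enumerated by depth-first search and the top *K* (default *K* = 10) are
returned under one of two criteria:

- **bottleneck** (maximised): `score(P) = min_{e ∈ P} w(e)` — the expression
  of the route's rate-limiting enzyme; a max–min (widest-path) objective.
- **stability** (minimised): `score(P) = sd({w(e) : e ∈ P})` — routes whose
  enzymes are expressed at similar levels rank first.

A user cohort (two-column CSV of gene and expression value) can be overlaid:
enzymes with fold change > 2 against the reference mean are flagged **red**
(up-regulated), < 0.5 **green** (down-regulated).

## Worked example

```r
library(metaroutr)

reactions <- tibble::tibble(
  reaction_id = c("R1", "R2", "R3", "R4", "R5"),
  substrates  = list("G6P", "G6P", "F6P", c("F6P", "ATP"), "FBP"),
  products    = list("F6P", "F6P", "FBP", "FBP", "PYR"),
  genes       = list("GPI", "GPI2", "PFKM", "PFKL", "PKM"),
  reversible  = c(TRUE, FALSE, FALSE, FALSE, FALSE))

expr <- tibble::tibble(
  gene = c("GPI", "GPI2", "PFKM", "PFKL", "PKM"),
  t1 = c(12, 3, 8, 15, 20), t2 = c(14, 5, 6, 17, 22), t3 = c(13, 4, 7, 16, 21))

weights <- filter_unexpressed(summarize_expression(expr))
graph   <- build_graph(reactions, weights)
graph
#> <metabolic_graph> 4 compounds, 4 edges (measure: mean, 12 currency compounds excluded)
#> # A tibble: 4 × 6
#>   source target reaction_id gene  weight mean_weight
#>   <chr>  <chr>  <chr>       <chr>  <dbl>       <dbl>
#> 1 F6P    FBP    R4          PFKL      16          16
#> 2 F6P    G6P    R1          GPI       13          13
#> 3 FBP    PYR    R5          PKM       21          21
#> 4 G6P    F6P    R1          GPI       13          13

tidy(find_routes(graph, "G6P", "PYR"))
#> # A tibble: 1 × 5
#>    rank score n_reactions compounds                genes
#>   <int> <dbl>       <int> <chr>                    <chr>
#> 1     1    13           3 G6P -> F6P -> FBP -> PYR GPI;PFKL;PKM
```

Reading the output: the G6P→F6P step had two candidate enzymes (GPI, mean 13
and GPI2, mean 4) — the collapse rule kept GPI. ATP was excluded as a
currency intermediate, so R4 contributes only the F6P→FBP edge. The single
surviving route scores 13 under the bottleneck criterion: its rate-limiting
enzyme is GPI, the least-expressed enzyme on the chain. `glance()` on the
result records the search settings (N = 8, K = 10, criterion, measure).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/metaroutr.R simulate --out-dir demo --seed 1 --plant C001,C005,C009
Rscript inst/cli/metaroutr.R search --reactions demo/reactions.csv \
  --expression demo/expression.csv --start C001 --end C009 \
  --cohort demo/cohort.csv --out demo/routes.csv
```

Subcommands: `stats`, `build`, `search`, `annotate`, `simulate`,
`list-compounds`. Exit codes: 0 success, 2 usage error, 3 validation error.

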