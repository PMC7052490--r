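# Independent double-loop construction oracle over
# (reaction, direction, substrate, product, gene) tuples.
construction_oracle <- function(reactions, weights, currency, measure) {
  wsel <- stats::setNames(weights[[measure]], weights$gene)
  wmean <- stats::setNames(weights$mean, weights$gene)
  rows <- list()
  for (i in seq_len(nrow(reactions))) {
    dirs <- list(c("substrates", "products"))
    if (reactions$reversible[i]) dirs <- c(dirs, list(c("products", "substrates")))
    for (d in dirs) {
      for (s in reactions[[d[1]]][[i]]) for (p in reactions[[d[2]]][[i]]) {
        for (g in reactions$genes[[i]]) {
          if (s %in% currency || p %in% currency || s == p) next
          if (!g %in% names(wsel)) next
          rows[[length(rows) + 1]] <- data.frame(
            source = s, target = p,
            reaction_id = reactions$reaction_id[i], gene = g,
            weight = unname(wsel[g]), mean_weight = unname(wmean[g]))
        }
      }
    }
  }
  cand <- unique(do.call(rbind, rows))
  # per ordered pair keep highest mean, ties by smallest (reaction_id, gene)
  out <- do.call(rbind, lapply(split(cand, paste(cand$source, cand$target)),
    function(grp) {
      grp <- grp[order(-grp$mean_weight, grp$reaction_id, grp$gene), ]
      grp[1, ]
    }))
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

test_that("graph construction applies all four rules on the handcrafted table", {
  g <- audit_graph()
  expect_equal(g$nodes, c("A", "B", "C", "D", "E"))
  expected_edges <- tibble::tibble(
    source = c("A", "B", "C", "D", "E"),
    target = c("B", "C", "D", "E", "D"),
    reaction_id = c("R2", "R3", "R4", "R5", "R5"),
    gene = c("G2", "G3", "G4", "G5", "G5"),
    weight = c(9, 4, 6, 2, 2),
    mean_weight = c(9, 4, 6, 2, 2)
  )
  expect_equal(g$edges, expected_edges)
  # rule-by-rule checks:
  expect_false("ATP" %in% g$nodes)                 # currency excluded
  expect_false("F" %in% g$nodes)                   # sub-threshold gene pruned
  expect_equal(g$edges$gene[g$edges$source == "A"], "G2") # parallel collapse
  expect_true(all(c("D", "E") %in% g$edges$source)) # reversible mirrored
})

test_that("currency intermediates are skipped but retainable", {
  rx <- tibble::tibble(reaction_id = "R1", substrates = list(c("A", "ATP")),
                       products = list("B"), genes = list("G1"),
                       reversible = FALSE)
  w <- summarize_expression(tibble::tibble(gene = "G1", s1 = 7, s2 = 7))
  g <- build_graph(rx, w)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$source, "A")
  expect_equal(g$edges$weight, 7)

  # empty currency set excludes nothing: ATP -> B edge appears too
  g2 <- build_graph(rx, w, currency = character())
  expect_setequal(g2$edges$source, c("A", "ATP"))

  # a retained currency compound stays available as an endpoint
  g3 <- build_graph(rx, w, retain = "ATP")
  expect_true("ATP" %in% g3$nodes)
  expect_true(any(g3$edges$source == "ATP"))
})

test_that("reactions with no surviving gene contribute nothing", {
  rx <- tibble::tibble(reaction_id = c("R1", "R2"),
                       substrates = list("A", "C"), products = list("B", "D"),
                       genes = list("GLOW", character()),
                       reversible = FALSE)
  w <- filter_unexpressed(summarize_expression(
    tibble::tibble(gene = "GLOW", s1 = 0.5, s2 = 0.5)))
  g <- build_graph(rx, w)
  expect_equal(nrow(g$edges), 0)
  expect_equal(length(g$nodes), 0)
})

test_that("random fixtures match the brute-force construction oracle", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed, n_reactions = 40, n_compounds = 20)
    rx <- generate_reaction_table(spec)
    expr <- generate_expression(spec, sort(unique(unlist(rx$genes))))
    w <- filter_unexpressed(summarize_expression(expr))
    for (measure in c("mean", "median", "sv")) {
      g <- build_graph(rx, w, measure = measure)
      oracle <- construction_oracle(rx, w, default_currency_set(), measure)
      expect_equal(g$edges, oracle)
    }
  }
})

test_that("parallel-edge collapse keeps the highest mean with lexicographic ties", {
  cand <- tibble::tibble(
    source = c("A", "A"), target = c("B", "B"),
    reaction_id = c("R1", "R2"), gene = c("G1", "G2"),
    weight = c(3, 9), mean_weight = c(3, 9))
  kept <- collapse_parallel_edges(cand)
  expect_equal(kept$reaction_id, "R2")
  expect_equal(kept$gene, "G2")

  # single candidate per pair: identity (up to canonical sort)
  one <- cand[1, ]
  expect_equal(collapse_parallel_edges(one), one)

  # tie on mean: smallest (reaction_id, gene) wins
  tie <- tibble::tibble(source = "A", target = "B",
                        reaction_id = c("R9", "R2", "R2"),
                        gene = c("GA", "GZ", "GB"),
                        weight = 1, mean_weight = 5)
  expect_equal(collapse_parallel_edges(tie)$reaction_id, "R2")
  expect_equal(collapse_parallel_edges(tie)$gene, "GB")

  # random multiset: retained mean equals the per-pair maximum; idempotent
  set.seed(21)
  rand <- tibble::tibble(
    source = sample(LETTERS[1:4], 60, TRUE),
    target = sample(letters[1:4], 60, TRUE),
    reaction_id = sprintf("R%02d", sample(99, 60, TRUE)),
    gene = sprintf("G%02d", sample(99, 60, TRUE)),
    weight = runif(60), mean_weight = round(runif(60, 1, 5), 1))
  kept <- collapse_parallel_edges(rand)
  maxima <- tapply(rand$mean_weight, paste(rand$source, rand$target), max)
  expect_equal(as.numeric(maxima[paste(kept$source, kept$target)]),
               kept$mean_weight)
  expect_equal(collapse_parallel_edges(kept), kept)
})

test_that("construction is deterministic and independent of row order", {
  spec <- fixture_spec(seed = 17)
  rx <- generate_reaction_table(spec)
  expr <- generate_expression(spec, sort(unique(unlist(rx$genes))))
  w <- filter_unexpressed(summarize_expression(expr))
  g1 <- build_graph(rx, w)
  set.seed(1)
  g2 <- build_graph(rx[sample(nrow(rx)), ], w[sample(nrow(w)), ])
  expect_equal(g1$edges, g2$edges)
  expect_equal(g1$nodes, g2$nodes)
})

test_that("enlarging the currency set never adds nodes or edges", {
  spec <- fixture_spec(seed = 23, n_currency = 0)
  rx <- generate_reaction_table(spec)
  expr <- generate_expression(spec, sort(unique(unlist(rx$genes))))
  w <- filter_unexpressed(summarize_expression(expr))
  g_small <- build_graph(rx, w, currency = character())
  extra <- g_small$nodes[1:3]
  g_big <- build_graph(rx, w, currency = extra)
  expect_true(all(g_big$nodes %in% g_small$nodes))
  key <- function(g) paste(g$edges$source, g$edges$target)
  expect_true(all(key(g_big) %in% key(g_small)))
})

test_that("no isolated nodes survive except explicit retains", {
  spec <- fixture_spec(seed = 29)
  rx <- generate_reaction_table(spec)
  expr <- generate_expression(spec, sort(unique(unlist(rx$genes))))
  w <- filter_unexpressed(summarize_expression(expr))
  g <- build_graph(rx, w)
  expect_setequal(g$nodes, unique(c(g$edges$source, g$edges$target)))
})

test_that("the default currency set names the canonical common compounds", {
  cs <- default_currency_set()
  expect_true(all(c("ATP", "H2O", "H+", "ADP") %in% cs))
  # query-time override: removing coenzyme A makes it searchable
  expect_true("coenzyme A" %in% cs)
  rx <- tibble::tibble(reaction_id = "R1", substrates = list("coenzyme A"),
                       products = list("acetyl-CoA"), genes = list("G1"),
                       reversible = FALSE)
  w <- summarize_expression(tibble::tibble(gene = "G1", s1 = 5, s2 = 5))
  g <- build_graph(rx, w, currency = setdiff(cs, "coenzyme A"))
  expect_equal(nrow(find_routes(g, "coenzyme A", "acetyl-CoA")), 1)
})

test_that("unknown weight measures are a configuration error", {
  w <- summarize_expression(tibble::tibble(gene = "G1", s1 = 5))
  expect_error(build_graph(audit_reactions(), w, measure = "max"),
               class = "metaroutr_config_error")
})
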