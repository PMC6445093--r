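triangle_graph <- function() {
  interaction_graph(data.frame(protein1 = c("A", "B", "C"),
                               protein2 = c("B", "C", "A"),
                               confidence = 900L))
}

test_that("edge merging keeps the best-scored copy and drops self-loops", {
  g <- interaction_graph(data.frame(
    protein1 = c("A", "B", "A", "C"),
    protein2 = c("B", "A", "A", "D"),
    confidence = c(600L, 700L, 999L, 400L)))
  expect_equal(nrow(g$edges), 2) # A-B deduplicated, A-A dropped
  ab <- g$edges[g$edges$protein1 == "A" & g$edges$protein2 == "B", ]
  expect_equal(ab$confidence, 700L)
  expect_error(interaction_graph(data.frame(protein1 = "A", protein2 = "B",
                                            confidence = 1200L)),
               "confidence")
})

test_that("confidence thresholding is strictly greater-than", {
  edges <- data.frame(protein1 = c("A", "C", "E"),
                      protein2 = c("B", "D", "F"),
                      confidence = c(500L, 501L, 499L))
  g <- merge_interaction_edges(edges, min_confidence = 500)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$protein1, "C")
  # curated edges are exempt and carry confidence 1000
  cur <- data.frame(protein1 = "X", protein2 = "Y", confidence = 1L,
                    provenance = "curated")
  g2 <- merge_interaction_edges(rbind(cbind(edges,
                                            provenance = "database"), cur))
  expect_true("X" %in% g2$nodes)
})

test_that("edge files round-trip through write and load", {
  g <- random_test_graph(30, seed = 14, p = 0.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(g, path)
  g2 <- load_and_merge_edges(path, min_confidence = 0)
  expect_equal(g2$edges[c("protein1", "protein2", "confidence")],
               g$edges[c("protein1", "protein2", "confidence")])

  # curated dialect: 2 columns, no scores
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), cpath)
  gc <- load_and_merge_edges(cpath)
  expect_equal(nrow(gc$edges), 2)
  expect_true(all(gc$edges$confidence == 1000L))
  expect_true(all(gc$edges$provenance == "curated"))

  # malformed line reported with its number
  bpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t600", "C\tD"), bpath)
  expect_error(load_and_merge_edges(bpath), "line 2")
  expect_error(load_and_merge_edges("no/such/file.tsv"), "missing")
})

test_that("induced subnetwork reports mapping, isolation and components", {
  g <- triangle_graph()
  sub <- induced_subnetwork(g, c("A", "B", "C", "ZZZ"))
  expect_equal(sub$unmapped, "ZZZ")
  expect_equal(nrow(sub$graph$edges), 3)
  expect_equal(max(sub$components$component), 1)

  expect_warning(out <- induced_subnetwork(g, c("Q1", "Q2")), "no seed")
  expect_length(out$graph$nodes, 0)
  expect_setequal(out$unmapped, c("Q1", "Q2"))

  # random graphs: components match the union-find oracle
  for (seed in 1:20) {
    rg <- random_test_graph(15, seed = seed)
    seeds <- sample(rg$nodes, 8)
    sub <- induced_subnetwork(rg, seeds)
    adj <- bf_adjacency(sub$graph)
    oracle <- bf_components(adj)
    got <- sub$components$component[match(rownames(adj),
                                          sub$components$protein_symbol)]
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(tapply(got, oracle,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("hub selection ranks by distinct seed links and honours exclusion", {
  # candidate H1 touches 3 seeds, H2 touches 1, ALB touches all 4
  edges <- data.frame(
    protein1 = c("H1", "H1", "H1", "H2", "ALB", "ALB", "ALB", "ALB"),
    protein2 = c("S1", "S2", "S3", "S1", "S1", "S2", "S3", "S4"),
    confidence = 900L)
  g <- interaction_graph(edges)
  seeds <- paste0("S", 1:4)
  res <- select_hubs(g, seeds, pools = list(p1 = c("H1", "H2", "ALB")),
                     n_per_pool = 2, exclude = "ALB")
  expect_equal(res$symbol[res$rank == 1], "ALB")
  expect_equal(res$links_to_seed[res$symbol == "ALB"], 4L)
  expect_true(res$excluded[res$symbol == "ALB"])
  expect_false(res$selected[res$symbol == "ALB"])
  expect_setequal(attr(res, "selected"), c("H1", "H2"))
  expect_error(select_hubs(g, seeds, list(p1 = "H1"), n_per_pool = 0),
               "n_per_pool")
})

test_that("hub selection is input-order invariant and matches brute force", {
  set.seed(99)
  rg <- random_test_graph(15, seed = 5, p = 0.35)
  seeds <- rg$nodes[1:6]
  pool <- rg$nodes[7:15]
  res1 <- select_hubs(rg, seeds, list(a = pool), n_per_pool = 2,
                      exclude = character())
  res2 <- select_hubs(rg, seeds, list(a = rev(pool)), n_per_pool = 2,
                      exclude = character())
  expect_identical(res1, res2)

  adj <- bf_adjacency(rg)
  links <- vapply(pool, function(s) sum(adj[s, seeds]), numeric(1))
  ord <- order(-links, pool)
  expect_equal(res1$symbol, pool[ord])
  expect_equal(res1$links_to_seed, as.integer(links[ord]))
  expect_setequal(attr(res1, "selected"), pool[ord][1:2])
})

test_that("topology metrics match closed forms on canonical graphs", {
  tri <- topology_metrics(triangle_graph())
  expect_equal(tri$clustering_coefficient, 1)
  expect_equal(tri$avg_neighbors, 2)
  expect_equal(tri$characteristic_path_length, 1)

  path3 <- interaction_graph(data.frame(protein1 = c("A", "B"),
                                        protein2 = c("B", "C")))
  p <- topology_metrics(path3)
  expect_equal(p$clustering_coefficient, 0)
  expect_equal(p$characteristic_path_length, (1 + 1 + 2) / 3)
  expect_equal(p$avg_neighbors, 2 * 2 / 3)
  expect_error(topology_metrics(interaction_graph(NULL)), "no nodes")
})

test_that("topology, distances and layers match brute-force oracles", {
  for (seed in 1:20) {
    n <- sample(4:15, 1)
    rg <- random_test_graph(n, seed = 100 + seed)
    adj <- bf_adjacency(rg)
    d <- bf_floyd_warshall(adj)
    tm <- topology_metrics(rg)
    off <- d[row(d) != col(d)]
    expect_equal(tm$clustering_coefficient, mean(bf_local_clustering(adj)),
                 tolerance = 1e-12)
    expect_equal(tm$avg_neighbors, mean(rowSums(adj)), tolerance = 1e-12)
    expect_equal(tm$avg_neighbors, 2 * tm$n_edges / tm$n_nodes,
                 tolerance = 1e-12)
    cpl_oracle <- if (any(is.finite(off))) mean(off[is.finite(off)])
                  else NA_real_
    expect_equal(tm$characteristic_path_length, cpl_oracle,
                 tolerance = 1e-12)

    # pairwise step sizes
    pick <- sample(rg$nodes, 3)
    for (a in pick) for (b in pick) {
      expect_equal(regulator_step_size(rg, a, b), d[a, b])
    }

    # layers = multi-source BFS minimum
    tops <- sample(rg$nodes, 2)
    lay <- assign_layers(rg, tops)
    mins <- apply(d[tops, , drop = FALSE], 2, min)
    finite <- is.finite(mins)
    bottom <- if (any(finite)) max(mins[finite]) + 1 else 1
    mins[!finite] <- bottom
    expect_equal(lay$layer[match(names(mins), lay$protein_symbol)],
                 as.integer(mins))
    expect_true(all(lay$layer[lay$protein_symbol %in% tops] == 0))
  }
})

test_that("regulator step size handles self, adjacency and absence", {
  g <- triangle_graph()
  expect_equal(regulator_step_size(g, "A", "A"), 0)
  expect_equal(regulator_step_size(g, "A", "B"), 1)
  expect_error(regulator_step_size(g, "A", "Z"), "Z")
  g2 <- interaction_graph(data.frame(protein1 = "A", protein2 = "B"),
                          nodes = c("A", "B", "LONER"))
  expect_equal(regulator_step_size(g2, "A", "LONER"), Inf)
  lay <- assign_layers(g2, "A")
  expect_equal(lay$layer[lay$protein_symbol == "LONER"], 2L)
  expect_false(lay$reachable[lay$protein_symbol == "LONER"])
  expect_error(assign_layers(g2, character()), "non-empty")
})

test_that("star graph layering puts all leaves at layer 1", {
  star <- interaction_graph(data.frame(protein1 = "HUB",
                                       protein2 = paste0("L", 1:5)))
  lay <- assign_layers(star, "HUB")
  expect_equal(lay$layer[lay$protein_symbol == "HUB"], 0L)
  expect_true(all(lay$layer[lay$protein_symbol != "HUB"] == 1L))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- letters[1:10]
  query <- letters[1:5]
  term <- letters[1:5]

  res <- geneset_enrichment(query, list(t1 = term, t2 = universe,
                                        t3 = letters[6:10]), universe)
  # term == universe -> p = 1; disjoint term -> overlap 0, p = 1
  expect_equal(res$p_value[res$term == "t2"], 1)
  expect_equal(res$overlap[res$term == "t3"], 0)
  expect_equal(res$p_value[res$term == "t3"], 1)

  # enumeration oracle: over all 5-subsets of the universe, the chance of
  # overlap >= observed with the term set
  enum_p <- function(term, obs) {
    combos <- combn(universe, length(query))
    mean(apply(combos, 2, function(s) length(intersect(s, term)) >= obs))
  }
  t1 <- res[res$term == "t1", ]
  expect_equal(t1$overlap, 5)
  expect_equal(t1$p_value, enum_p(term, 5), tolerance = 1e-12)
  expect_equal(t1$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  res2 <- geneset_enrichment(letters[1:5], list(t = letters[3:8]),
                             universe)
  expect_equal(res2$p_value, enum_p(letters[3:8], res2$overlap),
               tolerance = 1e-12)

  # p monotone nonincreasing in overlap for fixed sizes
  ps <- sapply(0:5, function(k) phyper(k - 1, 5, 5, 5, lower.tail = FALSE))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  expect_error(geneset_enrichment(character(), list(t = term), universe),
               "query")
  expect_error(geneset_enrichment(c("zzz"), list(t = term), universe),
               "subset")
})
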