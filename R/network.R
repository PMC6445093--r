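#' Construct an undirected scored interaction graph
#'
#' Canonical container for protein-protein association edges: undirected,
#' no self-loops, no duplicate edges (the highest confidence is retained on
#' merge, with curated provenance winning ties), integer confidence scores
#' on the 0-1000 scale. Isolated nodes are first-class: the node set can be
#' wider than the symbols appearing in edges.
#'
#' @param edges Data frame with columns `protein1`, `protein2`, and
#'   optionally `confidence` (default 1000) and `provenance` (default
#'   `"database"`).
#' @param nodes Optional character vector of additional node symbols.
#' @return An object of class `interaction_graph` with fields `edges`
#'   (tibble) and `nodes` (sorted character vector).
#' @export
interaction_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- tibble(protein1 = character(), protein2 = character(),
                    confidence = integer(), provenance = character())
  }
  edges <- as_tibble(edges)
  assert_cols(edges, c("protein1", "protein2"), "edge table")
  if (!"confidence" %in% names(edges)) edges$confidence <- 1000L
  if (!"provenance" %in% names(edges)) edges$provenance <- "database"
  if (any(is.na(edges$confidence)) ||
      any(edges$confidence < 0 | edges$confidence > 1000) ||
      any(edges$confidence != as.integer(edges$confidence))) {
    abort("edge confidence must be an integer in [0, 1000]")
  }
  edges$confidence <- as.integer(edges$confidence)

  edges <- filter(edges, .data$protein1 != .data$protein2)
  edges <- edges |>
    mutate(a = pmin(.data$protein1, .data$protein2),
           b = pmax(.data$protein1, .data$protein2)) |>
    group_by(.data$a, .data$b) |>
    arrange(dplyr::desc(.data$confidence),
            .data$provenance != "curated", .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    transmute(protein1 = .data$a, protein2 = .data$b,
              confidence = .data$confidence,
              provenance = .data$provenance) |>
    arrange(.data$protein1, .data$protein2)

  nodes <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  structure(list(edges = edges, nodes = nodes), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  deg <- graph_degree(x)
  cat(sprintf("<interaction_graph> %d nodes, %d edges (%d isolated)\n",
              length(x$nodes), nrow(x$edges), sum(deg == 0)))
  invisible(x)
}

#' Convert an interaction graph to igraph
#' @param graph An [interaction_graph()].
#' @return An undirected `igraph` object with a `confidence` edge attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

graph_degree <- function(graph) {
  deg <- setNames(rep(0L, length(graph$nodes)), graph$nodes)
  tab <- table(c(graph$edges$protein1, graph$edges$protein2))
  deg[names(tab)] <- as.integer(tab)
  deg
}

read_edge_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("edge file '%s' is empty", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  start <- 1L
  header <- fields[[1]]
  has_header <- (length(header) >= 3 && is.na(suppressWarnings(
    as.numeric(header[3])))) ||
    (length(header) == 2 && any(tolower(header) %in%
                                  c("protein1", "protein2")))
  if (has_header) start <- 2L
  body <- fields[start:length(fields)]
  if (length(body) == 0) abort(sprintf("edge file '%s' has no data", path))
  width <- ncols[start]
  if (!width %in% c(2L, 3L)) {
    abort(sprintf(
      "unknown edge dialect in '%s': expected 2 (curated) or 3 (scored) columns, found %d",
      path, width))
  }
  bad <- which(ncols[start:length(fields)] != width)
  if (length(bad)) {
    abort(sprintf("malformed line %d in '%s': expected %d fields",
                  bad[1] + start - 1L, path, width))
  }
  p1 <- vapply(body, `[`, character(1), 1)
  p2 <- vapply(body, `[`, character(1), 2)
  if (width == 3L) {
    conf <- suppressWarnings(as.numeric(vapply(body, `[`, character(1), 3)))
    if (anyNA(conf)) {
      abort(sprintf("malformed line %d in '%s': non-numeric confidence",
                    which(is.na(conf))[1] + start - 1L, path))
    }
    tibble(protein1 = p1, protein2 = p2, confidence = as.integer(conf),
           provenance = "database")
  } else {
    tibble(protein1 = p1, protein2 = p2, confidence = 1000L,
           provenance = "curated")
  }
}

#' Load, threshold and merge interaction edge files
#'
#' Reads any mix of scored (3-column: `protein1`, `protein2`,
#' `combined_score` on the 0-1000 scale, optional header) and curated
#' (2-column) tab-separated edge files. Scored edges with confidence at or
#' below `min_confidence` are dropped (strict "greater than"); curated
#' edges are always retained at confidence 1000. The merged graph is
#' deduplicated, keeping the highest confidence per undirected pair.
#'
#' @param files Character vector of file paths.
#' @param min_confidence Strict lower confidence bound for scored edges.
#' @param nodes Optional extra node symbols to keep as isolated nodes.
#' @return An [interaction_graph()].
#' @export
load_and_merge_edges <- function(files, min_confidence = 500, nodes = NULL) {
  stopifnot(length(files) >= 1)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(sprintf("missing edge file: %s", missing[1]))
  }
  edges <- map_dfr(files, read_edge_file)
  merge_interaction_edges(edges, min_confidence = min_confidence,
                          nodes = nodes)
}

#' Threshold and merge in-memory edge tables
#'
#' @param edges Edge tibble (`protein1`, `protein2`, `confidence`,
#'   `provenance`); curated rows are exempt from thresholding.
#' @inheritParams load_and_merge_edges
#' @return An [interaction_graph()].
#' @export
merge_interaction_edges <- function(edges, min_confidence = 500,
                                    nodes = NULL) {
  edges <- as_tibble(edges)
  if (!"provenance" %in% names(edges)) edges$provenance <- "database"
  if (!"confidence" %in% names(edges)) edges$confidence <- 1000L
  keep <- edges$provenance == "curated" | edges$confidence > min_confidence
  interaction_graph(edges[keep, ], nodes = nodes)
}

#' Write an interaction graph as a scored edge TSV
#' @param graph An [interaction_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  readr::write_tsv(graph$edges[c("protein1", "protein2", "confidence")],
                   path)
  invisible(path)
}

#' Induced subnetwork on a seed set
#'
#' Restricts the graph to the seed symbols present in it and reports what a
#' mapping step needs to audit: seeds absent from the interactome, isolated
#' seeds, and the connected components.
#'
#' @param graph An [interaction_graph()].
#' @param seeds Non-empty character vector of seed symbols.
#' @return A list of class `subnetwork`: `graph` (the induced
#'   [interaction_graph()]), `unmapped` seeds, `isolated` nodes, and a
#'   `components` tibble (`protein_symbol`, `component`).
#' @export
induced_subnetwork <- function(graph, seeds) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(seeds) == 0) abort("`seeds` must be non-empty")
  seeds <- unique(seeds)
  present <- intersect(seeds, graph$nodes)
  unmapped <- setdiff(seeds, graph$nodes)
  if (length(present) == 0) {
    warn("no seed symbol maps into the graph")
    sub <- interaction_graph(NULL, nodes = character())
    return(structure(list(graph = sub, unmapped = unmapped,
                          isolated = character(),
                          components = tibble(protein_symbol = character(),
                                              component = integer())),
                     class = "subnetwork"))
  }
  edges <- filter(graph$edges,
                  .data$protein1 %in% present & .data$protein2 %in% present)
  sub <- interaction_graph(edges, nodes = present)
  comp <- igraph::components(as_igraph(sub))
  components <- tibble(protein_symbol = names(comp$membership),
                       component = as.integer(comp$membership))
  deg <- graph_degree(sub)
  structure(list(graph = sub, unmapped = sort(unmapped),
                 isolated = sort(names(deg)[deg == 0]),
                 components = components),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d mapped nodes, %d edges, %d components, %d isolated, %d unmapped seeds\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              max(c(0L, x$components$component)), length(x$isolated),
              length(x$unmapped)))
  invisible(x)
}

#' Rank and select hub proteins by links to a seed set
#'
#' For each candidate pool, candidates are ranked by the number of distinct
#' seed nodes they are adjacent to in the graph (descending, ties broken
#' lexicographically by symbol) and the top `n_per_pool` non-excluded
#' candidates are selected. Excluded symbols (e.g. albumin, whose links
#' reflect depletion chemistry rather than biology) stay in the ranking
#' with their counts and a skip record. Candidates that are themselves
#' seeds are ignored.
#'
#' @param graph An [interaction_graph()].
#' @param seeds Character vector of seed symbols.
#' @param pools Named list of candidate symbol vectors (one element per
#'   pool).
#' @param n_per_pool Number of hubs to select per pool (>= 1).
#' @param exclude Symbols never selected (skips are recorded).
#' @return A tibble: `pool_id`, `symbol`, `links_to_seed`, `rank`,
#'   `excluded`, `selected`; the selected hub symbols are in
#'   `attr(, "selected")`.
#' @export
select_hubs <- function(graph, seeds, pools, n_per_pool = 2,
                        exclude = "ALB") {
  stopifnot(inherits(graph, "interaction_graph"))
  n_per_pool <- assert_count(n_per_pool, "n_per_pool", 1L)
  if (!is.list(pools) || length(pools) == 0) {
    abort("`pools` must be a non-empty list of symbol vectors")
  }
  pool_ids <- names(pools) %||% as.character(seq_along(pools))
  pool_ids[pool_ids == ""] <- as.character(which(pool_ids == ""))
  seeds <- unique(seeds)

  seed_links <- function(sym) {
    e <- graph$edges
    nb <- c(e$protein2[e$protein1 == sym], e$protein1[e$protein2 == sym])
    length(intersect(unique(nb), seeds))
  }

  res <- map_dfr(seq_along(pools), function(i) {
    cand <- setdiff(unique(pools[[i]]), seeds)
    cand <- intersect(cand, graph$nodes)
    if (length(cand) == 0) {
      return(tibble(pool_id = character(), symbol = character(),
                    links_to_seed = integer(), rank = integer(),
                    excluded = logical(), selected = logical()))
    }
    links <- unname(vapply(cand, seed_links, integer(1)))
    tb <- tibble(pool_id = pool_ids[i], symbol = cand,
                 links_to_seed = links) |>
      arrange(dplyr::desc(.data$links_to_seed), .data$symbol) |>
      mutate(rank = dplyr::row_number(),
             excluded = .data$symbol %in% exclude)
    eligible <- which(!tb$excluded)
    tb$selected <- FALSE
    tb$selected[head(eligible, n_per_pool)] <- TRUE
    tb
  })
  attr(res, "selected") <- res$symbol[res$selected]
  res
}

#' Global topology metrics of an interaction graph
#'
#' Mean local clustering coefficient (nodes of degree < 2 contribute 0),
#' average number of neighbors (`2E/N`), and characteristic path length
#' averaged over connected ordered pairs only (isolated nodes would make
#' the all-pairs mean infinite), plus node, edge and isolated-node counts.
#'
#' @param graph A non-empty [interaction_graph()].
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_isolated`,
#'   `clustering_coefficient`, `avg_neighbors`,
#'   `characteristic_path_length` (`NA` when no pair is connected).
#' @export
topology_metrics <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(graph$nodes) == 0) abort("graph has no nodes")
  g <- as_igraph(graph)
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  lc[!is.finite(lc)] <- 0
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  tibble(
    n_nodes = length(graph$nodes),
    n_edges = nrow(graph$edges),
    n_isolated = sum(deg == 0),
    clustering_coefficient = mean(lc),
    avg_neighbors = mean(deg),
    characteristic_path_length = if (length(finite)) mean(finite)
                                 else NA_real_
  )
}

#' Minimal step size between a protein and a regulator
#'
#' Unweighted shortest-path edge count between two symbols; `Inf` when they
#' are in different components.
#'
#' @param graph An [interaction_graph()].
#' @param node,regulator Symbols present in the graph.
#' @return A single number (0 when `node == regulator`; `Inf` if
#'   unreachable).
#' @export
regulator_step_size <- function(graph, node, regulator) {
  stopifnot(inherits(graph, "interaction_graph"))
  for (s in c(node, regulator)) {
    if (!s %in% graph$nodes) abort(sprintf("symbol not in graph: %s", s))
  }
  g <- as_igraph(graph)
  as.numeric(igraph::distances(g, v = node, to = regulator)[1, 1])
}

#' Assign hierarchical layers by distance to top regulators
#'
#' Layer of a node is its minimal step size to any of the top regulator
#' nodes (regulators themselves are layer 0). Nodes unreachable from every
#' regulator are placed in a distinct bottom layer (one past the deepest
#' reachable layer) and flagged.
#'
#' @param graph An [interaction_graph()].
#' @param top_nodes Non-empty regulator symbols, all present in the graph.
#' @return A tibble: `protein_symbol`, `layer`, `reachable`.
#' @export
assign_layers <- function(graph, top_nodes) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(top_nodes) == 0) abort("`top_nodes` must be non-empty")
  absent <- setdiff(top_nodes, graph$nodes)
  if (length(absent)) {
    abort(sprintf("regulator not in graph: %s", absent[1]))
  }
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = top_nodes)
  layer <- apply(d, 2, min)
  reachable <- is.finite(layer)
  bottom <- if (any(reachable)) max(layer[reachable]) + 1 else 1
  layer[!reachable] <- bottom
  tibble(protein_symbol = colnames(d), layer = as.integer(layer),
         reachable = reachable) |>
    arrange(.data$layer, .data$protein_symbol)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query set and
#' each annotation term within a fixed universe, with Benjamini-Hochberg
#' adjustment across terms. `p = P(overlap >= observed)` under random
#' drawing of `|query|` symbols from the universe.
#'
#' @param query Non-empty character vector, a subset of `universe`.
#' @param annotation Named list of term symbol sets (intersected with the
#'   universe).
#' @param universe Non-empty character vector of all testable symbols.
#' @return A tibble ordered by p: `term`, `term_size`, `query_size`,
#'   `overlap`, `p_value`, `q_value`.
#' @export
geneset_enrichment <- function(query, annotation, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (length(query) == 0) abort("`query` must be non-empty")
  if (length(setdiff(query, universe))) {
    abort("`query` must be a subset of `universe`")
  }
  if (!is.list(annotation) || is.null(names(annotation))) {
    abort("`annotation` must be a named list of symbol sets")
  }
  N <- length(universe)
  n <- length(query)
  res <- map_dfr(names(annotation), function(term) {
    set <- intersect(unique(annotation[[term]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    tibble(term = term, term_size = K, query_size = n, overlap = k,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value, .data$term)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT-format annotation file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("reading GMT files requires the 'fgsea' package")
  }
  fgsea::gmtPathways(path)
}
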