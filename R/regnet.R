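#' Construct a RegulatoryNetwork
#'
#' A typed, simple, undirected graph of transcription factors, intermediate
#' proteins and kinases. Edges carry a kind: `"ppi"` (protein interaction)
#' or `"phosphorylation"` (kinase to substrate).
#'
#' @param nodes Data.frame with columns `symbol`, `role` (one of `"tf"`,
#'   `"intermediate"`, `"kinase"`).
#' @param edges Data.frame with columns `from`, `to`, `kind`.
#' @param provenance Identifier of the query signature the network derives
#'   from.
#' @return An object of class `RegulatoryNetwork`.
#' @export
regulatory_network <- function(nodes, edges = NULL, provenance = NA_character_) {
  stopifnot(is.data.frame(nodes), all(c("symbol", "role") %in% names(nodes)))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "kind") %in% names(edges)))
  stopifnot(all(nodes$role %in% c("tf", "intermediate", "kinase")))
  stopifnot(all(edges$kind %in% c("ppi", "phosphorylation")))
  nodes <- nodes[!duplicated(nodes$symbol), , drop = FALSE]
  # canonical order + simplicity
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(from = a[keep], to = b[keep], kind = edges$kind[keep],
                        stringsAsFactors = FALSE)
    bad <- setdiff(c(edges$from, edges$to), nodes$symbol)
    if (length(bad)) stop("edges reference unknown nodes: ",
                          paste(bad, collapse = ", "))
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = c("tf", "intermediate", "kinase")))
  cat(sprintf(
    "RegulatoryNetwork (%s): %d nodes (%d tf, %d intermediate, %d kinase), %d edges\n",
    x$provenance, nrow(x$nodes), tab[["tf"]], tab[["intermediate"]],
    tab[["kinase"]], nrow(x$edges)))
  invisible(x)
}

# igraph view of a network (edge kinds dropped; metrics treat the network
# as one simple undirected graph)
as_igraph <- function(x) {
  if (inherits(x, "PPINetwork")) {
    g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                       vertices = data.frame(name = x$nodes))
  } else if (inherits(x, "RegulatoryNetwork")) {
    g <- igraph::graph_from_data_frame(
      x$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = x$nodes$symbol))
  } else stop("unsupported network object")
  igraph::simplify(g)
}

#' Top regulators from an enrichment table
#'
#' The first `n` term symbols by combined score descending, ties broken
#' lexicographically by term ID. Used to pick the top-10 transcription
#' factors and kinases feeding the regulatory network.
#'
#' @param enrichment Data.frame from [enrich()].
#' @param n Number of regulators (default 10).
#' @return Ordered character vector of term symbols.
#' @export
top_regulators <- function(enrichment, n = 10L) {
  if (n < 1) stop("n must be >= 1")
  if (!nrow(enrichment)) return(character())
  key <- if (all(is.na(enrichment$combined_score))) -enrichment$p else
    enrichment$combined_score
  ord <- order(-key, enrichment$term)
  head(enrichment$term[ord], n)
}

#' Expand seed regulators into a PPI subnetwork
#'
#' Genes2Networks-style expansion: the subnetwork consists of the seed
#' proteins plus every non-seed protein lying on any shortest path of length
#' at most `max_path_length` between two distinct seeds in the background
#' PPI; all background edges induced on these nodes are retained. Seeds are
#' labelled `tf`, added connectors `intermediate`; seeds absent from the PPI
#' are kept as isolated `tf` nodes.
#'
#' @param seeds Character vector of seed symbols (e.g. enriched TFs).
#' @param ppi A `PPINetwork` background.
#' @param max_path_length Maximum seed-to-seed shortest-path length through
#'   which connectors are collected; one of 1, 2, 3 (default 2).
#' @param provenance Optional provenance string stored on the network.
#' @return A `RegulatoryNetwork` of `tf` and `intermediate` nodes with
#'   `ppi` edges.
#' @export
g2n_expand <- function(seeds, ppi, max_path_length = 2L,
                       provenance = NA_character_) {
  stopifnot(inherits(ppi, "PPINetwork"))
  if (!length(seeds)) stop("seeds must be non-empty")
  if (!max_path_length %in% 1:3) stop("max_path_length must be 1, 2 or 3")
  seeds <- unique(toupper(seeds))
  g <- as_igraph(ppi)
  present <- intersect(seeds, igraph::V(g)$name)

  connectors <- character()
  if (length(present) >= 2) {
    D <- igraph::distances(g, v = present, to = present)
    for (i in seq_len(length(present) - 1)) {
      for (j in seq(i + 1, length(present))) {
        d <- D[i, j]
        if (is.finite(d) && d >= 2 && d <= max_path_length) {
          paths <- igraph::all_shortest_paths(
            g, from = present[i], to = present[j])$vpaths
          inner <- unlist(lapply(paths, function(p) {
            nm <- igraph::V(g)$name[as.integer(p)]
            nm[-c(1, length(nm))]
          }))
          connectors <- c(connectors, inner)
        }
      }
    }
  }
  connectors <- setdiff(unique(connectors), seeds)
  keep_nodes <- c(present, connectors)
  edges <- ppi$edges[ppi$edges$from %in% keep_nodes &
                       ppi$edges$to %in% keep_nodes, , drop = FALSE]
  nodes <- data.frame(
    symbol = c(seeds, connectors),
    role = c(rep("tf", length(seeds)), rep("intermediate", length(connectors))),
    stringsAsFactors = FALSE)
  edges$kind <- rep("ppi", nrow(edges))
  regulatory_network(nodes, edges, provenance = provenance)
}

#' Kinase enrichment and attachment
#'
#' Runs over-representation of the network's node symbols against a
#' kinase-substrate library, takes the top `n` kinases by combined score and
#' attaches each as a `kinase` node with `phosphorylation` edges to its
#' substrate proteins already present in the network. The kinase enrichment
#' table is stored in `attr(, "kinase_enrichment")`.
#'
#' @param network A `RegulatoryNetwork` with at least one node.
#' @param kinase_library `GeneSetLibrary` of kinase -> substrates terms.
#' @param universe Gene universe for the enrichment.
#' @param null_model Optional `NullRankModel` for the kinase library.
#' @param n Number of kinases to attach (default 10).
#' @return The augmented `RegulatoryNetwork`.
#' @export
kinase_enrich_and_attach <- function(network, kinase_library, universe,
                                     null_model = NULL, n = 10L) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  if (!length(kinase_library$terms)) stop("kinase library is empty")
  if (!nrow(network$nodes)) stop("network has no nodes")
  base_symbols <- network$nodes$symbol
  query <- intersect(base_symbols, toupper(universe))
  if (!length(query)) {
    warning("no network node lies in the universe; network unchanged")
    return(network)
  }
  enr <- suppressWarnings(enrich(query, kinase_library, universe, null_model))
  if (!nrow(enr)) {
    warning("no kinase term overlaps the network; network unchanged")
    return(network)
  }
  kinases <- top_regulators(enr, n)
  nodes <- network$nodes; edges <- network$edges
  for (kin in kinases) {
    substrates <- setdiff(intersect(kinase_library$terms[[kin]], base_symbols), kin)
    if (kin %in% nodes$symbol) {
      nodes$role[nodes$symbol == kin] <- "kinase"
    } else {
      nodes <- rbind(nodes, data.frame(symbol = kin, role = "kinase",
                                       stringsAsFactors = FALSE))
    }
    if (length(substrates))
      edges <- rbind(edges, data.frame(from = kin, to = substrates,
                                       kind = "phosphorylation",
                                       stringsAsFactors = FALSE))
  }
  out <- regulatory_network(nodes, edges, provenance = network$provenance)
  attr(out, "kinase_enrichment") <- enr
  out
}

#' Betweenness centrality
#'
#' For each node N, the sum over unordered node pairs (s, t), with s, t
#' distinct from N, of the fraction of shortest s-t paths passing through N.
#' Unnormalized, endpoints excluded, undirected; disconnected pairs
#' contribute zero. Edge kinds are ignored.
#'
#' @param network A `RegulatoryNetwork` or `PPINetwork`.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness <- function(network) {
  g <- as_igraph(network)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' k-core decomposition
#'
#' The core number of a node: the largest k such that the node belongs to a
#' maximal subgraph in which every node has degree at least k (standard
#' iterative peeling). Edge kinds are ignored.
#'
#' @param network A `RegulatoryNetwork` or `PPINetwork`.
#' @return Named integer vector of core numbers.
#' @export
kcore <- function(network) {
  g <- as_igraph(network)
  igraph::coreness(g)
}

#' Topology table for hub detection
#'
#' Per-node degree, betweenness and k-core number, with an `is_hub` flag
#' (all `FALSE` until [select_hubs()] is applied).
#'
#' @param network A `RegulatoryNetwork`.
#' @return A data.frame with columns `symbol`, `role`, `degree`,
#'   `betweenness`, `kcore`, `is_hub`.
#' @export
hub_table <- function(network) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  core <- igraph::coreness(g)
  idx <- match(network$nodes$symbol, names(deg))
  data.frame(symbol = network$nodes$symbol, role = network$nodes$role,
             degree = as.integer(deg[idx]), betweenness = as.numeric(btw[idx]),
             kcore = as.integer(core[idx]), is_hub = FALSE,
             stringsAsFactors = FALSE)
}

#' Select hub proteins
#'
#' Nodes are ranked by k-core number descending (the most centralized
#' shells), ties broken by betweenness, then degree, then symbol; the top
#' `top_k` are flagged as hubs.
#'
#' @param hub_table Data.frame from [hub_table()].
#' @param top_k Number of hubs to select (>= 1).
#' @return The hub table, re-ranked, with `is_hub` set on the first `top_k`
#'   rows; the ordered hub symbols are in `attr(, "hubs")`.
#' @export
select_hubs <- function(hub_table, top_k) {
  if (top_k < 1) stop("top_k must be >= 1")
  ord <- order(-hub_table$kcore, -hub_table$betweenness,
               -hub_table$degree, hub_table$symbol)
  out <- hub_table[ord, , drop = FALSE]
  out$is_hub <- seq_len(nrow(out)) <= top_k
  rownames(out) <- NULL
  attr(out, "hubs") <- out$symbol[out$is_hub]
  out
}

#' Export a network as SIF and GraphML
#'
#' @param network A `RegulatoryNetwork`.
#' @param sif_path,graphml_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, sif_path = NULL, graphml_path = NULL) {
  written <- character()
  if (!is.null(sif_path)) {
    lines <- if (nrow(network$edges)) {
      kind_tag <- ifelse(network$edges$kind == "phosphorylation", "ph", "pp")
      paste(network$edges$from, kind_tag, network$edges$to, sep = "\t")
    } else character()
    isolated <- setdiff(network$nodes$symbol,
                        c(network$edges$from, network$edges$to))
    writeLines(c(lines, isolated), sif_path)
    written <- c(written, sif_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = network$nodes[, c("symbol", "role"), drop = FALSE])
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
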