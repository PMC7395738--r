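# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive pure R, sharing no code path with
# the package implementations it cross-checks.

# exact upper-tail hypergeometric by complete enumeration of all
# choose(universe, query) draws; feasible for universe <= 12
oracle_hypergeom <- function(k, query_size, term_size, universe_size) {
  genes <- seq_len(universe_size)
  term <- seq_len(term_size)
  draws <- utils::combn(universe_size, query_size)
  hits <- apply(draws, 2, function(q) sum(q %in% term) >= k)
  mean(hits)
}

# adjacency matrix of a RegulatoryNetwork / PPINetwork / edge data.frame
adj_matrix <- function(edges, nodes) {
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    A[cbind(edges$from, edges$to)] <- 1L
    A[cbind(edges$to, edges$from)] <- 1L
  }
  A
}

# BFS single-source distances on an adjacency matrix
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(A[v, ] == 1L & is.infinite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# all simple paths from s to t of exactly length `len`, by DFS
enum_paths <- function(A, s, t, len) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) - 1 > len) return()
    if (v == t) {
      if (length(path) - 1 == len) paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(A[v, ] == 1L)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

# unnormalized betweenness, endpoints excluded, by enumerating every
# shortest path of every node pair
oracle_betweenness <- function(edges, nodes) {
  A <- adj_matrix(edges, nodes)
  n <- length(nodes)
  btw <- setNames(rep(0, n), nodes)
  if (n < 3) return(btw)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(A, s)
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[t]) || d[t] == 0) next
      paths <- enum_paths(A, s, t, d[t])
      sigma <- length(paths)
      if (sigma == 0) next
      for (p in paths) {
        inner <- p[-c(1, length(p))]
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  btw
}

# core numbers by direct peeling: for each k remove nodes of degree < k
# until stable; a node's core is the largest k it survives
oracle_kcore <- function(edges, nodes) {
  A <- adj_matrix(edges, nodes)
  core <- setNames(rep(0L, length(nodes)), nodes)
  for (k in seq_len(length(nodes))) {
    keep <- rep(TRUE, length(nodes))
    repeat {
      deg <- rowSums(A[keep, keep, drop = FALSE])
      drop <- names(deg)[deg < k]
      if (!length(drop)) break
      keep[match(drop, nodes)] <- FALSE
      if (!any(keep)) break
    }
    if (!any(keep)) break
    core[keep] <- k
  }
  core
}

# direct full gene-space CD solve: b ~ (gamma * S + (1 - gamma) * nu * I)^-1 d
oracle_cd <- function(study, gamma) {
  case <- study$values[, study$case_samples, drop = FALSE]
  ctrl <- study$values[, study$control_samples, drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  Sc <- (case - rowMeans(case)) %*% t(case - rowMeans(case))
  Sg <- (ctrl - rowMeans(ctrl)) %*% t(ctrl - rowMeans(ctrl))
  S <- (Sc + Sg) / (n1 + n2 - 2)
  nu <- mean(diag(S))
  d <- rowMeans(case) - rowMeans(ctrl)
  b <- solve(gamma * S + (1 - gamma) * nu * diag(nrow(S)), d)
  b <- b / sqrt(sum(b^2))
  up <- which(d > 0)
  anchor <- if (length(up)) up[which.max(abs(b[up]))] else which.max(abs(b))
  tsign <- if (length(up)) 1 else sign(d[anchor])
  if (sign(b[anchor]) != 0 && sign(b[anchor]) != tsign) b <- -b
  setNames(b, rownames(study$values))
}

# fixture builders ----------------------------------------------------------

random_study <- function(n_genes, n_case, n_ctrl, seed, shift_genes = NULL,
                         shift = 0, category = "cancer_vs_normal") {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  X <- matrix(rnorm(n_genes * (n_case + n_ctrl), 8, 1), n_genes,
              dimnames = list(genes,
                              c(paste0("c", seq_len(n_case)),
                                paste0("n", seq_len(n_ctrl)))))
  if (!is.null(shift_genes))
    X[shift_genes, seq_len(n_case)] <- X[shift_genes, seq_len(n_case)] + shift
  expression_study(paste0("rnd", seed), X,
                   case_samples = paste0("c", seq_len(n_case)),
                   control_samples = paste0("n", seq_len(n_ctrl)),
                   category = category)
}

make_sig <- function(study_id, up, down, category = "cancer_vs_normal") {
  scores <- c(setNames(seq(1, 0.5, length.out = max(1, length(up)))[seq_along(up)], up),
              setNames(-seq(1, 0.5, length.out = max(1, length(down)))[seq_along(down)], down))
  structure(list(study_id = study_id, up_genes = up, down_genes = down,
                 scores = scores, category = category,
                 cutoff = length(up) + length(down)),
            class = "GeneSignature")
}

random_edge_graph <- function(n_nodes, p, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}

as_regnet <- function(edges, nodes) {
  regulatory_network(
    data.frame(symbol = nodes, role = "intermediate", stringsAsFactors = FALSE),
    if (nrow(edges)) cbind(edges, kind = "ppi") else NULL)
}
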