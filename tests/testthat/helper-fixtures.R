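# shared fixtures and independent oracles

# random symmetric binary adjacency, no self-loops
rand_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[sample(ut, rbinom(1, length(ut), p))] <- 1L
  A + t(A)
}

# identity matrix whose thresholded graph at sigma in (lo, hi) equals A
adjacency_identity <- function(A, hi = 80, lo = 20, layer = "L1") {
  m <- ifelse(A > 0, hi, lo)
  diag(m) <- 100
  dimnames(m) <- list(paste0("o", seq_len(nrow(A))), paste0("o", seq_len(nrow(A))))
  identity_matrix(m, layer)
}

# brute-force all-pairs shortest-path lengths by plain BFS (no igraph)
bf_distances <- function(A, cap = nrow(A)) {
  n <- nrow(A)
  D <- matrix(cap, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, dist >= 0] <- dist[dist >= 0]
  }
  D
}

# brute-force edge betweenness: enumerate every shortest path of every
# unordered pair and split the pair's unit weight evenly across them
bf_edge_betweenness <- function(A) {
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  score <- setNames(rep(0, nrow(el)), key)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths
      )
      if (length(paths) == 0) next
      for (p in paths) {
        v <- as.integer(p)
        if (length(v) < 2) next
        for (i in seq_len(length(v) - 1)) {
          k <- paste(min(v[i], v[i + 1]), max(v[i], v[i + 1]))
          score[k] <- score[k] + 1 / length(paths)
        }
      }
    }
  }
  list(edges = el, score = unname(score), key = key)
}

# classical single-layer Girvan-Newman with the package's tie-break
# (smaller endpoint, then larger endpoint), via igraph betweenness --
# an implementation independent of the package's removal loop
reference_ng <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  removals <- list()
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g)
    el <- igraph::as_edgelist(g)
    o <- order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[o, , drop = FALSE]
    eb <- eb[o]
    best <- max(eb)
    pick <- which(eb >= best - 1e-9 * max(1, best))[1]
    removals[[length(removals) + 1]] <-
      c(min(el[pick, ]), max(el[pick, ]))
    g <- igraph::delete_edges(
      g,
      igraph::get_edge_ids(g, c(el[pick, 1], el[pick, 2]))
    )
  }
  do.call(rbind, removals)
}

# single-layer multiplex from an adjacency matrix
single_layer_multiplex <- function(A, sigma = 50) {
  build_multiplex(list(threshold_graph(adjacency_identity(A), sigma)))
}

# does a partition recover the planted blocks exactly?
recovers_blocks <- function(partition, blocks) {
  labs <- partition$community[match(names(blocks), partition$organism)]
  all(vapply(
    split(labs, blocks),
    function(x) length(unique(x)) == 1, logical(1)
  )) &&
    dplyr::n_distinct(labs) == dplyr::n_distinct(blocks)
}
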