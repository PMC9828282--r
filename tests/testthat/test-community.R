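test_that("edge betweenness matches hand counts and the brute-force oracle", {
  # path a-b-c: each edge carries 2 pair-paths
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  eb <- multiplex_edge_betweenness(single_layer_multiplex(P))
  expect_equal(eb$betweenness, c(2, 2))

  # two triangles joined by one bridge: the bridge is the unique maximum
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  eb2 <- multiplex_edge_betweenness(single_layer_multiplex(A))
  bridge <- eb2$from == 3 & eb2$to == 4
  expect_true(all(eb2$betweenness[bridge] > eb2$betweenness[!bridge]))

  # edgeless multiplex: empty score table
  E0 <- matrix(0, 3, 3)
  eb0 <- multiplex_edge_betweenness(single_layer_multiplex(E0))
  expect_equal(nrow(eb0), 0L)

  # random graphs vs explicit shortest-path enumeration
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    A <- rand_adjacency(n, 0.45)
    if (sum(A) == 0) next
    mine <- multiplex_edge_betweenness(single_layer_multiplex(A))
    oracle <- bf_edge_betweenness(A)
    key_m <- paste(mine$from, mine$to)
    key_o <- oracle$key
    expect_equal(mine$betweenness, oracle$score[match(key_m, key_o)],
      tolerance = 1e-9
    )
  }
})

test_that("single-layer modularity satisfies the closed-form anchor cases", {
  set.seed(62)
  # one-community partition of any graph: exactly 0
  for (rep in 1:6) {
    A <- rand_adjacency(sample(4:10, 1), 0.5)
    expect_equal(modularity_single(A, rep(1, nrow(A))), 0, tolerance = 1e-12)
  }
  # two disjoint triangles, partitioned correctly: 0.5
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  expect_equal(modularity_single(A, c(1, 1, 1, 2, 2, 2)), 0.5)
  # singleton partition: -sum_c (d_c / 2m)^2 < 0
  m <- sum(A) / 2
  expect_equal(
    modularity_single(A, 1:6),
    -sum((rowSums(A) / (2 * m))^2)
  )
  expect_lt(modularity_single(A, 1:6), 0)
  # edgeless graph: 0 by convention
  expect_equal(modularity_single(matrix(0, 3, 3), rep(1, 3)), 0)
  # cross-check against igraph on random graphs and partitions
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    A <- rand_adjacency(n, 0.5)
    if (sum(A) == 0) next
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, "undirected")
    expect_equal(modularity_single(A, memb),
      igraph::modularity(g, memb),
      tolerance = 1e-12
    )
  }
})

test_that("multilayer modularity reduces to the single-layer form at L = 1", {
  set.seed(63)
  for (rep in 1:6) {
    n <- sample(4:9, 1)
    A <- rand_adjacency(n, 0.5)
    if (sum(A) == 0) next
    M <- single_layer_multiplex(A)
    memb <- sample(1:3, n, replace = TRUE)
    expect_lt(
      abs(modularity_multiplex(M, memb) - modularity_single(A, memb)),
      1e-12
    )
  }
})

test_that("multilayer modularity equals an independent term-by-term summation", {
  # explicit double sum over (i, j, alpha, beta) on small multiplexes
  brute_q <- function(M, memb, gamma = 1, omega = 1) {
    n <- M$n
    L <- M$L
    total <- 0
    two_mu <- omega * n * L * (L - 1)
    for (a in seq_len(L)) two_mu <- two_mu + sum(M$adjacency[[a]])
    for (a in seq_len(L)) {
      A <- M$adjacency[[a]]
      m_a <- sum(A) / 2
      k <- unname(rowSums(A))
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (memb[i] != memb[j]) next
          null <- if (m_a > 0) gamma * k[i] * k[j] / (2 * m_a) else 0
          total <- total + A[i, j] - null
        }
      }
    }
    for (i in seq_len(n)) total <- total + omega * L * (L - 1) # delta_ij couplings
    total / two_mu
  }
  set.seed(64)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    L <- sample(2:3, 1)
    layers <- lapply(seq_len(L), function(a) {
      threshold_graph(
        adjacency_identity(rand_adjacency(n, 0.5), layer = paste0("L", a)), 50
      )
    })
    M <- build_multiplex(layers)
    for (memb in list(rep(1, n), seq_len(n), sample(1:2, n, replace = TRUE))) {
      expect_equal(modularity_multiplex(M, memb), brute_q(M, memb),
        tolerance = 1e-12
      )
    }
  }
  # two identical layers, planted two blocks: hand-expanded formula
  blocks <- rep(c(1, 2), each = 3)
  A <- outer(blocks, blocks, "==") * 1 - diag(6)
  layers <- lapply(1:2, function(a) {
    threshold_graph(adjacency_identity(A, layer = paste0("L", a)), 50)
  })
  M2 <- build_multiplex(layers)
  # per layer: sum_in A = 12, null = 2 * (9 * 36) / (2 * 6) ... expanded below
  m_a <- 6
  k <- rowSums(A)
  null_c <- 2 * sum(vapply(
    1:2,
    function(cc) sum(k[blocks == cc])^2, numeric(1)
  )) / (2 * m_a)
  two_mu <- 2 * 2 * m_a + 6 * 2 * 1
  expect_equal(
    modularity_multiplex(M2, blocks),
    (2 * 12 - null_c + 6 * 2 * 1) / two_mu
  )
})

test_that("multing at L = 1 reproduces classical Girvan-Newman removals", {
  set.seed(65)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    A <- rand_adjacency(n, 0.4)
    if (sum(A) == 0) next
    M <- single_layer_multiplex(A)
    tr <- multing(M)
    ref <- reference_ng(A)
    expect_equal(nrow(tr$steps), nrow(ref))
    expect_equal(cbind(tr$steps$from, tr$steps$to), ref, ignore_attr = TRUE)
    # community count along the trace is non-decreasing
    expect_true(all(diff(tr$steps$n_communities) >= 0))
    expect_true(tr$completed)
  }
})

test_that("multing removes cross-community bridges first on a 2-layer multiplex", {
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  layers <- lapply(1:2, function(a) {
    threshold_graph(adjacency_identity(A, layer = paste0("L", a)), 50)
  })
  tr <- multing(build_multiplex(layers))
  # first two removals are the two bridges; counts go 1 -> 1 -> 2
  expect_equal(tr$steps$from[1:2], c(3, 3))
  expect_equal(tr$steps$to[1:2], c(4, 4))
  expect_equal(tr$steps$n_communities[1:2], c(1L, 2L))
  # max-Q partition is the two triangles
  p <- best_partition(tr, "max_Q")
  expect_equal(dplyr::n_distinct(p$community), 2L)
  expect_equal(p$community[1:3], rep(p$community[1], 3))
  expect_equal(p$community[4:6], rep(p$community[4], 3))
})

test_that("partition selection strategies walk the trace correctly", {
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  tr <- multing(single_layer_multiplex(A))
  # before the first event: the single-community partition
  p0 <- best_partition(tr, "before_event", k = 1)
  expect_equal(dplyr::n_distinct(p0$community), 1L)
  # first partition with 2 communities
  p2 <- best_partition(tr, "at_community_count", c = 2)
  expect_equal(dplyr::n_distinct(p2$community), 2L)
  # group_split: partition at the branch-out of the first triangle
  pg <- best_partition(tr, "group_split", group = paste0("o", 1:3))
  labs <- pg$community[1:3]
  expect_equal(length(unique(labs)), 1L)
  expect_false(any(pg$community[4:6] == labs[1]))
  # modularity attribute matches a recomputation
  expect_equal(
    attr(pg, "modularity"),
    modularity_multiplex(tr$multiplex, pg$community)
  )
  # unreachable community count
  expect_error(best_partition(tr, "at_community_count", c = 99),
    class = "multipsn_selection_error"
  )
})
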