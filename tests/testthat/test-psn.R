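test_that("thresholding is inclusive, bounded and respects presence", {
  ids <- c("A", "B", "C")
  m <- matrix(c(100, 64, 63.5, 64, 100, 64, 63.5, 64, 100), 3, 3,
    dimnames = list(ids, ids)
  )
  W <- identity_matrix(m)
  G <- threshold_graph(W, 64)
  expect_equal(G$adjacency["A", "B"], 1L) # w = 64, sigma = 64: inclusive
  expect_equal(G$adjacency["A", "C"], 0L) # w = 63.5 < 64
  expect_equal(unname(diag(G$adjacency)), rep(0L, 3))

  # sigma = 0 connects every present pair
  G0 <- threshold_graph(W, 0)
  expect_equal(sum(G0$adjacency), 3L * 2L)

  expect_error(threshold_graph(W, 101), class = "multipsn_domain_error")

  # absent organisms get no edges at any sigma
  m2 <- m
  m2["C", ] <- 0
  m2[, "C"] <- 0
  GA <- threshold_graph(identity_matrix(m2), 0)
  expect_equal(sum(GA$adjacency["C", ]), 0L)
})

test_that("the threshold family has 101 nested networks", {
  set.seed(21)
  W <- adjacency_identity(rand_adjacency(8), hi = 70, lo = 35)
  fam <- threshold_family(W)
  expect_length(fam, 101L)
  for (k in seq_len(100)) {
    hi <- fam[[k + 1]]$adjacency
    lo <- fam[[k]]$adjacency
    expect_true(all(hi <= lo)) # edges(sigma2) subset of edges(sigma1)
  }
  # constant matrix: identical complete graphs at every sigma below the level
  mc <- matrix(100, 4, 4)
  Wc <- identity_matrix(mc)
  famc <- threshold_family(Wc)
  expect_true(all(vapply(
    famc,
    function(G) sum(G$adjacency) == 12, logical(1)
  )))
})

test_that("neighborhood orders match brute-force BFS with the cap rule", {
  # path a-b-c: order(a, c) = 2
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  G <- threshold_graph(adjacency_identity(A), 50)
  D <- neighborhood_matrix(G)
  expect_equal(D[1, 3], 2)

  # isolated node: order n to everyone
  A2 <- rbind(cbind(A, 0), 0)
  G2 <- threshold_graph(adjacency_identity(A2), 50)
  expect_equal(unname(neighborhood_matrix(G2)[4, 1:3]), rep(4, 3))

  # complete graph: all off-diagonal orders 1
  A3 <- matrix(1, 4, 4) - diag(4)
  D3 <- neighborhood_matrix(threshold_graph(adjacency_identity(A3), 50))
  expect_true(all(D3[upper.tri(D3)] == 1))

  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    A <- rand_adjacency(n, 0.35)
    D <- neighborhood_matrix(threshold_graph(adjacency_identity(A), 50))
    expect_equal(D, bf_distances(A), ignore_attr = TRUE)
  }
})

test_that("dissimilarity is a symmetric non-negative divergence", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    G1 <- threshold_graph(adjacency_identity(rand_adjacency(n)), 50)
    G2 <- threshold_graph(adjacency_identity(rand_adjacency(n)), 50)
    expect_equal(dissimilarity(G1, G1), 0)
    d12 <- dissimilarity(G1, G2)
    expect_gte(d12, 0)
    expect_equal(d12, dissimilarity(G2, G1))
    # agrees with the brute-force oracle formula
    D1 <- bf_distances(igraph::as_adjacency_matrix(
      igraph::graph_from_adjacency_matrix(G1$adjacency, "undirected"),
      sparse = FALSE
    ))
    D2 <- bf_distances(G2$adjacency)
    expect_equal(d12, sum(abs(D1 - D2)) / (n * (n - 1)))
  }

  # K3 vs path: hand-checkable via brute force
  K3 <- matrix(1, 3, 3) - diag(3)
  P3 <- K3
  P3[1, 3] <- P3[3, 1] <- 0
  GK <- threshold_graph(adjacency_identity(K3), 50)
  GP <- threshold_graph(adjacency_identity(P3), 50)
  expect_equal(
    dissimilarity(GK, GP),
    sum(abs(bf_distances(K3) - bf_distances(P3))) / 6
  )

  # mismatched organism sets
  G4 <- threshold_graph(adjacency_identity(rand_adjacency(4)), 50)
  G5 <- threshold_graph(adjacency_identity(rand_adjacency(5)), 50)
  expect_error(dissimilarity(G4, G5), class = "multipsn_input_error")
})

test_that("dissimilarity profiles locate the transitions of block matrices", {
  # constant 80 off-diagonal: a single spike where the complete graph dies
  n <- 6
  m <- matrix(80, n, n)
  diag(m) <- 100
  prof <- dissimilarity_profile(identity_matrix(m))
  expect_equal(prof$delta[prof$sigma == 80], n - 1) # complete -> empty: all orders 1 -> n
  expect_equal(sum(prof$delta > 0), 1L)
  expect_equal(profile_peaks(prof), 80)

  # all-zero off-diagonal: since w = 0 >= sigma = 0 (inclusive rule), the
  # sigma = 0 network is complete and dies at sigma = 1; flat zero after
  m0 <- diag(100, 4)
  prof0 <- dissimilarity_profile(identity_matrix(m0))
  expect_equal(prof0$delta[prof0$sigma == 0], 3)
  expect_true(all(prof0$delta[prof0$sigma > 0] == 0))
  expect_length(profile_peaks(prof0), 0L) # grid endpoint is not a peak

  # two blocks (within 90, between 40): peaks at the two crossings
  blocks <- rep(c(1, 2), each = 4)
  m2 <- outer(blocks, blocks, function(a, b) ifelse(a == b, 90, 40))
  diag(m2) <- 100
  prof2 <- dissimilarity_profile(identity_matrix(m2))
  expect_setequal(profile_peaks(prof2), c(40, 90))
})

test_that("threshold selection modes behave as specified", {
  expect_equal(
    select_threshold(structure(tibble::tibble(), class = "dissimilarity_profile"),
      mode = "manual", value = 64
    ),
    64
  )

  blocks <- rep(c(1, 2), each = 4)
  m2 <- outer(blocks, blocks, function(a, b) ifelse(a == b, 90, 40))
  diag(m2) <- 100
  ids <- paste0("o", 1:8)
  dimnames(m2) <- list(ids, ids)
  W <- identity_matrix(m2)
  prof <- dissimilarity_profile(W)
  # probe = block 1: the peak immediately preceding block separation
  expect_equal(
    select_threshold(prof,
      mode = "split_guided", W = W,
      probe = ids[blocks == 1]
    ),
    40
  )
  # max_peak: the largest delta wins (here the between-level collapse,
  # where 32 ordered pairs jump from order 1 to the cap n = 8)
  expect_equal(select_threshold(prof, mode = "max_peak"), 40)

  # no peaks -> selection error with a diagnostic
  prof0 <- dissimilarity_profile(identity_matrix(diag(100, 4)))
  expect_error(select_threshold(prof0, mode = "max_peak"),
    class = "multipsn_selection_error"
  )
})
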