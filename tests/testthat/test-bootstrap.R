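two_block_matrices <- function(n1 = 4, n2 = 4, L = 2, within = 90, between = 30) {
  blocks <- rep(c(1, 2), c(n1, n2))
  m <- outer(blocks, blocks, function(a, b) ifelse(a == b, within, between))
  diag(m) <- 100
  ids <- paste0("o", seq_along(blocks))
  dimnames(m) <- list(ids, ids)
  lapply(seq_len(L), function(a) identity_matrix(m, paste0("L", a)))
}

test_that("binomial resampling fixes the bounds and matches binomial moments", {
  m <- matrix(c(100, 100, 0, 100, 100, 50, 0, 50, 100), 3, 3)
  diag(m) <- 100
  W <- identity_matrix(m)
  set.seed(81)
  for (rep in 1:5) {
    R <- resample_matrix(W, Y = 50)
    expect_equal(R[1, 2], 100) # p = 1: always 100
    expect_equal(R[1, 3], 0) # p = 0: always 0
    expect_true(isSymmetric(unclass(R)))
    expect_equal(unname(diag(unclass(R))), rep(100, 3))
  }

  # w = 50, Y = 200: mean 50, variance 100^2 * 0.25 / 200 = 12.5,
  # checked within 3 standard errors over 10,000 draws
  Y <- 200
  n_draws <- 10000
  m2 <- matrix(c(100, 50, 50, 100), 2, 2)
  W2 <- identity_matrix(m2)
  set.seed(82)
  draws <- vapply(
    seq_len(n_draws),
    function(i) resample_matrix(W2, Y)[1, 2], numeric(1)
  )
  se_mean <- sqrt(12.5 / n_draws)
  expect_lt(abs(mean(draws) - 50), 3 * se_mean)
  se_var <- 12.5 * sqrt(2 / (n_draws - 1))
  expect_lt(abs(var(draws) - 12.5), 3 * se_var)

  # variance shrinks toward the bounds, as for strongly similar sequences
  W3 <- identity_matrix(matrix(c(100, 90, 90, 100), 2, 2))
  set.seed(83)
  hi <- vapply(1:2000, function(i) resample_matrix(W3, Y)[1, 2], numeric(1))
  expect_lt(var(hi), var(draws))
})

test_that("each replicate perturbs exactly one layer and reuses thresholds", {
  mats <- two_block_matrices(L = 3, within = 80, between = 20)
  th <- setNames(c(50, 50, 50), c("L1", "L2", "L3"))
  set.seed(84)
  for (rep in 1:5) {
    part <- bootstrap_replicate(mats, th, Y = 60,
      strategy = list(strategy = "max_Q")
    )
    expect_length(attr(part, "resampled_layers"), 1L)
    expect_s3_class(part, "community_partition")
  }
  # all-layers mode perturbs every layer
  part <- bootstrap_replicate(mats, th, Y = 60,
    strategy = list(strategy = "max_Q"), mode = "all_layers"
  )
  expect_length(attr(part, "resampled_layers"), 3L)
})

test_that("zero-variance matrices reproduce the block partition in every replicate", {
  # identities at 100 within blocks, 0 between: resampling is a fixed point
  mats <- two_block_matrices(L = 2, within = 100, between = 0)
  th <- setNames(c(50, 50), c("L1", "L2"))
  bs <- psn_bootstrap(mats, th, Y = 40, n_reps = 10,
    groups = list(block1 = paste0("o", 1:4), block2 = paste0("o", 5:8)),
    strategy = list(strategy = "max_Q"), seed = 85
  )
  expect_equal(bs$support, c(100, 100))
})

test_that("wide-gap planted multiplexes are recovered in almost all replicates", {
  mats <- two_block_matrices(n1 = 5, n2 = 5, L = 2, within = 90, between = 20)
  th <- setNames(c(55, 55), c("L1", "L2"))
  bs <- psn_bootstrap(mats, th, Y = 300, n_reps = 50,
    groups = list(block1 = paste0("o", 1:5)),
    strategy = list(strategy = "max_Q"), seed = 86,
    keep_partitions = TRUE
  )
  expect_gte(bs$support[1], 98)
  expect_length(attr(bs, "partitions"), 50)
})

test_that("bootstrap runs are bit-reproducible under a fixed seed", {
  mats <- two_block_matrices(L = 2)
  th <- setNames(c(55, 55), c("L1", "L2"))
  run <- function() {
    psn_bootstrap(mats, th, Y = 30, n_reps = 5,
      groups = list(b1 = paste0("o", 1:4)),
      strategy = list(strategy = "max_Q"), seed = 87,
      keep_partitions = TRUE
    )
  }
  a <- run()
  b <- run()
  expect_identical(
    lapply(attr(a, "partitions"), tidy),
    lapply(attr(b, "partitions"), tidy)
  )
  expect_identical(a$support, b$support)
})

test_that("group and sister support count exact-community recovery", {
  p_of <- function(memb) {
    ids <- paste0("o", seq_along(memb))
    structure(
      tibble::tibble(
        organism = ids, community = as.integer(memb),
        is_isolated = FALSE
      ),
      class = c("community_partition", "tbl_df", "tbl", "data.frame")
    )
  }
  g <- paste0("o", 1:2)
  always <- list(p_of(c(1, 1, 2, 2)), p_of(c(1, 1, 2, 3)))
  never <- list(p_of(c(1, 2, 1, 2)), p_of(c(1, 2, 2, 2)))
  expect_equal(group_support(always, g), 100)
  expect_equal(group_support(never, g), 0)
  # 3 of 4: 75.0
  mixed <- c(always, list(p_of(c(1, 1, 2, 2)), p_of(c(1, 3, 2, 2))))
  expect_equal(group_support(mixed, g), 75)
  # containment counts super-communities too
  sup <- list(p_of(c(1, 1, 1, 2)))
  expect_equal(group_support(sup, g), 0)
  expect_equal(group_support(sup, g, criterion = "containment"), 100)
  expect_error(group_support(always, c("o1", "zz")),
    class = "multipsn_input_error"
  )

  h <- paste0("o", 3:4)
  expect_equal(sister_support(always, g, h), 50) # second partition splits h
  expect_equal(sister_support(list(p_of(c(1, 1, 1, 1))), g, h), 0)
  expect_error(sister_support(always, g, c("o2", "o3")),
    class = "multipsn_input_error"
  )
})
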