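#' Binomial resampling of an identity matrix
#'
#' For each unordered organism pair, the original identity `w_ij` is divided
#' by 100 and taken as the success probability of a binomial with `Y` trials
#' (the layer's alignment length); the resampled identity is `k * 100 / Y`
#' for `k` drawn successes, written symmetrically into both entries. The
#' diagonal is untouched. Identities of 0 or 100 are fixed points, and the
#' sampling variance `100^2 p (1 - p) / Y` shrinks as identities approach
#' either bound - mirroring how strongly similar sequence pairs vary little
#' under traditional sequence resampling.
#'
#' Draws use R's current RNG stream, one draw per unordered pair in
#' column-major upper-triangle order.
#'
#' @param W a symmetric [identity_matrix()].
#' @param Y alignment length for the layer (trials per pair).
#' @return A resampled [identity_matrix()].
#' @export
resample_matrix <- function(W, Y) {
  stopifnot(inherits(W, "identity_matrix"), Y >= 1)
  m <- unclass(W)
  ut <- upper.tri(m)
  p <- m[ut] / 100
  k <- rbinom(length(p), size = Y, prob = p)
  m[ut] <- k * 100 / Y
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  identity_matrix(m, layer_name(W))
}

#' One bootstrap replicate of the community analysis
#'
#' Picks one layer uniformly at random (or perturbs all layers with
#' `mode = "all_layers"`), resamples its identity matrix with
#' [resample_matrix()], re-thresholds every layer at the *original* run's
#' `sigma_th` values, rebuilds the multiplex, reruns [multing()] and returns
#' the partition selected by the same strategy as the original run. All
#' other layers' matrices are left untouched.
#'
#' @param matrices named list of symmetric, harmonized [identity_matrix()]
#'   objects (the original layers).
#' @param thresholds named numeric vector: the original per-layer
#'   `sigma_th`.
#' @param Y named numeric vector (or single number) of per-layer alignment
#'   lengths.
#' @param strategy partition-selection strategy passed to
#'   [best_partition()]: a list with element `strategy` and its parameters
#'   (`k`, `c`, or `group`).
#' @param mode `"one_layer"` (one randomly chosen layer perturbed per
#'   replicate) or `"all_layers"` (a stronger sensitivity variant).
#' @param gamma,omega modularity parameters, as in [multing()].
#' @return A `community_partition` with a `resampled_layers` attribute.
#' @export
bootstrap_replicate <- function(matrices, thresholds, Y,
                                strategy = list(strategy = "max_Q"),
                                mode = c("one_layer", "all_layers"),
                                gamma = 1, omega = 1) {
  mode <- match.arg(mode)
  nm <- vapply(matrices, layer_name, character(1))
  names(matrices) <- nm
  if (length(Y) == 1L) Y <- setNames(rep(Y, length(nm)), nm)
  chosen <- if (mode == "one_layer") sample(nm, 1L) else nm
  perturbed <- matrices
  for (layer in chosen) {
    perturbed[[layer]] <- resample_matrix(matrices[[layer]], Y[[layer]])
  }
  layers <- lapply(nm, function(layer) {
    threshold_graph(perturbed[[layer]], thresholds[[layer]])
  })
  M <- build_multiplex(layers)
  part <- run_and_select(M, strategy, gamma, omega)
  attr(part, "resampled_layers") <- chosen
  part
}

# run multing with the cheapest stop consistent with the selection strategy
run_and_select <- function(M, strategy, gamma, omega) {
  stop_group <- NULL
  stop_comm <- NULL
  if (identical(strategy$strategy, "group_split")) stop_group <- strategy$group
  if (identical(strategy$strategy, "at_community_count")) {
    stop_comm <- strategy$c
  }
  if (nrow(M$intra_edges) == 0L) {
    return(organism_components(M))
  }
  # stop condition may hold before any removal
  if (!is.null(stop_group)) {
    init <- organism_components(M)
    in_group <- M$organisms %in% stop_group
    mixed <- any(vapply(
      split(in_group, init$community),
      function(z) any(z) && !all(z), logical(1)
    ))
    if (!mixed) {
      attr(init, "modularity") <-
        modularity_multiplex(M, init, gamma, omega)
      return(init)
    }
  }
  trace <- multing(M,
    gamma = gamma, omega = omega,
    stop_communities = stop_comm, stop_group = stop_group
  )
  do.call(best_partition, c(list(trace = trace), strategy))
}

#' Bootstrap support for community structure
#'
#' Runs `n_reps` bootstrap replicates ([bootstrap_replicate()]) under a
#' single seeded RNG stream (layer choice, then binomial draws, in that
#' order per replicate) and summarises how often named organism groups are
#' recovered.
#'
#' @inheritParams bootstrap_replicate
#' @param n_reps number of replicates (the headline analyses use 1000).
#' @param groups named list of organism-identifier vectors to score.
#' @param criterion `"exact"` (group = community: all members share one
#'   label and nobody else carries it) or `"containment"` (all members share
#'   one label).
#' @param seed optional integer seed; with a fixed seed the whole run is
#'   reproducible.
#' @param keep_partitions keep the per-replicate partitions in the result?
#' @return A `bootstrap_summary` tibble: `group`, `support` (percent of
#'   replicates), `n_reps`; the replicate partitions are attached as an
#'   attribute when requested.
#' @export
psn_bootstrap <- function(matrices, thresholds, Y, n_reps = 1000,
                          groups = list(),
                          strategy = list(strategy = "max_Q"),
                          criterion = c("exact", "containment"),
                          mode = c("one_layer", "all_layers"),
                          gamma = 1, omega = 1,
                          seed = NULL, keep_partitions = FALSE) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  partitions <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    partitions[[r]] <- bootstrap_replicate(
      matrices, thresholds, Y,
      strategy = strategy, mode = mode, gamma = gamma, omega = omega
    )
  }
  out <- bootstrap_support(partitions, groups, criterion = criterion)
  if (keep_partitions) attr(out, "partitions") <- partitions
  out
}

#' Summarise group support over stored partitions
#'
#' @param partitions list of `community_partition`s (e.g. bootstrap
#'   replicates).
#' @inheritParams psn_bootstrap
#' @return A `bootstrap_summary` tibble (`group`, `support`, `n_reps`).
#' @export
bootstrap_support <- function(partitions, groups,
                              criterion = c("exact", "containment")) {
  criterion <- match.arg(criterion)
  support <- vapply(groups, function(g) {
    group_support(partitions, g, criterion = criterion)
  }, numeric(1))
  out <- tibble(
    group = names(groups), support = unname(support),
    n_reps = length(partitions)
  )
  attr(out, "groups") <- groups
  class(out) <- c("bootstrap_summary", class(out))
  out
}

#' Support for a single organism group
#'
#' Percentage of partitions in which the group is recovered: under the
#' `"exact"` criterion the group's members all share one community label and
#' no outside organism carries that label; under `"containment"` only the
#' first condition applies.
#'
#' @inheritParams bootstrap_support
#' @param group organism identifiers.
#' @return A percentage in `[0, 100]`.
#' @export
group_support <- function(partitions, group,
                          criterion = c("exact", "containment")) {
  criterion <- match.arg(criterion)
  stopifnot(length(partitions) >= 1L, length(group) >= 1L)
  hits <- vapply(partitions, function(p) {
    idx <- match(group, p$organism)
    if (anyNA(idx)) {
      abort("group contains unknown organisms",
        class = "multipsn_input_error"
      )
    }
    labs <- p$community[idx]
    if (dplyr::n_distinct(labs) != 1L) {
      return(FALSE)
    }
    if (criterion == "containment") {
      return(TRUE)
    }
    sum(p$community == labs[1L]) == length(group)
  }, logical(1))
  100 * mean(hits)
}

#' Sister-placement support for two groups
#'
#' Percentage of partitions in which `group_a` and `group_b` are each
#' recovered as exact communities with distinct labels - the
#' operationalization, at the chosen partition depth, of e.g. the
#' mitochondria-as-sister-to-all-Alphaproteobacteria placement.
#'
#' @inheritParams group_support
#' @param group_a,group_b disjoint organism sets.
#' @return A percentage in `[0, 100]`.
#' @export
sister_support <- function(partitions, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint", class = "multipsn_input_error")
  }
  hits <- vapply(partitions, function(p) {
    exact <- function(g) {
      labs <- p$community[match(g, p$organism)]
      dplyr::n_distinct(labs) == 1L &&
        sum(p$community == labs[1L]) == length(g)
    }
    if (!exact(group_a) || !exact(group_b)) {
      return(FALSE)
    }
    p$community[match(group_a[1L], p$organism)] !=
      p$community[match(group_b[1L], p$organism)]
  }, logical(1))
  100 * mean(hits)
}
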