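#' Edge betweenness on the global multiplex graph
#'
#' Shortest-path edge betweenness (unit edge lengths, unordered-pair
#' counting) computed on the full global graph - intra-layer edges plus the
#' inter-layer couplings - so that a removal in one layer reroutes paths
#' through the other layers. Scores are surfaced for the removable
#' intra-layer edges only.
#'
#' @inheritParams organism_components
#' @return A tibble `layer`, `from`, `to`, `betweenness` (one row per
#'   remaining intra-layer edge), sorted in the deterministic tie-break order
#'   `(layer, from, to)`.
#' @export
multiplex_edge_betweenness <- function(M, removed_intra = NULL) {
  stopifnot(inherits(M, "multiplex_network"))
  e <- global_edges(M, removed_intra)
  if (nrow(e) == 0L || !any(e$type == "intra")) {
    return(tibble(
      layer = integer(0), from = integer(0), to = integer(0),
      betweenness = numeric(0)
    ))
  }
  scores <- cpp_edge_betweenness(M$n * M$L, e$src, e$dst)
  intra <- e$type == "intra"
  rep_from <- replica_of(e$src[intra], M$n)
  rep_to <- replica_of(e$dst[intra], M$n)
  tibble(
    layer = rep_from$layer,
    from = rep_from$organism, to = rep_to$organism,
    betweenness = scores[intra]
  )
}

#' Multiplex Girvan-Newman community detection
#'
#' Divisive detection on a multiplex: repeatedly recompute shortest-path
#' edge betweenness on the full global graph (intra + inter edges, unit
#' lengths), remove the single intra-layer edge with the maximal score (ties
#' broken lexicographically on layer, then endpoints), project connectivity
#' to organisms, and evaluate the multilayer modularity of the resulting
#' partition on the original thresholded multiplex. Inter-layer couplings
#' are never removed, so replicas of one organism always stay together and
#' the trace is organism-level. The loop runs until no intra-layer edge
#' remains, unless an early stop is requested.
#'
#' With a single layer the procedure reduces exactly to classical
#' Girvan-Newman on that layer.
#'
#' @inheritParams organism_components
#' @param gamma resolution parameter of the multilayer modularity (default
#'   1).
#' @param omega inter-layer coupling weight in the modularity (default 1).
#' @param stop_communities optional integer: stop once the organism-level
#'   community count reaches this value.
#' @param stop_group optional organism identifiers: stop once no community
#'   contains both members and non-members of the group (the group has
#'   fully branched out).
#' @return A `removal_trace`: list with `steps` (tibble `step`, `layer`,
#'   `from`, `to`, `betweenness`, `n_communities`, `modularity`), `events`
#'   (tibble of split events: `event`, `step`, `parent`, `children`
#'   list-column), membership snapshots at each event, the generating
#'   multiplex, and `completed` (TRUE when every intra-layer edge was
#'   removed).
#' @export
multing <- function(M, gamma = 1, omega = 1,
                    stop_communities = NULL, stop_group = NULL) {
  stopifnot(inherits(M, "multiplex_network"))
  if (nrow(M$intra_edges) == 0L) {
    abort("multiplex has no intra-layer edges", class = "multipsn_input_error")
  }
  group_idx <- integer(0)
  if (!is.null(stop_group)) {
    group_idx <- match(stop_group, M$organisms)
    if (anyNA(group_idx)) {
      abort("stop_group contains unknown organisms",
        class = "multipsn_input_error"
      )
    }
  }
  res <- cpp_multing(
    M$n, M$L,
    M$intra_edges$layer, M$intra_edges$from, M$intra_edges$to,
    gamma, omega,
    if (is.null(stop_communities)) 0L else as.integer(stop_communities),
    group_idx
  )
  steps <- tibble(
    step = res$step, layer = res$layer, from = res$from, to = res$to,
    betweenness = res$betweenness, n_communities = res$n_communities,
    modularity = res$modularity
  )
  events <- tibble(
    event = seq_along(res$events),
    step = vapply(res$events, function(ev) ev$step, integer(1)),
    parent = vapply(res$events, function(ev) ev$parent, integer(1)),
    children = lapply(res$events, function(ev) ev$children)
  )
  structure(
    list(
      steps = steps, events = events,
      memberships = res$memberships,
      membership_steps = res$membership_steps,
      multiplex = M, gamma = gamma, omega = omega,
      completed = res$completed
    ),
    class = "removal_trace"
  )
}

#' @export
print.removal_trace <- function(x, ...) {
  cat(
    "<removal_trace>", nrow(x$steps), "removals,", nrow(x$events),
    "split events,", if (x$completed) "complete" else "early-stopped", "\n"
  )
  if (nrow(x$steps) > 0) {
    k <- which.max(x$steps$modularity)
    cat(
      " max Q =", format(x$steps$modularity[k], digits = 4),
      "at step", x$steps$step[k], "(",
      x$steps$n_communities[k], "communities )\n"
    )
  }
  invisible(x)
}

#' Single-layer modularity of a partition
#'
#' `Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(C_i, C_j)` over all ordered
#' pairs including `i = j`, so the one-community partition of any graph
#' scores exactly 0. Returns 0 for an edgeless graph by convention.
#'
#' @param G a `layer_graph` (or a binary symmetric adjacency matrix).
#' @param partition a `community_partition`, or an integer membership vector
#'   in node order.
#' @return The modularity `Q`.
#' @export
modularity_single <- function(G, partition) {
  A <- if (inherits(G, "layer_graph")) G$adjacency else as.matrix(G)
  memb <- membership_vector(partition, nrow(A))
  m <- sum(A) / 2
  if (m == 0) {
    return(0)
  }
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

membership_vector <- function(partition, n) {
  memb <- if (inherits(partition, "community_partition")) {
    partition$community
  } else {
    as.integer(as.factor(partition))
  }
  if (length(memb) != n) {
    abort("partition must cover every node", class = "multipsn_input_error")
  }
  memb
}

#' Multilayer modularity of an organism-level partition
#'
#' The multilayer (multiplex) modularity with resolution `gamma` and
#' inter-layer coupling `omega`:
#' `Q = (1/2mu) [ sum_alpha sum_ij (A_ij^alpha - gamma k_i^alpha k_j^alpha /
#' 2m_alpha) delta(g_i, g_j) + omega n L (L - 1) ]`,
#' where `2mu` is the total strength including couplings. Partitions are
#' organism-level, so all replicas of an organism share its label and the
#' coupling term is saturated. With `L = 1` and `gamma = 1` this equals
#' [modularity_single()] on the layer.
#'
#' @inheritParams multing
#' @param partition a `community_partition` or integer membership vector
#'   over organisms.
#' @return The modularity `Q`.
#' @export
modularity_multiplex <- function(M, partition, gamma = 1, omega = 1) {
  stopifnot(inherits(M, "multiplex_network"))
  memb <- membership_vector(partition, M$n)
  two_mu <- omega * M$n * M$L * (M$L - 1)
  total <- omega * M$n * M$L * (M$L - 1) # saturated coupling term
  for (a in seq_len(M$L)) {
    A <- M$adjacency[[a]]
    m_a <- sum(A) / 2
    two_mu <- two_mu + 2 * m_a
    if (m_a == 0) next
    k <- rowSums(A)
    same <- outer(memb, memb, "==")
    total <- total + sum((A - gamma * outer(k, k) / (2 * m_a)) * same)
  }
  if (two_mu == 0) {
    return(0)
  }
  total / two_mu
}

#' Partitions along a removal trace
#'
#' `partition_at()` returns the organism partition holding at (i.e.
#' immediately after) a given removal step; `best_partition()` selects one
#' partition by strategy:
#'
#' * `"max_Q"`: the recorded partition with the greatest modularity
#'   (earliest step on ties);
#' * `"before_event"`: the partition immediately before split event `k`;
#' * `"at_community_count"`: the first partition with exactly `c`
#'   organism-level communities;
#' * `"group_split"`: the partition established at the event where the
#'   `group` organisms fully branch out (no community mixes members and
#'   non-members) - e.g. the partition immediately after the mitochondrial
#'   split, whose modularity is the headline Q of a run.
#'
#' @param trace a `removal_trace` from [multing()].
#' @param strategy one of `"max_Q"`, `"before_event"`,
#'   `"at_community_count"`, `"group_split"`.
#' @param k split event index for `"before_event"`.
#' @param c community count for `"at_community_count"`.
#' @param group organism identifiers for `"group_split"`.
#' @return A `community_partition` with its modularity as an attribute.
#' @export
best_partition <- function(trace,
                           strategy = c(
                             "max_Q", "before_event",
                             "at_community_count", "group_split"
                           ),
                           k = NULL, c = NULL, group = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(trace, "removal_trace"))
  M <- trace$multiplex
  if (strategy == "max_Q") {
    counts <- c(
      dplyr::n_distinct(trace$memberships[, 1L]),
      trace$steps$n_communities
    )
    qs <- c(
      modularity_multiplex(
        M, trace$memberships[, 1L],
        trace$gamma, trace$omega
      ),
      trace$steps$modularity
    )
    best <- which.max(qs)
    step <- c(0L, trace$steps$step)[best]
    return(partition_at(trace, step))
  }
  if (strategy == "before_event") {
    stopifnot(!is.null(k), k >= 1, k <= nrow(trace$events))
    return(partition_at(trace, trace$events$step[k] - 1L))
  }
  if (strategy == "at_community_count") {
    stopifnot(!is.null(c))
    if (dplyr::n_distinct(trace$memberships[, 1L]) == c) {
      return(partition_at(trace, 0L))
    }
    hit <- which(trace$steps$n_communities == c)
    if (length(hit) == 0L) {
      abort(paste("no partition with", c, "communities along the trace"),
        class = "multipsn_selection_error"
      )
    }
    return(partition_at(trace, trace$steps$step[hit[1L]]))
  }
  # group_split
  stopifnot(!is.null(group))
  gi <- match(group, M$organisms)
  if (anyNA(gi)) {
    abort("group contains unknown organisms", class = "multipsn_input_error")
  }
  in_group <- seq_len(M$n) %in% gi
  for (j in seq_len(ncol(trace$memberships))) {
    memb <- trace$memberships[, j]
    mixed <- any(vapply(
      split(in_group, memb),
      function(z) any(z) && !all(z), logical(1)
    ))
    if (!mixed) {
      return(partition_at(trace, trace$membership_steps[j]))
    }
  }
  abort("group never branches out along the trace",
    class = "multipsn_selection_error"
  )
}

#' @rdname best_partition
#' @param step removal step (0 = before any removal).
#' @export
partition_at <- function(trace, step) {
  stopifnot(inherits(trace, "removal_trace"), step >= 0)
  j <- max(which(trace$membership_steps <= step))
  memb <- trace$memberships[, j]
  q <- if (step == 0L) {
    modularity_multiplex(
      trace$multiplex, memb, trace$gamma,
      trace$omega
    )
  } else {
    trace$steps$modularity[match(step, trace$steps$step)]
  }
  new_partition(memb, trace$multiplex, modularity = q)
}

#' When does each organism leave a group?
#'
#' For every organism of `group`, the removal step at which it first stopped
#' sharing a community with the group's core - the community holding the
#' plurality of the group's members at each snapshot (smallest label on
#' ties). Organisms still with the core at the end of the trace get `NA`.
#' Used to rank early-diverging members of a community, e.g. the
#' Rickettsiales-like sub-block leaving the alphaproteobacterial community.
#'
#' @inheritParams best_partition
#' @return A tibble `organism`, `departure_step`.
#' @export
departure_steps <- function(trace, group) {
  stopifnot(inherits(trace, "removal_trace"))
  M <- trace$multiplex
  gi <- match(group, M$organisms)
  if (anyNA(gi)) {
    abort("group contains unknown organisms", class = "multipsn_input_error")
  }
  dep <- rep(NA_integer_, length(gi))
  for (j in seq_len(ncol(trace$memberships))) {
    memb <- trace$memberships[gi, j]
    core <- as.integer(names(which.max(table(memb))))
    out <- is.na(dep) & memb != core
    dep[out] <- trace$membership_steps[j]
  }
  tibble(organism = M$organisms[gi], departure_step = dep)
}
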