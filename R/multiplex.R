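#' Assemble thresholded layers into a multiplex network
#'
#' Every organism is a node in every layer (present or not); replicas of one
#' organism are joined by unweighted inter-layer couplings forming a full
#' clique across the L layers, so each organism carries `L(L-1)/2` coupling
#' edges. Global node enumeration follows `(alpha - 1) n + i` for organism
#' `i` in layer `alpha`.
#'
#' @param layers list of `layer_graph`s (from [threshold_graph()]) sharing
#'   one ordered organism set.
#' @return A `multiplex_network`: list with `organisms`, `n`, `L`,
#'   `layer_names`, `sigmas`, `adjacency` (per-layer binary matrices) and
#'   `intra_edges` (tibble `layer`, `from`, `to` as organism indices,
#'   lexicographically sorted - the deterministic tie-break order).
#' @examples
#' W <- identity_matrix(matrix(c(100, 80, 80, 100), 2, 2), "Cob")
#' M <- build_multiplex(list(threshold_graph(W, 50), threshold_graph(W, 50)))
#' M$L
#' @export
build_multiplex <- function(layers) {
  stopifnot(length(layers) >= 1L)
  for (G in layers) stopifnot(inherits(G, "layer_graph"))
  ids <- layers[[1L]]$organisms
  for (G in layers) {
    if (!identical(G$organisms, ids)) {
      abort("all layers must share one ordered organism set (harmonize first)",
        class = "multipsn_input_error"
      )
    }
  }
  n <- length(ids)
  L <- length(layers)
  edges <- purrr::map_dfr(seq_len(L), function(a) {
    A <- layers[[a]]$adjacency
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    tibble(
      layer = a,
      from = as.integer(idx[, "row"]), to = as.integer(idx[, "col"])
    )
  })
  edges <- dplyr::arrange(edges, .data$layer, .data$from, .data$to)
  structure(
    list(
      organisms = ids, n = n, L = L,
      layer_names = vapply(layers, function(G) G$layer_name, character(1)),
      sigmas = vapply(layers, function(G) G$sigma, numeric(1)),
      adjacency = lapply(layers, function(G) G$adjacency),
      intra_edges = edges
    ),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(
    "<multiplex_network>", x$L, "layers x", x$n, "organisms (",
    x$n * x$L, "global nodes ),", nrow(x$intra_edges), "intra-layer edges,",
    x$n * x$L * (x$L - 1) / 2, "inter-layer couplings\n"
  )
  cat(
    " layers:",
    paste0(x$layer_names, " (sigma ", x$sigmas, ")", collapse = ", "), "\n"
  )
  invisible(x)
}

#' @export
organisms.multiplex_network <- function(x) x$organisms

#' Global node enumeration of a multiplex
#'
#' Organism `i` in layer `alpha` is global node `(alpha - 1) n + i`;
#' `global_index()` maps `(alpha, i)` forward and `replica_of()` inverts the
#' map.
#'
#' @param alpha layer index (1-based).
#' @param i organism index (1-based).
#' @param n number of organisms per layer.
#' @return `global_index()`: integer node id in `1..nL`. `replica_of()`: a
#'   list with `layer` and `organism`.
#' @export
global_index <- function(alpha, i, n) (alpha - 1L) * n + i

#' @rdname global_index
#' @param node global node id.
#' @export
replica_of <- function(node, n) {
  list(
    layer = (node - 1L) %/% n + 1L,
    organism = (node - 1L) %% n + 1L
  )
}

# intra + inter edge list on global node ids (1-based);
# removed_intra: optional tibble(layer, from, to) to drop
global_edges <- function(M, removed_intra = NULL) {
  e <- M$intra_edges
  if (!is.null(removed_intra) && nrow(removed_intra) > 0) {
    key <- paste(e$layer, e$from, e$to)
    drop <- paste(removed_intra$layer, removed_intra$from, removed_intra$to)
    if (!all(drop %in% key)) {
      abort("removed edges must be existing intra-layer edges",
        class = "multipsn_input_error"
      )
    }
    e <- e[!key %in% drop, , drop = FALSE]
  }
  intra <- tibble(
    src = global_index(e$layer, e$from, M$n),
    dst = global_index(e$layer, e$to, M$n),
    type = rep("intra", nrow(e)), layer = e$layer
  )
  if (M$L < 2L) {
    return(intra)
  }
  pairs <- utils::combn(seq_len(M$L), 2L)
  inter <- tibble(
    src = as.vector(outer(global_index(pairs[1L, ], 0L, M$n), seq_len(M$n), "+")),
    dst = as.vector(outer(global_index(pairs[2L, ], 0L, M$n), seq_len(M$n), "+")),
    type = "inter", layer = NA_integer_
  )
  dplyr::bind_rows(intra, inter)
}

#' Project multiplex connectivity down to organisms
#'
#' Connected components of the global graph (remaining intra-layer edges
#' plus all inter-layer couplings), mapped to organism labels. Since
#' couplings are never removed, all replicas of one organism always share a
#' component, so components at the global level are organism partitions.
#' Organisms without a single intra-layer edge in any layer are flagged
#' `is_isolated` (each is its own singleton community).
#'
#' @param M a `multiplex_network`.
#' @param removed_intra optional tibble (`layer`, `from`, `to`) of removed
#'   intra-layer edges.
#' @return A `community_partition` tibble: `organism`, `community` (integer
#'   label, canonical = smallest member index), `is_isolated`.
#' @export
organism_components <- function(M, removed_intra = NULL) {
  stopifnot(inherits(M, "multiplex_network"))
  e <- M$intra_edges
  if (!is.null(removed_intra) && nrow(removed_intra) > 0) {
    key <- paste(e$layer, e$from, e$to)
    drop <- paste(removed_intra$layer, removed_intra$from, removed_intra$to)
    if (!all(drop %in% key)) {
      abort("removed edges must be existing intra-layer edges",
        class = "multipsn_input_error"
      )
    }
    e <- e[!key %in% drop, , drop = FALSE]
  }
  new_partition(memb_from_edges(M$n, e), M)
}

# organism-level union-find over an intra edge tibble; canonical labels
memb_from_edges <- function(n, edges) {
  g <- igraph::graph_from_edgelist(
    cbind(edges$from, edges$to),
    directed = FALSE
  )
  g <- g + igraph::vertices(setdiff(seq_len(n), seq_len(igraph::vcount(g))))
  comp <- igraph::components(g)$membership[seq_len(n)]
  canonical <- vapply(split(seq_len(n), comp), min, integer(1))
  as.integer(canonical[as.character(comp)])
}

new_partition <- function(memb, M, modularity = NA_real_) {
  iso <- !(seq_len(M$n) %in% c(M$intra_edges$from, M$intra_edges$to))
  out <- tibble(
    organism = M$organisms,
    community = as.integer(memb),
    is_isolated = iso
  )
  attr(out, "modularity") <- modularity
  class(out) <- c("community_partition", class(out))
  out
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- sort(table(x$community[!x$is_isolated]), decreasing = TRUE)
  cat(
    "<community_partition>", dplyr::n_distinct(x$community), "communities (",
    sum(x$is_isolated), "isolated );",
    "sizes:", paste(utils::head(as.integer(sizes), 8), collapse = ", ")
  )
  q <- attr(x, "modularity")
  if (!is.na(q)) cat(" | Q =", format(q, digits = 4))
  cat("\n")
  NextMethod()
}

#' Write a multiplex as an edge list
#'
#' Global-node edge list (`src_global`, `dst_global`, `type` intra/inter,
#' `layer`), tab-separated, for interoperability and debugging.
#'
#' @inheritParams organism_components
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multiplex_edgelist <- function(M, path) {
  e <- global_edges(M)
  names(e)[1:2] <- c("src_global", "dst_global")
  write.table(e,
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
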