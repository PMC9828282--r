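#' Dendrogram of the edge-removal process
#'
#' Converts a complete removal trace into a rooted tree of bifurcation
#' events: each internal node is a split event (its height the removal step
#' at which it happened, multifurcations allowed when one removal splits a
#' community into more than two parts), each leaf an organism. When the
#' starting multiplex is already disconnected, the root joins the initial
#' components at step 0.
#'
#' @param trace a completed `removal_trace` (run to zero intra-layer edges,
#'   so every organism ends as a singleton).
#' @return A `psn_dendrogram`: list with the recursive `tree`, `organisms`
#'   and `n_steps`.
#' @export
build_dendrogram <- function(trace) {
  stopifnot(inherits(trace, "removal_trace"))
  if (!trace$completed) {
    abort("dendrogram needs a complete trace (no early stop)",
      class = "multipsn_input_error"
    )
  }
  M <- trace$multiplex
  events <- trace$events
  # node for community with canonical label `lab`, born at event step `born`
  grow <- function(lab, born, members) {
    if (length(members) == 1L) {
      return(list(leaf = M$organisms[members]))
    }
    nxt <- which(events$parent == lab & events$step > born)
    # the first later event whose parent label matches AND whose children
    # partition this member set (labels are reused by sub-communities)
    for (e in nxt) {
      kids <- events$children[[e]]
      if (all(kids %in% members)) {
        memb_after <- trace$memberships[, which(trace$membership_steps == events$step[e])[1L]]
        parts <- lapply(kids, function(k) members[memb_after[members] == k])
        return(list(
          step = events$step[e],
          children = mapply(grow, kids, events$step[e], parts,
            SIMPLIFY = FALSE
          )
        ))
      }
    }
    abort("removal trace does not resolve all organisms") # unreachable on complete traces
  }
  init <- trace$memberships[, 1L]
  roots <- sort(unique(init))
  tree <- if (length(roots) == 1L) {
    grow(roots, 0L, seq_len(M$n))
  } else {
    list(
      step = 0L,
      children = lapply(roots, function(r) grow(r, 0L, which(init == r)))
    )
  }
  structure(
    list(
      tree = tree, organisms = M$organisms,
      n_steps = nrow(trace$steps)
    ),
    class = "psn_dendrogram"
  )
}

#' @export
print.psn_dendrogram <- function(x, ...) {
  cat(
    "<psn_dendrogram>", length(x$organisms), "leaves,", x$n_steps,
    "removal steps\n"
  )
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Internal node labels carry the split step (`s<step>`); when a
#' `bootstrap_summary` is supplied, an internal node whose leaf set exactly
#' matches one of the summary's groups is labelled with that group's support
#' percentage instead. Organism labels are quoted when they contain Newick
#' metacharacters.
#'
#' @param d a `psn_dendrogram`.
#' @param with_support optional [bootstrap_support()] summary.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(d, with_support = NULL) {
  stopifnot(inherits(d, "psn_dendrogram"))
  groups <- list()
  if (!is.null(with_support)) {
    groups <- attr(with_support, "groups")
    support <- setNames(with_support$support, with_support$group)
  }
  esc <- function(lab) {
    if (grepl("[\\s()\\[\\]:;,']", lab, perl = TRUE)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  walk <- function(node) {
    if (!is.null(node$leaf)) {
      return(list(str = esc(node$leaf), leaves = node$leaf))
    }
    parts <- lapply(node$children, walk)
    leaves <- sort(unlist(lapply(parts, `[[`, "leaves")))
    label <- paste0("s", node$step)
    if (length(groups) > 0) {
      hit <- which(vapply(
        groups,
        function(g) identical(sort(g), leaves), logical(1)
      ))
      if (length(hit) > 0) {
        label <- format(support[[names(groups)[hit[1L]]]], digits = 4)
      }
    }
    list(
      str = paste0(
        "(", paste(vapply(parts, `[[`, character(1), "str"),
          collapse = ","
        ),
        ")", label
      ),
      leaves = leaves
    )
  }
  paste0(walk(d$tree)$str, ";")
}

#' @rdname to_newick
#' @param x a `psn_dendrogram`.
#' @param ... unused.
#' @return `as.phylo()`: an [ape::read.tree()] tree for plotting and
#'   downstream phylogenetic tooling.
#' @importFrom ape as.phylo
#' @export
as.phylo.psn_dendrogram <- function(x, ...) {
  ape::read.tree(text = to_newick(x))
}
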