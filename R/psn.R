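#' Threshold an identity matrix into an unweighted network
#'
#' Applies the adjacency rule `A(sigma)_ij = 1` iff `w_ij >= sigma` (the
#' comparison is inclusive) for distinct organisms both present in the layer.
#' Absent organisms receive no edges, so they enter the network as isolated
#' nodes.
#'
#' @param W a symmetric [identity_matrix()].
#' @param sigma identity threshold in `[0, 100]`.
#' @return A `layer_graph`: list with `layer_name`, `sigma`, `organisms`,
#'   `present` and the binary `adjacency` matrix (zero diagonal).
#' @examples
#' W <- identity_matrix(matrix(c(100, 64, 64, 100), 2, 2), "Cob")
#' threshold_graph(W, 64)$adjacency
#' @export
threshold_graph <- function(W, sigma) {
  stopifnot(inherits(W, "identity_matrix"))
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0 || sigma > 100) {
    abort("sigma must be a single value in [0, 100]",
      class = "multipsn_domain_error"
    )
  }
  m <- unclass(W)
  present <- diag(m) > 0
  A <- (m >= sigma) * 1L
  diag(A) <- 0L
  A[!present, ] <- 0L
  A[, !present] <- 0L
  structure(
    list(
      layer_name = layer_name(W), sigma = sigma,
      organisms = rownames(m), present = setNames(present, rownames(m)),
      adjacency = A
    ),
    class = "layer_graph"
  )
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(
    "<layer_graph>", x$layer_name, "sigma =", x$sigma, "-",
    length(x$organisms), "organisms,", sum(x$adjacency) / 2, "edges\n"
  )
  invisible(x)
}

#' @export
organisms.layer_graph <- function(x) x$organisms

#' @export
is_present.layer_graph <- function(x) x$present

#' The full threshold family of a layer
#'
#' Networks at every integer threshold `sigma` in `[0, 100]` (101 networks);
#' edge sets are nested, shrinking as `sigma` grows.
#'
#' @inheritParams threshold_graph
#' @param sigmas thresholds to evaluate (default the integer grid `0:100`).
#' @return A named list of `layer_graph`s.
#' @export
threshold_family <- function(W, sigmas = 0:100) {
  out <- lapply(sigmas, function(s) threshold_graph(W, s))
  names(out) <- as.character(sigmas)
  out
}

#' Neighborhood-order matrix of a layer graph
#'
#' Shortest-path length between every organism pair, with pairs in different
#' components (including isolated nodes) assigned the cap `Lambda = n`. This
#' cap is what turns a component split into a large, sharp contribution to
#' the dissimilarity between consecutive thresholded networks.
#'
#' @param G a `layer_graph`.
#' @return An `n x n` numeric matrix; zero diagonal.
#' @export
neighborhood_matrix <- function(G) {
  stopifnot(inherits(G, "layer_graph"))
  n <- length(G$organisms)
  g <- igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected")
  D <- igraph::distances(g)
  D[is.infinite(D)] <- n
  diag(D) <- 0
  D
}

#' Dissimilarity between two networks on the same organisms
#'
#' `delta = sum_{i != j} |order1(i,j) - order2(i,j)| / (n (n - 1))`, where
#' `order` is the neighborhood-order (shortest-path) matrix with
#' disconnected-pair cap `n`. Zero iff the two graphs induce identical
#' neighborhood orders; symmetric and non-negative.
#'
#' @param G1,G2 `layer_graph`s over the same ordered organism set.
#' @return A non-negative number.
#' @export
dissimilarity <- function(G1, G2) {
  stopifnot(inherits(G1, "layer_graph"), inherits(G2, "layer_graph"))
  if (!identical(G1$organisms, G2$organisms)) {
    abort("graphs must share one ordered organism set",
      class = "multipsn_input_error"
    )
  }
  n <- length(G1$organisms)
  if (n < 2L) {
    return(0)
  }
  D1 <- neighborhood_matrix(G1)
  D2 <- neighborhood_matrix(G2)
  sum(abs(D1 - D2)) / (n * (n - 1))
}

#' Dissimilarity profile over the threshold grid
#'
#' Evaluates `delta(sigma, sigma + step)` between the networks thresholded at
#' consecutive grid values, for `sigma` on the integer grid. Sharp peaks mark
#' thresholds at which the network's modular structure reorganizes (edges
#' bundles vanish, components split); their maxima are the candidate
#' per-layer thresholds.
#'
#' Peaks are strict local maxima of `delta` on the grid interior; a plateau
#' counts as one peak at its smallest `sigma` when strictly above both
#' flanking values.
#'
#' @inheritParams threshold_graph
#' @param step grid increment `Delta sigma` (default 1).
#' @return A `dissimilarity_profile`: a tibble with columns `sigma`, `delta`
#'   and attributes `layer_name`, `step` and `peaks`.
#' @export
dissimilarity_profile <- function(W, step = 1) {
  stopifnot(inherits(W, "identity_matrix"), step >= 1)
  sigmas <- seq(0, 100 - step, by = step)
  graphs <- threshold_family(W, c(sigmas, 100))
  delta <- vapply(
    seq_along(sigmas),
    function(k) dissimilarity(graphs[[k]], graphs[[k + 1L]]),
    numeric(1)
  )
  out <- tibble(sigma = sigmas, delta = delta)
  attr(out, "layer_name") <- layer_name(W)
  attr(out, "step") <- step
  attr(out, "peaks") <- find_peaks(sigmas, delta)
  class(out) <- c("dissimilarity_profile", class(out))
  out
}

#' @rdname dissimilarity_profile
#' @param x a `dissimilarity_profile`.
#' @return `profile_peaks()`: the `sigma` values of detected peaks.
#' @export
profile_peaks <- function(x) attr(x, "peaks")

# strict local maxima on the grid; plateaus resolve to their smallest sigma
find_peaks <- function(sigma, delta) {
  n <- length(delta)
  if (n < 3L) {
    return(numeric(0))
  }
  peaks <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (delta[i] > delta[i - 1L]) {
      # plateau from i to j; a peak iff delta drops after the plateau
      j <- i
      while (j < n && delta[j + 1L] == delta[i]) j <- j + 1L
      if (j < n && delta[j + 1L] < delta[i]) peaks <- c(peaks, sigma[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

#' Select a per-layer threshold from a dissimilarity profile
#'
#' Three modes. `"split_guided"` (the default, and the strategy used for the
#' mitochondrial analysis) returns the largest peak `sigma` at which a probe
#' organism subset is still connected to the rest of its component - i.e. the
#' peak immediately preceding the threshold at which the probe splits off.
#' `"max_peak"` returns the peak with the largest `delta` (smallest `sigma`
#' on ties). `"manual"` passes `value` through.
#'
#' @param profile a [dissimilarity_profile()].
#' @param mode `"split_guided"`, `"max_peak"` or `"manual"`.
#' @param W the identity matrix the profile came from (needed for
#'   `"split_guided"` connectivity checks).
#' @param probe organism identifiers of the probe subset (e.g. the
#'   eukaryotes) for `"split_guided"`.
#' @param value the user-chosen threshold for `"manual"`.
#' @return The selected threshold `sigma_th` (a single number).
#' @export
select_threshold <- function(profile,
                             mode = c("split_guided", "max_peak", "manual"),
                             W = NULL, probe = NULL, value = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    stopifnot(is.numeric(value), length(value) == 1L)
    return(value)
  }
  peaks <- profile_peaks(profile)
  if (length(peaks) == 0L) {
    abort(
      paste0(
        "no dissimilarity peaks for layer ", attr(profile, "layer_name"),
        "; profile delta range [", min(profile$delta), ", ",
        max(profile$delta), "]"
      ),
      class = "multipsn_selection_error"
    )
  }
  if (mode == "max_peak") {
    d <- profile$delta[match(peaks, profile$sigma)]
    return(peaks[which.max(d)])
  }
  # split_guided
  if (is.null(W) || is.null(probe)) {
    abort("split_guided selection needs W and a probe organism subset",
      class = "multipsn_selection_error"
    )
  }
  bad <- setdiff(probe, rownames(W))
  if (length(bad) > 0) {
    abort(paste("unknown probe organisms:", paste(bad, collapse = ", ")),
      class = "multipsn_input_error"
    )
  }
  connected <- vapply(peaks, function(s) {
    probe_attached(threshold_graph(W, s), probe)
  }, logical(1))
  if (!any(connected)) {
    abort(
      paste0(
        "probe subset already split at every peak of layer ",
        attr(profile, "layer_name"), " (peaks: ",
        paste(peaks, collapse = ", "), ")"
      ),
      class = "multipsn_selection_error"
    )
  }
  max(peaks[connected])
}

# TRUE while some connected component mixes probe and non-probe organisms
probe_attached <- function(G, probe) {
  g <- igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected")
  comp <- igraph::components(g)$membership
  in_probe <- G$organisms %in% probe
  any(vapply(
    split(in_probe, comp),
    function(z) any(z) && !all(z), logical(1)
  ))
}

#' Select thresholds for a set of layers
#'
#' Convenience wrapper: computes the dissimilarity profile of every layer and
#' applies [select_threshold()], returning a tidy table.
#'
#' @param layers named list of symmetric [identity_matrix()] objects.
#' @inheritParams select_threshold
#' @param values named numeric vector of manual thresholds (mode
#'   `"manual"`).
#' @param step grid increment for the profiles.
#' @return A tibble with columns `layer`, `sigma_th`, and `n_peaks`, plus a
#'   `profiles` attribute holding the per-layer profiles.
#' @export
select_thresholds <- function(layers,
                              mode = c("split_guided", "max_peak", "manual"),
                              probe = NULL, values = NULL, step = 1) {
  mode <- match.arg(mode)
  profiles <- lapply(layers, dissimilarity_profile, step = step)
  sigma_th <- vapply(seq_along(layers), function(k) {
    select_threshold(profiles[[k]],
      mode = mode, W = layers[[k]], probe = probe,
      value = if (!is.null(values)) values[[layer_name(layers[[k]])]]
    )
  }, numeric(1))
  out <- tibble(
    layer = vapply(layers, layer_name, character(1)),
    sigma_th = sigma_th,
    n_peaks = vapply(profiles, function(p) length(profile_peaks(p)), integer(1))
  )
  attr(out, "profiles") <- profiles
  out
}
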