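#' Specification of a planted-block multilayer fixture
#'
#' Defines the generative model for synthetic per-ortholog identity
#' matrices: organisms are assigned to blocks (planted communities), and
#' each pairwise identity is drawn from a normal distribution whose mean and
#' standard deviation depend on the block pair, truncated to `[0, 100]`.
#' Within-block levels sit well above between-block levels, emulating the
#' block structure of real ortholog identity matrices. Organisms can be
#' declared missing from individual layers to exercise the isolated-node
#' rule.
#'
#' @param block_assignment named character (or factor) vector: organism id
#'   -> block label.
#' @param n_layers number of ortholog layers L.
#' @param within_mean,within_sd identity distribution for within-block
#'   pairs: scalars, or named vectors keyed by block.
#' @param between_mean,between_sd identity distribution for between-block
#'   pairs: scalars, or full block-by-block matrices (dimnames = blocks) for
#'   pair-specific levels such as distinct outgroup separations.
#' @param missing_per_layer optional list (length `n_layers`) of organism
#'   ids absent from each layer.
#' @param layer_names optional layer labels.
#' @return A `planted_spec` object.
#' @export
planted_spec <- function(block_assignment, n_layers = 2,
                         within_mean = 80, within_sd = 4,
                         between_mean = 40, between_sd = 4,
                         missing_per_layer = NULL, layer_names = NULL) {
  ids <- names(block_assignment)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("block_assignment must be named by unique organism ids",
      class = "multipsn_input_error"
    )
  }
  blocks <- sort(unique(as.character(block_assignment)))
  expand_within <- function(x) {
    if (length(x) == 1L) x <- setNames(rep(x, length(blocks)), blocks)
    if (!all(blocks %in% names(x))) {
      abort("per-block parameters must name every block",
        class = "multipsn_input_error"
      )
    }
    x[blocks]
  }
  expand_between <- function(x, within) {
    if (is.matrix(x)) {
      if (!all(blocks %in% rownames(x)) || !all(blocks %in% colnames(x))) {
        abort("between matrix must cover every block pair",
          class = "multipsn_input_error"
        )
      }
      m <- x[blocks, blocks]
    } else {
      m <- matrix(x, length(blocks), length(blocks),
        dimnames = list(blocks, blocks)
      )
    }
    diag(m) <- within
    (m + t(m)) / 2
  }
  wm <- expand_within(within_mean)
  ws <- expand_within(within_sd)
  mean_mat <- expand_between(between_mean, wm)
  sd_mat <- expand_between(between_sd, ws)
  if (any(mean_mat < 0 | mean_mat > 100) || any(sd_mat < 0)) {
    abort("means must lie in [0, 100] and sds be non-negative",
      class = "multipsn_input_error"
    )
  }
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_len(n_layers))
  if (!is.null(missing_per_layer)) {
    if (length(missing_per_layer) != n_layers) {
      abort("missing_per_layer must have one entry per layer",
        class = "multipsn_input_error"
      )
    }
    bad <- setdiff(unlist(missing_per_layer), ids)
    if (length(bad) > 0) {
      abort("missing organisms unknown to the spec",
        class = "multipsn_input_error"
      )
    }
  }
  structure(
    list(
      organisms = ids,
      block_assignment = setNames(as.character(block_assignment), ids),
      blocks = blocks, n_layers = as.integer(n_layers),
      mean_mat = mean_mat, sd_mat = sd_mat,
      missing_per_layer = missing_per_layer, layer_names = layer_names
    ),
    class = "planted_spec"
  )
}

#' Generate planted-block identity matrices
#'
#' Draws the layers described by a [planted_spec()]: symmetric matrices with
#' diagonal 100, pairwise identities drawn once per unordered pair from the
#' block-pair distribution and truncated to `[0, 100]`, absent organisms
#' zeroed out per the isolated-node rule. Deterministic for a fixed RNG
#' state: call `set.seed()` (or pass `seed`) for reproducible fixtures.
#'
#' @param spec a [planted_spec()].
#' @param seed optional integer seed.
#' @return Named list of [identity_matrix()] objects, one per layer.
#' @export
generate_planted <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "planted_spec"))
  if (!is.null(seed)) set.seed(seed)
  ids <- spec$organisms
  n <- length(ids)
  bl <- spec$block_assignment
  out <- lapply(seq_len(spec$n_layers), function(a) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- which(upper.tri(m), arr.ind = TRUE)
    mu <- spec$mean_mat[cbind(bl[ut[, 1L]], bl[ut[, 2L]])]
    sd <- spec$sd_mat[cbind(bl[ut[, 1L]], bl[ut[, 2L]])]
    w <- pmin(100, pmax(0, rnorm(nrow(ut), mu, sd)))
    m[ut] <- w
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    if (!is.null(spec$missing_per_layer)) {
      gone <- spec$missing_per_layer[[a]]
      m[gone, ] <- 0
      m[, gone] <- 0
    }
    identity_matrix(m, spec$layer_names[a])
  })
  setNames(out, spec$layer_names)
}

#' Synthetic mitochondrial-origin benchmark fixture
#'
#' A labelled multilayer fixture emulating the shape of the
#' mitochondrial-origin dataset: by default 86 organisms - 6 eukaryotes
#' (the mitochondrial sequences), 72 Alphaproteobacteria of which 17 form
#' an early-diverging Rickettsiales-like sub-block, and 4 each of Beta- and
#' Gammaproteobacteria as outgroups - over 8 ortholog layers. Four
#' organisms (one alphaproteobacterium, one beta, two gamma) are given
#' uniformly low identities so that they are isolated in every thresholded
#' layer. The identity levels (documented in the methods vignette) are
#' chosen so that the eukaryote block stays attached to the
#' alphaproteobacterial community up to the highest dissimilarity peaks,
#' the outgroups form a single separate community, and the
#' Rickettsiales-like members are the most weakly attached members of the
#' alpha community. This is synthetic test scaffolding, not real sequence
#' data.
#'
#' @param seed integer seed (the fixture is deterministic per seed).
#' @param n_eukaryote,n_alpha,n_beta,n_gamma block sizes (n_alpha includes
#'   the Rickettsiales-like members and any alpha isolate).
#' @param n_rickettsiales size of the early-diverging sub-block.
#' @param n_isolated number of all-layer-isolated organisms (allocated one
#'   to alpha, one to beta, the rest to gamma, in that order).
#' @param L number of layers.
#' @param layer_names layer labels; defaults to the eight mitochondrial
#'   ortholog names.
#' @return A list with `matrices` (named list of [identity_matrix()]),
#'   `taxonomy` (tibble `organism`, `class`, `order`), and `groups` (named
#'   list of organism-id vectors: `eukaryote`, `alpha`, `alpha_community`,
#'   `rickettsiales`, `outgroup`, `isolated`).
#' @export
mito_fixture <- function(seed = 1,
                         n_eukaryote = 6, n_alpha = 72,
                         n_rickettsiales = 17,
                         n_beta = 4, n_gamma = 4, n_isolated = 4,
                         L = 8,
                         layer_names = c(
                           "Cob", "Cox2", "Cox3", "Nad1",
                           "Nad4", "Nad5", "Nad6", "Nad9"
                         )[seq_len(L)]) {
  stopifnot(
    n_rickettsiales < n_alpha, n_isolated <= 2 + n_gamma,
    length(layer_names) == L
  )
  iso_alpha <- min(1L, n_isolated)
  iso_beta <- if (n_isolated >= 2L) 1L else 0L
  iso_gamma <- n_isolated - iso_alpha - iso_beta
  stopifnot(iso_gamma <= n_gamma, iso_beta <= n_beta, iso_alpha <= n_alpha)
  n_alpha_other <- n_alpha - n_rickettsiales - iso_alpha
  pad <- function(p, k) sprintf("%s%02d", p, seq_len(k))
  ids <- list(
    euk = pad("Euk", n_eukaryote),
    rick = pad("Rick", n_rickettsiales),
    alpha = pad("Alpha", n_alpha_other),
    beta = pad("Beta", n_beta - iso_beta),
    gamma = pad("Gamma", n_gamma - iso_gamma),
    iso = c(
      if (iso_alpha) "AlphaIso01",
      if (iso_beta) "BetaIso01",
      if (iso_gamma) pad("GammaIso", iso_gamma)
    )
  )
  assignment <- setNames(
    rep(names(ids), lengths(ids)),
    unlist(ids, use.names = FALSE)
  )
  blocks <- c("euk", "rick", "alpha", "beta", "gamma", "iso")
  mean_mat <- matrix(NA_real_, 6, 6, dimnames = list(blocks, blocks))
  sd_mat <- matrix(3, 6, 6, dimnames = list(blocks, blocks))
  # identity levels (percent): see the methods vignette for rationale
  diag(mean_mat) <- c(72, 61, 66, 70, 70, 25)
  mean_mat["euk", c("rick", "alpha")] <- 52
  mean_mat["euk", c("beta", "gamma")] <- 40
  mean_mat["rick", "alpha"] <- 60
  mean_mat["rick", c("beta", "gamma")] <- 45
  mean_mat["alpha", c("beta", "gamma")] <- 45
  mean_mat["beta", "gamma"] <- 60
  mean_mat[, "iso"] <- 25
  mean_mat["iso", ] <- 25
  mean_mat[lower.tri(mean_mat)] <- t(mean_mat)[lower.tri(mean_mat)]
  diag(mean_mat) <- c(72, 61, 66, 70, 70, 25)
  diag(sd_mat) <- c(4, 3, 3, 4, 4, 3)
  spec <- planted_spec(
    assignment,
    n_layers = L,
    within_mean = setNames(diag(mean_mat), blocks),
    within_sd = setNames(diag(sd_mat), blocks),
    between_mean = mean_mat, between_sd = sd_mat,
    layer_names = layer_names
  )
  matrices <- generate_planted(spec, seed = seed)
  cls <- c(
    euk = "Eukaryote", rick = "Alphaproteobacteria",
    alpha = "Alphaproteobacteria", beta = "Betaproteobacteria",
    gamma = "Gammaproteobacteria", iso = NA_character_
  )
  iso_cls <- c(
    if (iso_alpha) "Alphaproteobacteria",
    if (iso_beta) "Betaproteobacteria",
    if (iso_gamma) rep("Gammaproteobacteria", iso_gamma)
  )
  taxonomy <- tibble(
    organism = names(assignment),
    class = unname(cls[assignment]),
    order = ifelse(assignment == "rick", "Rickettsiales", NA_character_)
  )
  taxonomy$class[assignment == "iso"] <- iso_cls
  groups <- list(
    eukaryote = ids$euk,
    alpha = c(ids$rick, ids$alpha, if (iso_alpha) "AlphaIso01"),
    alpha_community = c(ids$rick, ids$alpha),
    rickettsiales = ids$rick,
    outgroup = c(ids$beta, ids$gamma),
    isolated = ids$iso
  )
  list(matrices = matrices, taxonomy = taxonomy, groups = groups)
}
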