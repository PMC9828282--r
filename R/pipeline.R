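#' Run the full multiplex PSN pipeline
#'
#' End-to-end driver: symmetrize and harmonize the per-ortholog identity
#' matrices, select per-layer thresholds at dissimilarity peaks (or take
#' manual values), assemble the multiplex, run multiplex Girvan-Newman,
#' select the reporting partition, build the dendrogram (when the trace runs
#' to completion) and optionally bootstrap the community support. When
#' `out_dir` is given, every artifact is written to disk and listed in the
#' returned manifest; with a fixed `seed` the outputs are byte-identical
#' across runs.
#'
#' @param matrices named list of [identity_matrix()] objects (or file paths
#'   understood by [read_identity_matrix()]), one per ortholog layer.
#' @param taxonomy optional tibble with columns `organism` and `class`
#'   (annotates the community table).
#' @param threshold_mode `"split_guided"`, `"max_peak"` or `"manual"`.
#' @param probe organism ids guiding `"split_guided"` selection and the
#'   default `"group_split"` partition strategy (e.g. the eukaryotes).
#' @param manual_thresholds named numeric vector of per-layer `sigma_th`
#'   (mode `"manual"`).
#' @param strategy partition-selection strategy for [best_partition()]; the
#'   default reports the partition at the probe's branch-out.
#' @param run_to `"complete"` (full removal trace; enables the dendrogram)
#'   or `"partition"` (stop as soon as the strategy's partition is
#'   determined; cheaper on large inputs).
#' @param gamma,omega multilayer modularity parameters.
#' @param bootstrap_reps bootstrap replicates (0 = skip).
#' @param bootstrap_groups named list of organism groups to score; defaults
#'   to the probe group when bootstrapping.
#' @param Y per-layer alignment lengths for the bootstrap.
#' @param seed seed driving the bootstrap RNG stream.
#' @param out_dir optional output directory for artifacts.
#' @param verbose print per-stage progress?
#' @return A `psn_pipeline` list: `thresholds`, `profiles`, `multiplex`,
#'   `trace`, `partition`, `dendrogram` (or NULL), `newick` (or NULL),
#'   `bootstrap` (or NULL), `communities` (annotated tibble), `manifest`
#'   (tibble of written files).
#' @export
run_pipeline <- function(matrices, taxonomy = NULL,
                         threshold_mode = c(
                           "split_guided", "max_peak",
                           "manual"
                         ),
                         probe = NULL, manual_thresholds = NULL,
                         strategy = NULL,
                         run_to = c("complete", "partition"),
                         gamma = 1, omega = 1,
                         bootstrap_reps = 0, bootstrap_groups = NULL,
                         Y = 400, seed = NULL,
                         out_dir = NULL, verbose = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  run_to <- match.arg(run_to)
  say <- function(...) if (verbose) message("[multipsn] ", ...)
  t0 <- Sys.time()

  if (is.character(matrices)) {
    matrices <- lapply(matrices, read_identity_matrix)
  }
  say("symmetrizing and harmonizing ", length(matrices), " layers")
  matrices <- lapply(matrices, symmetrize)
  harm <- harmonize_layers(matrices)
  layers <- harm$layers

  if (is.null(probe) && !is.null(taxonomy)) {
    probe <- taxonomy$organism[tolower(taxonomy$class) %in%
      c("eukaryote", "eukaryota")]
    if (length(probe) == 0L) probe <- NULL
  }
  if (is.null(strategy)) {
    strategy <- if (!is.null(probe)) {
      list(strategy = "group_split", group = probe)
    } else {
      list(strategy = "max_Q")
    }
  }

  say("selecting thresholds (", threshold_mode, ")")
  thresholds <- select_thresholds(layers,
    mode = threshold_mode,
    probe = probe, values = manual_thresholds
  )
  profiles <- attr(thresholds, "profiles")
  say(
    "sigma_th: ",
    paste(thresholds$layer, thresholds$sigma_th,
      sep = "=",
      collapse = ", "
    )
  )

  graphs <- purrr::map2(
    layers, thresholds$sigma_th,
    function(W, s) threshold_graph(W, s)
  )
  M <- build_multiplex(graphs)
  say(
    "multiplex: ", M$n, " organisms x ", M$L, " layers, ",
    nrow(M$intra_edges), " intra-layer edges"
  )

  say("running multiplex Girvan-Newman (", run_to, ")")
  stop_group <- NULL
  stop_comm <- NULL
  if (run_to == "partition") {
    if (identical(strategy$strategy, "group_split")) {
      stop_group <- strategy$group
    }
    if (identical(strategy$strategy, "at_community_count")) {
      stop_comm <- strategy$c
    }
  }
  trace <- multing(M,
    gamma = gamma, omega = omega,
    stop_communities = stop_comm, stop_group = stop_group
  )
  partition <- do.call(best_partition, c(list(trace = trace), strategy))
  say(
    "partition: ", dplyr::n_distinct(partition$community),
    " communities, Q = ",
    format(attr(partition, "modularity"), digits = 4)
  )

  dendro <- NULL
  newick <- NULL
  if (trace$completed) {
    dendro <- build_dendrogram(trace)
  }

  boot <- NULL
  if (bootstrap_reps > 0) {
    if (is.null(bootstrap_groups)) {
      bootstrap_groups <- if (!is.null(probe)) list(probe = probe) else list()
    }
    say("bootstrap: ", bootstrap_reps, " replicates")
    boot <- psn_bootstrap(
      layers,
      thresholds = setNames(thresholds$sigma_th, thresholds$layer),
      Y = Y, n_reps = bootstrap_reps, groups = bootstrap_groups,
      strategy = strategy, gamma = gamma, omega = omega, seed = seed
    )
  }
  if (!is.null(dendro)) newick <- to_newick(dendro, with_support = boot)

  communities <- partition
  if (!is.null(taxonomy)) {
    communities <- dplyr::left_join(partition, taxonomy, by = "organism")
  }

  manifest <- tibble(kind = character(0), path = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(kind, fname, writer) {
      path <- file.path(out_dir, fname)
      writer(path)
      manifest <<- dplyr::bind_rows(manifest, tibble(kind = kind, path = path))
    }
    emit("thresholds", "thresholds.tsv", function(p) {
      write.table(as.data.frame(thresholds),
        p,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    for (k in seq_along(profiles)) {
      nmk <- thresholds$layer[k]
      emit("profile", paste0("profile_", nmk, ".csv"), local({
        pk <- profiles[[k]]
        function(p) {
          write.table(as.data.frame(pk), p,
            sep = ",",
            quote = FALSE, row.names = FALSE
          )
        }
      }))
    }
    emit("multiplex", "multiplex_edges.tsv", function(p) {
      write_multiplex_edgelist(M, p)
    })
    emit("trace", "trace.csv", function(p) {
      write.table(as.data.frame(trace$steps), p,
        sep = ",",
        quote = FALSE, row.names = FALSE
      )
    })
    emit("communities", "communities.tsv", function(p) {
      write.table(as.data.frame(communities), p,
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
    })
    if (!is.null(newick)) {
      emit("dendrogram", "dendrogram.nwk", function(p) {
        writeLines(newick, p)
      })
    }
    if (!is.null(boot)) {
      emit("bootstrap", "bootstrap.tsv", function(p) {
        write.table(as.data.frame(boot), p,
          sep = "\t",
          quote = FALSE, row.names = FALSE
        )
      })
    }
  }
  say("done in ", format(Sys.time() - t0, digits = 3))
  structure(
    list(
      thresholds = thresholds, profiles = profiles, multiplex = M,
      trace = trace, partition = partition, dendrogram = dendro,
      newick = newick, bootstrap = boot, communities = communities,
      manifest = manifest
    ),
    class = "psn_pipeline"
  )
}

#' @export
print.psn_pipeline <- function(x, ...) {
  cat("<psn_pipeline>\n thresholds:\n")
  print(as.data.frame(x$thresholds), row.names = FALSE)
  print(x$trace)
  print(x$partition)
  if (!is.null(x$bootstrap)) print(as.data.frame(x$bootstrap), row.names = FALSE)
  invisible(x)
}
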