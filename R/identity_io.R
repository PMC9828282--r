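#' Percent-identity matrices
#'
#' An `identity_matrix` is a square numeric matrix of pairwise percent amino
#' acid identities `w_ij` in `[0, 100]`, with organism identifiers as row and
#' column names and a `layer_name` attribute naming the ortholog it came from.
#' A diagonal entry of 100 marks an organism as present in the layer; absent
#' organisms (after [harmonize_layers()]) carry all-zero rows and columns
#' including the diagonal, so presence is recoverable from the matrix alone.
#'
#' @param values square numeric matrix with unique row/column names, entries
#'   in `[0, 100]`.
#' @param layer_name ortholog label for the layer.
#' @return An object of class `identity_matrix` (a base matrix with
#'   attributes).
#' @examples
#' W <- identity_matrix(matrix(c(100, 55, 55, 100), 2, 2,
#'   dimnames = list(c("A", "B"), c("A", "B"))), "Cob")
#' organisms(W)
#' @export
identity_matrix <- function(values, layer_name = "layer") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("identity matrix must be square", class = "multipsn_format_error")
  }
  if (is.null(rownames(values)) && is.null(colnames(values))) {
    ids <- paste0("org", seq_len(nrow(values)))
    dimnames(values) <- list(ids, ids)
  }
  if (is.null(rownames(values))) rownames(values) <- colnames(values)
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    abort("row and column labels must agree", class = "multipsn_format_error")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate organism labels", class = "multipsn_format_error")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("identity values must be numeric and non-missing",
      class = "multipsn_format_error"
    )
  }
  if (any(values < 0 | values > 100)) {
    abort("identity values must lie in [0, 100]",
      class = "multipsn_domain_error"
    )
  }
  structure(values,
    layer_name = as.character(layer_name),
    class = c("identity_matrix", class(values))
  )
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(
    "<identity_matrix> layer:", layer_name(x), "-", nrow(x), "organisms,",
    sum(is_present(x)), "present\n"
  )
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 6))
  invisible(x)
}

#' Accessors for identity matrices and layer graphs
#'
#' `organisms()` returns the canonical ordered organism identifiers,
#' `layer_name()` the ortholog label, and `is_present()` a logical vector
#' marking organisms present in the layer (non-zero diagonal).
#'
#' @param x an `identity_matrix` or `layer_graph`.
#' @return A character vector, a string, or a named logical vector.
#' @export
organisms <- function(x) UseMethod("organisms")

#' @export
organisms.identity_matrix <- function(x) rownames(x)

#' @rdname organisms
#' @export
layer_name <- function(x) attr(x, "layer_name")

#' @rdname organisms
#' @export
is_present <- function(x) UseMethod("is_present")

#' @export
is_present.identity_matrix <- function(x) {
  setNames(diag(unclass(x)) > 0, rownames(x))
}

#' Read a labelled square identity matrix
#'
#' Reads a square percent-identity matrix with a header row and a leading
#' label column (TSV by default, CSV via `dialect`). The file is returned as
#' stored: values are *not* symmetrized, so an asymmetric matrix is preserved
#' until an explicit [symmetrize()] call.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param layer_name ortholog label; defaults to the file name without
#'   extension.
#' @return An [identity_matrix()].
#' @export
read_identity_matrix <- function(path, dialect = c("tsv", "csv"),
                                 layer_name = NULL) {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
    tsv = read.delim(path, row.names = 1, check.names = FALSE),
    csv = read.csv(path, row.names = 1, check.names = FALSE)
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort(paste0("non-numeric entries in ", path),
      class = "multipsn_format_error"
    )
  }
  if (is.null(layer_name)) {
    layer_name <- sub("\\.[^.]*$", "", basename(path))
  }
  identity_matrix(m, layer_name)
}

#' Write an identity matrix
#'
#' Writes the labelled square matrix in the same TSV/CSV layout
#' [read_identity_matrix()] consumes, so files round-trip.
#'
#' @inheritParams read_identity_matrix
#' @param W an [identity_matrix()].
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(W, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- as.data.frame(unclass(W))
  write.table(df,
    file = path, sep = sep, quote = FALSE,
    row.names = TRUE, col.names = NA
  )
  invisible(path)
}

#' Read a multiple protein alignment
#'
#' Reads an aligned FASTA or Clustal file into an `alignment_set`: a list of
#' equal-length aligned amino-acid strings keyed by organism identifier.
#' Requires the Biostrings package.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param layer_name ortholog label; defaults to the file name.
#' @return An object of class `alignment_set` with fields `layer_name`,
#'   `sequences` (named character vector) and `length` (alignment columns Y).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           layer_name = NULL) {
  format <- match.arg(format)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading alignments requires the Biostrings package")
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  if (is.null(layer_name)) layer_name <- sub("\\.[^.]*$", "", basename(path))
  alignment_set(seqs, layer_name)
}

#' @rdname read_alignment
#' @param sequences named character vector of equal-length aligned sequences.
#' @export
alignment_set <- function(sequences, layer_name = "layer") {
  sequences <- unlist(as.list(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("sequences must carry unique organism names",
      class = "multipsn_format_error"
    )
  }
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L || lens == 0L) {
    abort("aligned sequences must share one positive length",
      class = "multipsn_alignment_error"
    )
  }
  structure(
    list(
      layer_name = as.character(layer_name),
      sequences = sequences, length = lens
    ),
    class = "alignment_set"
  )
}

#' Pairwise percent identity from an alignment
#'
#' Computes `w_ij` = 100 x (columns where organisms i and j carry the same
#' non-gap residue) / denominator. With `denominator = "alignment"` (the
#' default) the denominator is the full alignment length Y, so columns with a
#' gap in either sequence count against identity but never as a match; with
#' `"pairwise"` it is the number of columns where both sequences are ungapped
#' (some aligners' convention). The diagonal is set to 100 and the result is
#' symmetric by construction.
#'
#' @param aln an `alignment_set`.
#' @param denominator `"alignment"` (all columns) or `"pairwise"`
#'   (both-ungapped columns only).
#' @return An [identity_matrix()].
#' @export
percent_identity <- function(aln, denominator = c("alignment", "pairwise")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "alignment_set"))
  if (length(aln$sequences) < 2L) {
    abort("need at least two sequences", class = "multipsn_alignment_error")
  }
  chars <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  gap <- chars == "-" | chars == "."
  n <- nrow(chars)
  W <- matrix(100, n, n, dimnames = list(names(aln$sequences), names(aln$sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- !gap[i, ] & !gap[j, ]
      matches <- sum(both & chars[i, ] == chars[j, ])
      denom <- if (denominator == "alignment") aln$length else sum(both)
      W[i, j] <- W[j, i] <- if (denom == 0) 0 else 100 * matches / denom
    }
  }
  identity_matrix(W, aln$layer_name)
}

#' Symmetrize an identity matrix
#'
#' Replaces every off-diagonal pair `w_ij`, `w_ji` by its arithmetic mean;
#' the diagonal is untouched. Idempotent.
#'
#' @param W an [identity_matrix()].
#' @return A symmetric [identity_matrix()].
#' @export
symmetrize <- function(W) {
  stopifnot(inherits(W, "identity_matrix"))
  m <- unclass(W)
  d <- diag(m)
  m <- (m + t(m)) / 2
  diag(m) <- d
  identity_matrix(m, layer_name(W))
}

#' Align multiple layers onto one organism set
#'
#' Takes per-ortholog identity matrices over possibly different organism
#' sets and reconciles them onto the union, in a single canonical order
#' (first appearance across layers). An organism absent from a layer is kept
#' there as an isolated node: its row, column and diagonal are set to zero,
#' which removes it from that layer's networks at every threshold while
#' leaving it coupled to its replicas in the multiplex.
#'
#' @param matrices list of [identity_matrix()] objects.
#' @return A list with `organisms` (canonical ids) and `layers` (the
#'   harmonized matrices, identical ordering).
#' @export
harmonize_layers <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  for (W in matrices) stopifnot(inherits(W, "identity_matrix"))
  ids <- unique(unlist(lapply(matrices, rownames)))
  if (length(ids) == 0L) {
    abort("empty organism union", class = "multipsn_input_error")
  }
  layers <- lapply(matrices, function(W) {
    out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    keep <- intersect(ids, rownames(W))
    out[keep, keep] <- unclass(W)[keep, keep]
    identity_matrix(out, layer_name(W))
  })
  names(layers) <- vapply(layers, layer_name, character(1))
  list(organisms = ids, layers = layers)
}
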