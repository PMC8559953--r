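#' Read/write connectomes as dense delimited text
#'
#' Dense adjacency matrices are stored as tab-delimited text with no header
#' or row names, one row per node.
#'
#' @param W weight matrix or `cs_connectome`.
#' @param path file path.
#' @return `read_connectome_tsv()` returns a numeric matrix.
#' @export
write_connectome_tsv <- function(W, path) {
  utils::write.table(as_weights(W), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read/write connectomes as GraphML
#'
#' Undirected weighted GraphML via igraph; node count is preserved even for
#' isolated nodes.
#'
#' @param W weight matrix or `cs_connectome`.
#' @param path file path.
#' @return `read_connectome_graphml()` returns a numeric weight matrix.
#' @export
write_connectome_graphml <- function(W, path) {
  igraph::write_graph(as_graph(W), path, format = "graphml")
  invisible(path)
}

#' @rdname write_connectome_graphml
#' @export
read_connectome_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  m <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  dimnames(m) <- NULL
  m
}

#' Load a set of externally supplied connectomes for evaluation
#'
#' Builds a `cs_connectome_set` from adjacency files plus a manifest table
#' keyed by the sample fields, so external connectomes can enter the
#' stability / discriminability / feature evaluations.
#'
#' @param paths character vector of adjacency files (`.tsv`/`.txt` dense
#'   text or `.graphml`).
#' @param index data frame with one row per file; recognized columns:
#'   subject, session, subsample, pipeline, mode, sim.
#' @return a `cs_connectome_set`.
#' @export
read_connectome_set <- function(paths, index) {
  stopifnot(length(paths) == nrow(index))
  defaults <- list(subject = 1L, session = 1L, subsample = 1L,
                   pipeline = "ext", mode = "ext", sim = 0L)
  for (f in names(defaults)) {
    if (is.null(index[[f]])) index[[f]] <- defaults[[f]]
  }
  conns <- lapply(seq_along(paths), function(i) {
    m <- if (grepl("\\.graphml$", paths[i])) {
      read_connectome_graphml(paths[i])
    } else {
      read_connectome_tsv(paths[i])
    }
    new_connectome(m, as.list(index[i, , drop = FALSE]))
  })
  structure(list(connectomes = conns,
                 index = index[, names(defaults), drop = FALSE]),
            class = "cs_connectome_set")
}

#' Write a cohort manifest
#' @param index execution index data frame.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(index, path) {
  utils::write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path)
}
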