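#' Directed pathway graph
#'
#' A `pathway_graph` is a light container for a directed graph with stable,
#' ordered node identifiers: the unit on which every centrality in this
#' package is computed. Adjacency entries are strictly 0/1 -- duplicate
#' edges collapse and self-loops are dropped at construction (with a
#' warning), because the centrality recurrences used here are defined on a
#' simple 0/1 adjacency.
#'
#' @param edges a two-column character matrix or data frame of directed
#'   edges (`source`, `target`), or a list of length-2 character vectors.
#'   May be empty if `nodes` is supplied.
#' @param nodes optional character vector of node identifiers. Nodes found
#'   in `edges` keep first-appearance order; additional isolated nodes are
#'   appended in lexicographic order.
#' @param pathway_id text label for the pathway.
#' @return an object of class `pathway_graph` with elements `pathway_id`,
#'   `nodes` (character), and `edges` (integer matrix, one row per edge,
#'   columns `from`/`to` indexing into `nodes`).
#' @examples
#' g <- pathway_graph(rbind(c("a", "b"), c("b", "c")), pathway_id = "toy")
#' degrees(g)
#' @export
pathway_graph <- function(edges = NULL, nodes = NULL, pathway_id = "pathway") {
  if (is.null(edges) || (is.list(edges) && !is.data.frame(edges) && length(edges) == 0L)) {
    em <- matrix(character(0), ncol = 2)
  } else if (is.data.frame(edges)) {
    em <- as.matrix(edges[, 1:2, drop = FALSE])
    storage.mode(em) <- "character"
  } else if (is.matrix(edges)) {
    if (ncol(edges) < 2) stop("edge matrix must have two columns (source, target)")
    em <- edges[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  } else if (is.list(edges)) {
    bad <- which(vapply(edges, length, 1L) != 2L)
    if (length(bad)) stop("malformed edge row ", bad[1], ": expected (source, target) pair")
    em <- do.call(rbind, lapply(edges, as.character))
  } else {
    stop("edges must be a two-column matrix/data.frame or a list of pairs")
  }
  if (nrow(em) == 0L && is.null(nodes)) {
    stop("empty edge list: supply an explicit node list for an edgeless graph")
  }
  if (nrow(em) > 0L) {
    empty <- !nzchar(em) | is.na(em)
    if (any(empty)) {
      stop("malformed edge row ", which(rowSums(matrix(empty, ncol = 2)) > 0)[1],
           ": empty node identifier")
    }
  }
  # node order: an explicit `nodes` vector fixes the order; otherwise first
  # appearance in the edge stream (source before target, row by row).
  # Declared-but-unseen nodes stay isolated.
  seen <- unique(as.vector(t(em)))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers in `nodes`")
    unknown <- setdiff(seen, nodes)
    if (length(unknown)) {
      stop("edge endpoint(s) not in declared node list: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    ids <- nodes
  } else {
    ids <- seen
  }
  if (nrow(em) > 0L) {
    fi <- match(em[, 1], ids)
    ti <- match(em[, 2], ids)
    loops <- fi == ti
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) removed from pathway '", pathway_id, "'")
      fi <- fi[!loops]; ti <- ti[!loops]
    }
    keep <- !duplicated(fi + ti * (length(ids) + 1L))
    eidx <- cbind(from = fi[keep], to = ti[keep])
  } else {
    eidx <- cbind(from = integer(0), to = integer(0))
  }
  structure(
    list(pathway_id = as.character(pathway_id), nodes = ids, edges = eidx),
    class = "pathway_graph"
  )
}

#' Build a pathway graph from an edge list
#'
#' Convenience wrapper around [pathway_graph()] matching the package's
#' TSV edge-list layout. Nodes are ordered by first appearance in the edge
#' stream; nodes listed in `nodes` but absent from the edges are appended
#' in lexicographic order as isolated nodes.
#'
#' @param rows sequence of (source, target) pairs: a two-column
#'   matrix/data frame or list of length-2 vectors.
#' @param pathway_id text label.
#' @param nodes optional explicit node list (for isolated nodes).
#' @return a `pathway_graph`.
#' @export
from_edge_list <- function(rows, pathway_id = "pathway", nodes = NULL) {
  no_rows <- is.null(rows) || (is.list(rows) && !is.data.frame(rows) && !length(rows)) ||
    ((is.matrix(rows) || is.data.frame(rows)) && nrow(rows) == 0L)
  if (no_rows) {
    return(pathway_graph(NULL, nodes = sort(as.character(nodes)),
                         pathway_id = pathway_id))
  }
  g <- pathway_graph(rows, nodes = NULL, pathway_id = pathway_id)
  if (!is.null(nodes)) {
    extra <- sort(setdiff(as.character(nodes), g$nodes))
    if (length(extra)) {
      g <- pathway_graph(cbind(g$nodes[g$edges[, "from"]],
                               g$nodes[g$edges[, "to"]]),
                         nodes = c(g$nodes, extra), pathway_id = pathway_id)
    }
  }
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges
#' @param g a `pathway_graph`.
#' @return integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Transpose a directed graph
#'
#' Reverses every edge direction; the node set and node order are
#' unchanged, so `transpose_graph(transpose_graph(g))` reproduces `g`.
#'
#' @param g a `pathway_graph`.
#' @return the transposed `pathway_graph`.
#' @export
transpose_graph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  g$edges <- cbind(from = g$edges[, "to"], to = g$edges[, "from"])
  g
}

#' Underlying undirected graph
#'
#' Projects a directed graph onto its underlying undirected graph,
#' represented as a symmetric directed graph (both orientations of every
#' edge) so that all centrality code paths apply unchanged. The result is
#' idempotent under re-projection and equal to its own transpose.
#'
#' @param g a `pathway_graph`.
#' @return a symmetric `pathway_graph`.
#' @export
underlying_undirected <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  e <- rbind(g$edges, cbind(from = g$edges[, "to"], to = g$edges[, "from"]))
  keep <- !duplicated(e[, 1] + e[, 2] * (length(g$nodes) + 1L))
  g$edges <- e[keep, , drop = FALSE]
  g
}

#' Out- and in-degrees
#'
#' @param g a `pathway_graph`.
#' @return list with numeric vectors `out` and `in_` (aligned to
#'   `g$nodes`); `sum(out) == sum(in_) == n_edges(g)`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  n <- length(g$nodes)
  list(
    out = tabulate(g$edges[, "from"], nbins = n),
    in_ = tabulate(g$edges[, "to"], nbins = n)
  )
}

#' Adjacency matrix
#'
#' Dense 0/1 adjacency with `A[i, j] = 1` iff the edge (node i -> node j)
#' is present; rows/columns follow the graph's stable node order.
#'
#' @param g a `pathway_graph`.
#' @return an `n x n` base matrix with node-id dimnames.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) A[g$edges] <- 1
  A
}

#' Adjacency bundle
#'
#' The adjacency matrix together with the clamped diagonal degree
#' matrices used by the spectral centralities: `D_out` has entries
#' `max(out-degree, 1)` and `D_in` has entries `max(in-degree, 1)`.
#' Clamping applies only inside these matrices, never to degree
#' centrality itself.
#'
#' @param g a `pathway_graph`.
#' @return list with `A`, and numeric diagonal vectors `d_out`, `d_in`
#'   (the diagonals of `D_out`/`D_in`).
#' @export
adjacency_bundle <- function(g) {
  d <- degrees(g)
  list(A = adjacency_matrix(g), d_out = pmax(d$out, 1), d_in = pmax(d$in_, 1))
}

#' Spectral radius of the adjacency matrix
#'
#' Largest eigenvalue modulus of the 0/1 adjacency; by Perron-Frobenius
#' this is a non-negative real and equals the largest positive eigenvalue
#' for a non-negative matrix. Used by the pathway eigenvalue filter and
#' the Katz convergence precondition. Dense eigendecomposition is used up
#' to 200 nodes; power iteration (tolerance 1e-9) above, falling back to
#' the dense routine if the iteration stalls.
#'
#' @param g a `pathway_graph` (non-empty).
#' @return non-negative scalar.
#' @export
spectral_radius <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  n <- length(g$nodes)
  if (n == 0L) stop("spectral radius of an empty graph is undefined")
  if (nrow(g$edges) == 0L) return(0)
  A <- adjacency_matrix(g)
  if (n <= 200L) {
    return(max(Mod(eigen(A, only.values = TRUE)$values)))
  }
  # power iteration on A^T A is unreliable for the modulus of complex
  # spectra; iterate on A directly and monitor the Rayleigh-style ratio
  x <- rep(1, n)
  lam <- 0
  for (k in seq_len(5000L)) {
    y <- as.vector(A %*% x)
    ny <- sqrt(sum(y * y))
    if (ny == 0) return(0)  # nilpotent: trajectory died out
    lam_new <- ny / sqrt(sum(x * x))
    x <- y / ny
    if (abs(lam_new - lam) < 1e-9 * max(1, lam_new)) return(lam_new)
    lam <- lam_new
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Read / write edge-list TSV
#'
#' Two or three tab-separated columns `source  target  [interaction-type]`;
#' lines starting with `#` are ignored. The third column, when present, is
#' ignored on read (edges here are unweighted and untyped).
#'
#' @param path file path.
#' @param pathway_id pathway label; defaults to the file name without
#'   extension.
#' @return `read_edge_list`: a `pathway_graph`; `write_edge_list`: the
#'   path, invisibly.
#' @export
read_edge_list <- function(path, pathway_id = NULL) {
  if (!file.exists(path)) stop("no such edge-list file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (is.null(pathway_id)) pathway_id <- sub("\\.[^.]*$", "", basename(path))
  if (!length(lines)) stop("edge-list file has no data rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L)) {
    stop("malformed edge-list row ", which(nf < 2L)[1], " in ", path,
         ": expected at least 2 tab-separated fields")
  }
  em <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  pathway_graph(em, pathway_id = pathway_id)
}

#' @rdname read_edge_list
#' @param g a `pathway_graph` to write.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# pathway: ", g$pathway_id), con)
  if (nrow(g$edges)) {
    writeLines(paste(g$nodes[g$edges[, "from"]], g$nodes[g$edges[, "to"]],
                     sep = "\t"), con)
  }
  invisible(path)
}
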