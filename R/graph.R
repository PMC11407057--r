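#' Construct a molecular graph
#'
#' A molecular graph is a labelled simple undirected graph: atoms are
#' vertices (with an element label), bonds are edges.  Hydrogens are not
#' represented.  Self-loops and duplicate bonds are rejected.
#'
#' @param vertices a data.frame with columns `id` (unique integers) and
#'   `element` (character labels such as `"Bi"`, `"I"`, `"C"`, `"X"`), or a
#'   named character vector of elements whose names are the ids.
#' @param edges a two-column matrix or data.frame of vertex-id pairs, or a
#'   list of length-2 vectors.  Order within a pair is irrelevant.
#' @return an object of class `"molgraph"` with components `ids` (sorted
#'   integer vector), `elements` (character vector parallel to `ids`) and
#'   `edges` (two-column integer matrix, each row `(min, max)`-normalised,
#'   rows sorted; zero rows for an edgeless graph).
#' @examples
#' g <- make_graph(data.frame(id = 1:2, element = c("Bi", "I")),
#'                 edges = rbind(c(1, 2)))
#' n_edges(g)
#' @export
make_graph <- function(vertices, edges = NULL) {
  if (is.data.frame(vertices)) {
    if (!all(c("id", "element") %in% names(vertices)))
      stop("`vertices` data.frame needs columns `id` and `element`")
    ids <- as.integer(vertices$id)
    elements <- as.character(vertices$element)
  } else {
    ids <- as.integer(names(vertices))
    elements <- as.character(vertices)
  }
  if (anyNA(ids)) stop("vertex ids must be integers")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate vertex id: ", paste(unique(dup), collapse = ", "))
  ord <- order(ids)
  ids <- ids[ord]; elements <- elements[ord]

  em <- normalize_edges(edges)
  if (nrow(em)) {
    loops <- em[, 1] == em[, 2]
    if (any(loops))
      stop("self-loop at vertex ", paste(unique(em[loops, 1]), collapse = ", "))
    unknown <- setdiff(c(em), ids)
    if (length(unknown))
      stop("edge endpoint not a declared vertex: ",
           paste(unknown, collapse = ", "))
    key <- paste(em[, 1], em[, 2])
    if (anyDuplicated(key)) {
      bad <- em[duplicated(key), , drop = FALSE][1, ]
      stop("duplicate edge: (", bad[1], ", ", bad[2], ")")
    }
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  }
  structure(list(ids = ids, elements = elements, edges = em),
            class = "molgraph")
}

# Coerce the accepted edge inputs to an n x 2 integer matrix with
# each row sorted ascending.
normalize_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (is.matrix(edges) && nrow(edges) == 0) ||
      (is.list(edges) && length(edges) == 0)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, as.integer))
  em <- as.matrix(edges)
  if (ncol(em) != 2) stop("edges must have two columns")
  storage.mode(em) <- "integer"
  if (anyNA(em)) stop("edge endpoints must be integers")
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  colnames(em) <- c("from", "to")
  em
}

#' @export
print.molgraph <- function(x, ...) {
  tab <- table(x$elements)
  cat("Molecular graph: ", length(x$ids), " atoms, ", nrow(x$edges),
      " bonds\n", sep = "")
  cat("  elements:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Number of vertices / edges of a molecular graph
#' @param g a `molgraph`
#' @return an integer count
#' @export
n_vertices <- function(g) length(g$ids)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' Vertex degrees
#' @param g a `molgraph`
#' @return named integer vector of degrees, in ascending id order
#' @export
graph_degrees <- function(g) {
  d <- integer(length(g$ids))
  names(d) <- g$ids
  if (nrow(g$edges)) {
    t1 <- table(factor(g$edges[, 1], levels = g$ids))
    t2 <- table(factor(g$edges[, 2], levels = g$ids))
    d <- as.integer(t1 + t2)
    names(d) <- g$ids
  }
  d
}

#' Adjacency matrix of a molecular graph
#'
#' Returns the dense symmetric 0/1 adjacency matrix under ascending
#' vertex-id ordering (the ordering affects only the matrix layout; every
#' descriptor in this package is spectral and hence permutation-invariant).
#'
#' @param g a `molgraph`
#' @return a base integer matrix with zero diagonal; dimnames are the
#'   vertex ids.
#' @examples
#' adjacency_matrix(reference_graph("path", 2))
#' @export
adjacency_matrix <- function(g) {
  nv <- length(g$ids)
  a <- matrix(0L, nv, nv, dimnames = list(g$ids, g$ids))
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1], g$ids)
    j <- match(g$edges[, 2], g$ids)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

# Internal: igraph view of a molgraph (vertex order = ascending id).
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$ids), directed = FALSE)
  if (nrow(g$edges)) {
    idx <- rbind(match(g$edges[, 1], g$ids), match(g$edges[, 2], g$ids))
    ig <- igraph::add_edges(ig, as.vector(idx))
  }
  ig
}

#' Test bipartiteness and extract a 2-colouring
#'
#' Bipartite molecular graphs have spectra symmetric about zero, hence
#' signature 0 and equal positive/negative inertia — the pattern seen in
#' both lattice families here.
#'
#' @param g a `molgraph`
#' @return a list with `bipartite` (logical) and, when `TRUE`, `parts`:
#'   a list of two vectors of vertex ids (part containing the smallest id
#'   first); when `FALSE`, `parts` is `NULL`.
#' @examples
#' is_bipartite_graph(reference_graph("cycle", 6))$bipartite  # TRUE
#' is_bipartite_graph(reference_graph("cycle", 5))$bipartite  # FALSE
#' @export
is_bipartite_graph <- function(g) {
  ig <- as_igraph(g)
  bm <- igraph::bipartite_mapping(ig)
  if (!bm$res) return(list(bipartite = FALSE, parts = NULL))
  type <- bm$type
  p1 <- g$ids[!type]; p2 <- g$ids[type]
  if (length(p2) && (!length(p1) || min(p2) < min(p1))) {
    tmp <- p1; p1 <- p2; p2 <- tmp
  }
  list(bipartite = TRUE, parts = list(p1, p2))
}

#' Is the graph connected?
#' @param g a `molgraph`
#' @return logical
#' @export
is_connected_graph <- function(g) {
  if (length(g$ids) <= 1) return(TRUE)
  igraph::is_connected(as_igraph(g))
}
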