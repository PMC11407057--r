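#' Read and write molecular graphs as edge-list TSV
#'
#' The dialect is a plain tab-separated file:
#' * lines starting with `#` are comments,
#' * vertex lines are `V<TAB>id<TAB>element`,
#' * edge lines are `id1<TAB>id2` (two integer fields),
#' * blank lines are ignored.
#'
#' Vertices referenced only by edges are not implied: every vertex must be
#' declared in a `V` line, so isolated atoms round-trip faithfully.
#' `write_edge_list()` followed by `read_edge_list()` reproduces the graph
#' exactly (ids, elements, edge set).
#'
#' @param path file path
#' @param g a `molgraph`
#' @return `read_edge_list()` returns a `molgraph`; `write_edge_list()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_edge_list(reference_graph("path", 3), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  vid <- integer(0); vel <- character(0)
  ef <- integer(0); et <- integer(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (fields[1] == "V") {
      if (length(fields) != 3)
        stop("line ", k, ": vertex line needs 3 fields (V, id, element)")
      id <- suppressWarnings(as.integer(fields[2]))
      if (is.na(id)) stop("line ", k, ": non-integer vertex id '",
                          fields[2], "'")
      vid <- c(vid, id); vel <- c(vel, fields[3])
    } else {
      if (length(fields) != 2)
        stop("line ", k, ": edge line needs 2 fields, got ",
             length(fields))
      ab <- suppressWarnings(as.integer(fields))
      if (anyNA(ab)) stop("line ", k, ": non-integer vertex id in edge '",
                          ln, "'")
      ef <- c(ef, ab[1]); et <- c(et, ab[2])
    }
  }
  make_graph(data.frame(id = vid, element = vel),
             if (length(ef)) cbind(ef, et) else NULL)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "molgraph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# molecular graph edge list (latticespectra)", con)
  writeLines(paste("V", g$ids, g$elements, sep = "\t"), con)
  if (nrow(g$edges))
    writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), con)
  invisible(path)
}

#' Write an adjacency matrix to disk
#'
#' `"matrix-market"` writes the sparse coordinate symmetric *pattern*
#' format (1-based indices, lower triangle) via the Matrix package;
#' `"csv"` writes the dense 0/1 matrix with an id header column.
#'
#' @param g a `molgraph`
#' @param path output file
#' @param format `"matrix-market"` or `"csv"`
#' @return `path`, invisibly
#' @export
write_adjacency <- function(g, path, format = c("matrix-market", "csv")) {
  if (!is.character(format) || !format[1] %in% c("matrix-market", "csv"))
    stop("unknown adjacency format '", format[1],
         "'; supported: matrix-market, csv")
  format <- format[1]
  if (format == "matrix-market") {
    nv <- length(g$ids)
    i <- match(g$edges[, 2], g$ids)  # row > col: lower triangle
    j <- match(g$edges[, 1], g$ids)
    sm <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                               dims = c(nv, nv), symmetric = TRUE)
    Matrix::writeMM(methods::as(sm, "nMatrix"), path)
  } else {
    a <- adjacency_matrix(g)
    utils::write.csv(as.data.frame(a), path, row.names = TRUE)
  }
  invisible(path)
}

#' Read a graph from a Matrix Market adjacency matrix
#'
#' Accepts any Matrix Market matrix readable by [Matrix::readMM()] whose
#' nonzero pattern is symmetric with zero diagonal.  All atoms get the
#' generic element label `"X"` and ids `1..n`.
#'
#' @param path Matrix Market file
#' @return a `molgraph`
#' @export
read_adjacency_graph <- function(path) {
  m <- Matrix::readMM(path)
  m <- methods::as(m, "TsparseMatrix")
  n <- nrow(m)
  if (ncol(m) != n) stop("adjacency matrix must be square")
  i <- m@i + 1L; j <- m@j + 1L
  if (any(i == j)) stop("adjacency matrix has a nonzero diagonal")
  keep <- i > j
  em <- cbind(i, j)
  em2 <- unique(rbind(em[keep, , drop = FALSE],
                      em[!keep, c(2, 1), drop = FALSE]))
  if (!isSymmetric(unname(as.matrix(m != 0))))
    stop("adjacency pattern is not symmetric")
  make_graph(data.frame(id = seq_len(n), element = "X"), em2)
}
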