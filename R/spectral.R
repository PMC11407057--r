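#' Adjacency spectrum of a graph or symmetric matrix
#'
#' Computes all eigenvalues of the (symmetric 0/1) adjacency matrix with
#' the dense symmetric eigensolver and records the tolerance used to
#' classify eigenvalues as zero.  The default tolerance is
#' `1e-8 * max(1, lambda_1)`: adjacency spectra of the lattice families
#' treated here are well separated at that scale, and it can be
#' overridden per call.
#'
#' @param x a `molgraph` or a symmetric numeric matrix
#' @param zero_tol non-negative zero-classification tolerance; `NULL`
#'   (default) selects `1e-8 * max(1, lambda_1)`
#' @return an object of class `"spectrum"`: list with `values`
#'   (eigenvalues sorted descending), `zero_tol` and `order` (matrix
#'   order)
#' @examples
#' spectrum_of(reference_graph("star", 5))$values   # 2, 0, 0, 0, -2
#' @export
spectrum_of <- function(x, zero_tol = NULL) {
  if (inherits(x, "molgraph")) x <- adjacency_matrix(x)
  if (!is.matrix(x) || !isSymmetric(unname(x * 1.0)))
    stop("input must be a molgraph or a symmetric matrix")
  vals <- if (nrow(x) == 0) numeric(0)
          else sort(eigen(x, symmetric = TRUE, only.values = TRUE)$values,
                    decreasing = TRUE)
  if (is.null(zero_tol))
    zero_tol <- 1e-8 * max(1, if (length(vals)) abs(vals[1]) else 0)
  if (zero_tol < 0) stop("zero_tol must be non-negative")
  structure(list(values = vals, zero_tol = zero_tol, order = nrow(x)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Adjacency spectrum, order ", x$order,
      " (zero tolerance ", format(x$zero_tol), ")\n", sep = "")
  print(round(x$values, 6))
  invisible(x)
}

as_spectrum <- function(x) {
  if (inherits(x, "spectrum")) x else spectrum_of(x)
}

#' Graph energy
#'
#' The energy of a molecular graph is the sum of the absolute values of
#' its adjacency eigenvalues, `E(G) = sum |lambda_i|` — in Hückel theory a
#' proxy for total pi-electron energy.
#'
#' @param x a `spectrum`, `molgraph` or symmetric matrix
#' @return non-negative scalar; 0 exactly for edgeless graphs
#' @examples
#' graph_energy(reference_graph("cycle", 6))   # 8
#' @export
graph_energy <- function(x) sum(abs(as_spectrum(x)$values))

#' Estrada index
#'
#' `EE(G) = sum exp(lambda_i)` over the adjacency eigenvalues; equals the
#' vertex count for edgeless graphs.
#'
#' @inheritParams graph_energy
#' @return positive scalar
#' @examples
#' estrada_index(reference_graph("path", 2))   # exp(1) + exp(-1)
#' @export
estrada_index <- function(x) sum(exp(as_spectrum(x)$values))

#' Inertia indices and nullity
#'
#' Partitions the spectrum with the recorded zero tolerance:
#' `lambda > tol` counts toward the positive inertia index `p`,
#' `|lambda| <= tol` toward the nullity `eta`, `lambda < -tol` toward the
#' negative inertia index `n`.  Nonzero nullity marks open-shell
#' (reactive) character of the molecule, zero nullity a closed shell.
#'
#' @inheritParams graph_energy
#' @return named integer vector `c(p_plus, eta, n_minus)`
#' @examples
#' inertia_of(reference_graph("star", 5))   # 1, 3, 1
#' @export
inertia_of <- function(x) {
  s <- as_spectrum(x)
  c(p_plus = sum(s$values > s$zero_tol),
    eta = sum(abs(s$values) <= s$zero_tol),
    n_minus = sum(s$values < -s$zero_tol))
}

#' Signature and rank of the adjacency matrix
#'
#' `signature = p - n`, `rank = p + n` in terms of the inertia indices.
#' Bipartite graphs have symmetric spectra, hence signature 0.
#'
#' @inheritParams graph_energy
#' @return named integer vector `c(signature, rank)`
#' @export
signature_rank <- function(x) {
  i <- inertia_of(x)
  c(signature = unname(i["p_plus"] - i["n_minus"]),
    rank = unname(i["p_plus"] + i["n_minus"]))
}

#' Descriptor sweep over a lattice family
#'
#' Runs the full pipeline — generate the structure, build its adjacency
#' matrix, compute the spectrum, derive all descriptors — for each `n` in
#' `n_range` at fixed `m` (for the reference families, `n_range` is the
#' vertex count `k` and `m` is ignored).
#'
#' @param structure `"bii3"`, `"bre"`, or a reference family name
#'   (`"path"`, `"cycle"`, `"star"`, `"complete"`, `"empty"`)
#' @param m horizontal unit-cell count (lattice families)
#' @param n_range integer vector of vertical unit-cell counts (or vertex
#'   counts for reference families)
#' @param zero_tol passed to [spectrum_of()]
#' @param rules optional rule list overriding the builtin tiling rules
#' @return a data.frame of class `"descriptor_table"` with columns
#'   `m, n, n_vertices, n_edges, energy, estrada, p, n_minus, eta,
#'   signature, rank`
#' @examples
#' descriptor_sweep("bii3", m = 3, n_range = 1:2)
#' @export
descriptor_sweep <- function(structure, m = NA, n_range, zero_tol = NULL,
                             rules = NULL) {
  if (length(n_range) == 0) stop("n_range must be non-empty")
  rows <- lapply(n_range, function(n) {
    g <- generate_structure(structure, m, n, rules)
    s <- spectrum_of(g, zero_tol = zero_tol)
    i <- inertia_of(s); sr <- signature_rank(s)
    data.frame(m = m, n = n, n_vertices = n_vertices(g),
               n_edges = n_edges(g),
               energy = graph_energy(s), estrada = estrada_index(s),
               p = unname(i["p_plus"]), n_minus = unname(i["n_minus"]),
               eta = unname(i["eta"]), signature = unname(sr["signature"]),
               rank = unname(sr["rank"]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("descriptor_table", "data.frame")
  out
}

# Internal dispatcher shared by the sweep, the calibration report and the
# CLI.
generate_structure <- function(structure, m, n, rules = NULL) {
  switch(structure,
    bii3 = bii3_sheet(m, n, rules %||% bii3_rules()),
    bre = benzene_ptype(m, n, rules %||% bre_rules()),
    path = ,
    cycle = ,
    star = ,
    complete = ,
    empty = reference_graph(structure, n),
    stop("unknown structure '", structure,
         "'; supported: bii3, bre, path, cycle, star, complete, empty"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a descriptor table as CSV
#'
#' Column layout `m,n,energy,estrada,p,n_minus,eta,signature,rank`
#' (vertex/edge counts included for convenience); full precision.
#'
#' @param d a `descriptor_table` from [descriptor_sweep()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_descriptors <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}
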