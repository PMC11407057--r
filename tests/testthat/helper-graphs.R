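# Shared test helpers: random graphs and the characteristic-polynomial
# eigenvalue oracle (independent of the symmetric eigensolver path).

random_molgraph <- function(nv, p_edge = 0.3) {
  pairs <- t(combn(nv, 2))
  keep <- runif(nrow(pairs)) < p_edge
  make_graph(data.frame(id = seq_len(nv), element = "X"),
             if (any(keep)) pairs[keep, , drop = FALSE] else NULL)
}

# Eigenvalues as roots of the exactly-expanded characteristic polynomial
# (Faddeev-LeVerrier via pracma::charpoly, roots via base polyroot).
charpoly_eigenvalues <- function(a) {
  cf <- pracma::charpoly(a)          # descending powers, monic
  if (length(cf) == 1) return(numeric(0))
  r <- polyroot(rev(cf))
  sort(Re(r), decreasing = TRUE)
}

# Relabel the vertices of a molgraph by a random permutation of new ids.
relabel_graph <- function(g, new_ids) {
  map <- setNames(new_ids, g$ids)
  em <- g$edges
  if (nrow(em)) em <- cbind(map[as.character(em[, 1])],
                            map[as.character(em[, 2])])
  make_graph(data.frame(id = new_ids, element = g$elements),
             if (nrow(g$edges)) em else NULL)
}

expect_spectra_equal <- function(g, expected, tol = 1e-8) {
  expect_equal(spectrum_of(g)$values, expected, tolerance = tol)
}
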