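test_that("small-graph spectra match their closed forms", {
  expect_spectra_equal(reference_graph("path", 2), c(1, -1))
  expect_spectra_equal(reference_graph("star", 5), c(2, 0, 0, 0, -2))
  expect_spectra_equal(reference_graph("cycle", 6),
                       c(2, 1, 1, -1, -1, -2))
  expect_spectra_equal(reference_graph("path", 3), c(sqrt(2), 0, -sqrt(2)))
  expect_error(spectrum_of(rbind(c(0, 1), c(0, 0))), "symmetric")
})

test_that("energy and Estrada index match closed-form values", {
  expect_equal(graph_energy(reference_graph("path", 2)), 2)
  expect_equal(graph_energy(reference_graph("cycle", 6)), 8)
  expect_equal(graph_energy(reference_graph("path", 3)), 2 * sqrt(2),
               tolerance = 1e-10)
  expect_equal(graph_energy(reference_graph("empty", 5)), 0)

  expect_equal(estrada_index(reference_graph("empty", 4)), 4)
  expect_equal(estrada_index(reference_graph("path", 2)),
               exp(1) + exp(-1), tolerance = 1e-10)
  expect_equal(estrada_index(reference_graph("cycle", 6)),
               exp(2) + 2 * exp(1) + 2 * exp(-1) + exp(-2),
               tolerance = 1e-10)
})

test_that("inertia, signature and rank partition the spectrum", {
  expect_equal(unname(inertia_of(reference_graph("star", 5))), c(1, 3, 1))
  expect_equal(unname(inertia_of(reference_graph("cycle", 6))), c(3, 0, 3))
  expect_equal(unname(inertia_of(reference_graph("path", 3))), c(1, 1, 1))
  expect_equal(unname(signature_rank(reference_graph("star", 5))), c(0, 2))
  expect_equal(unname(signature_rank(reference_graph("path", 3))), c(0, 2))
  expect_equal(unname(signature_rank(reference_graph("cycle", 6))), c(0, 6))

  set.seed(7)
  for (trial in 1:10) {
    g <- random_molgraph(sample(4:20, 1))
    i <- inertia_of(g); sr <- signature_rank(g)
    expect_equal(sum(i), n_vertices(g))
    expect_equal(unname(sr["signature"]),
                 unname(i["p_plus"] - i["n_minus"]))
    expect_equal(unname(sr["rank"]), unname(i["p_plus"] + i["n_minus"]))
  }
})

test_that("eigensolver agrees with the characteristic-polynomial oracle", {
  graphs <- list(reference_graph("path", 5),
                 reference_graph("cycle", 7),
                 reference_graph("star", 9),
                 reference_graph("complete", 6),
                 reference_graph("cycle", 12))
  set.seed(11)
  graphs <- c(graphs, lapply(1:5, function(i) random_molgraph(12)))
  for (g in graphs) {
    a <- adjacency_matrix(g)
    oracle <- charpoly_eigenvalues(a)
    s <- spectrum_of(g)
    # polyroot resolves individual high-multiplicity roots only to ~1e-6,
    # but the errors cancel in the descriptor sums
    expect_equal(s$values, oracle, tolerance = 1e-4)
    expect_equal(graph_energy(s), sum(abs(oracle)), tolerance = 1e-8)
    expect_equal(estrada_index(s), sum(exp(oracle)), tolerance = 1e-8)
  }
})

test_that("trace identities hold on random graphs", {
  set.seed(123)
  for (trial in 1:30) {
    g <- random_molgraph(sample(5:40, 1))
    v <- spectrum_of(g)$values
    expect_equal(sum(v), 0, tolerance = 1e-8)
    scale <- max(1, 2 * n_edges(g))
    expect_equal(sum(v^2) / scale, 2 * n_edges(g) / scale,
                 tolerance = 1e-8)
  }
})

test_that("Estrada index agrees with the truncated trace series", {
  for (g in list(reference_graph("cycle", 8),
                 reference_graph("path", 10),
                 bii3_sheet(1, 1))) {
    a <- adjacency_matrix(g) * 1.0
    if (abs(spectrum_of(g)$values[1]) > 6) next
    acc <- diag(nrow(a))
    total <- sum(diag(acc))
    for (k in 1:30) {
      acc <- acc %*% a / k
      total <- total + sum(diag(acc))
    }
    expect_equal(estrada_index(g), total, tolerance = 1e-6)
  }
})

test_that("bipartite spectra are symmetric about zero", {
  for (g in list(bii3_sheet(2, 2), benzene_ptype(2, 1),
                 reference_graph("path", 7),
                 reference_graph("cycle", 8))) {
    v <- spectrum_of(g)$values
    expect_equal(v, -rev(v), tolerance = 1e-8)
    i <- inertia_of(g)
    expect_equal(unname(i["p_plus"]), unname(i["n_minus"]))
    expect_equal(unname(signature_rank(g)["signature"]), 0)
  }
})

test_that("descriptors are invariant under vertex relabelling", {
  set.seed(99)
  for (trial in 1:5) {
    g <- random_molgraph(sample(5:25, 1))
    perm <- sample(1000, n_vertices(g))
    h <- relabel_graph(g, perm)
    expect_equal(spectrum_of(h)$values, spectrum_of(g)$values,
                 tolerance = 1e-10)
    expect_equal(graph_energy(h), graph_energy(g), tolerance = 1e-10)
    expect_equal(estrada_index(h), estrada_index(g), tolerance = 1e-10)
    expect_identical(inertia_of(h), inertia_of(g))
  }
})

test_that("descriptor_sweep runs the full pipeline", {
  d <- descriptor_sweep("bii3", m = 3, n_range = 1:3)
  expect_equal(nrow(d), 3)
  expect_true(all(diff(d$energy) > 0))  # energy grows with lattice size
  expect_equal(d$p + d$n_minus + d$eta, d$n_vertices)
  expect_equal(d$rank, d$p + d$n_minus)

  dc <- descriptor_sweep("cycle", n_range = 6)
  expect_equal(dc$energy, 8, tolerance = 1e-10)

  expect_error(descriptor_sweep("bii3", 3, integer(0)), "non-empty")
  expect_error(descriptor_sweep("nope", 3, 1:2), "unknown structure")
})

test_that("descriptor CSV round-trips through write_descriptors", {
  d <- descriptor_sweep("cycle", n_range = c(4, 6, 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(d, f)
  d2 <- read.csv(f)
  expect_equal(d2$energy, d$energy, tolerance = 1e-12)
  expect_true(all(c("m", "n", "energy", "estrada", "p", "n_minus",
                    "eta", "signature", "rank") %in% names(d2)))
})
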