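test_that("surface basis rows follow the fixed term order", {
  expect_equal(unname(surface_basis(1, 1)[1, ]), rep(1, 9))
  expect_equal(unname(surface_basis(2, 3)[1, ]),
               c(36, 18, 9, 12, 6, 3, 4, 2, 1))
  expect_error(surface_basis(0, 1), ">= 1")
})

test_that("noiseless grid data recovers the generating coefficients", {
  set.seed(2024)
  for (trial in 1:10) {
    theta <- rnorm(9, sd = 5)
    d <- expand.grid(m = 1:4, n = 1:4)
    d$energy <- drop(surface_basis(d$m, d$n) %*% theta)
    fit <- fit_surface(d)
    expect_lt(max(abs(unname(coef(fit)) - theta)), 1e-8)
    expect_lt(fit$sse, 1e-16)
  }
})

test_that("rank-deficient designs raise identifiability errors", {
  d22 <- expand.grid(m = 1:2, n = 1:2); d22$energy <- 1
  expect_error(fit_surface(d22), "at least 9 observations")
  d29 <- expand.grid(m = 1:2, n = 1:5); d29$energy <- rnorm(10)
  expect_error(fit_surface(d29), "3 distinct m")
  d92 <- expand.grid(m = 1:5, n = 1:2); d92$energy <- rnorm(10)
  expect_error(fit_surface(d92), "3 distinct n")
})

test_that("noise-corrupted fits improve with grid size", {
  set.seed(5)
  theta <- rnorm(9)
  err_for <- function(k) {
    d <- expand.grid(m = 1:k, n = 1:k)
    d$energy <- drop(surface_basis(d$m, d$n) %*% theta) +
      rnorm(nrow(d), sd = 0.1)
    max(abs(unname(coef(fit_surface(d))) - theta))
  }
  e4 <- mean(replicate(5, err_for(4)))
  e8 <- mean(replicate(5, err_for(8)))
  expect_lt(e8, e4)
})

test_that("residuals are orthogonal to the design columns", {
  set.seed(6)
  d <- expand.grid(m = 1:5, n = 1:5)
  d$energy <- drop(surface_basis(d$m, d$n) %*% rnorm(9)) + rnorm(25)
  fit <- fit_surface(d)
  X <- surface_basis(d$m, d$n)
  expect_lt(max(abs(crossprod(X, residuals(fit)))) /
              max(abs(crossprod(X, d$energy))), 1e-8)
})

test_that("evaluate_surface and reduce_at_m are consistent", {
  set.seed(8)
  for (trial in 1:10) {
    model <- paper_model("E_BII3")
    model$coefficients[] <- rnorm(9)
    for (m in sample(1:10, 3)) {
      q <- reduce_at_m(model, m)
      n <- 1:10
      expect_equal(eval_quadratic(q, n), evaluate_surface(model, m, n),
                   tolerance = 1e-12)
    }
  }
  only_c9 <- paper_model("E_BII3")
  only_c9$coefficients[] <- c(rep(0, 8), 5)
  q <- reduce_at_m(only_c9, 7)
  expect_equal(c(q$a2, q$a1, q$a0), c(0, 0, 5))
  expect_error(reduce_at_m(only_c9, 0), "positive integer")
})

test_that("builtin models carry the published coefficients", {
  e_bii3 <- coef(paper_model("E_BII3"))
  expect_equal(unname(e_bii3["mn"]), 13.794)
  expect_equal(unname(e_bii3["const"]), -0.3239)
  ee_bre <- coef(paper_model("EE_BRE"))
  expect_equal(unname(ee_bre["mn"]), 70.062)
  expect_equal(unname(ee_bre["n"]), 2.193)
  expect_error(paper_model("E_FOO"), "E_BII3, EE_BII3, E_BRE, EE_BRE")
})

test_that("the BiI3 energy model reproduces its published estimates", {
  model <- paper_model("E_BII3")
  expect_equal(round_half_away(evaluate_surface(model, 3, 2)), 116.989)
  expect_equal(round_half_away(evaluate_surface(model, 3, 10)), 524.431)
  expect_equal(round_half_away(evaluate_surface(model, 3, 3)), 167.919)
  # full published column for n = 2..10 to printed precision (the n = 1
  # row is a documented inconsistency of the source table)
  t2 <- paper_table("table2_energy_bii3")
  est <- evaluate_surface(model, 3, 2:10)
  expect_lt(max(abs(est - t2$estimated[2:10])), 1e-3)

  q3 <- reduce_at_m(model, 3)
  expect_equal(c(q3$a2, q3$a1, q3$a0), c(3.0063e-5, 50.9299, 15.1294),
               tolerance = 1e-10)
})

test_that("fitting generated BiI3 energies gives a near-perfect surface", {
  grid <- do.call(rbind, lapply(1:4, function(mm)
    descriptor_sweep("bii3", m = mm, n_range = 1:4)))
  fit <- fit_surface(grid, value = "energy", structure_tag = "bii3")
  expect_gte(fit$r_squared, 0.9999)
})

test_that("surface models serialize and restore at full precision", {
  set.seed(10)
  d <- expand.grid(m = 1:4, n = 1:4)
  d$energy <- drop(surface_basis(d$m, d$n) %*% rnorm(9))
  fit <- fit_surface(d, structure_tag = "synthetic")
  f <- withr::local_tempfile(fileext = ".txt")
  write_surface_model(fit, f)
  back <- read_surface_model(f)
  expect_equal(coef(back), coef(fit), tolerance = 0)
  expect_equal(back$property_tag, "energy")
  expect_equal(back$structure_tag, "synthetic")
})

test_that("model methods behave like a classed fit object", {
  d <- expand.grid(m = 1:4, n = 1:4)
  d$energy <- 2 * d$m * d$n + 1
  fit <- fit_surface(d)
  expect_output(print(fit), "Bilinear-quadratic")
  expect_output(print(summary(fit)), "Observations: 16")
  expect_equal(length(coef(fit)), 9)
  expect_equal(unname(predict(fit, data.frame(m = 2, n = 3))), 13,
               tolerance = 1e-8)
  expect_equal(fitted(fit), d$energy, tolerance = 1e-8)
  expect_equal(unname(predict(fit)), d$energy, tolerance = 1e-8)
})

test_that("rounding helpers implement both printed conventions", {
  expect_equal(round_half_away(2.5e-3, 3), 0.003)
  expect_equal(round_half_away(-2.5e-3, 3), -0.003)
  expect_equal(trunc_decimal(269.77965, 3), 269.779)
  expect_equal(round_half_away(269.77965, 3), 269.780)
})
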