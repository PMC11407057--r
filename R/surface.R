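#' Bilinear-quadratic basis row in (m, n)
#'
#' The predictive surfaces used for both lattice families are quadratic
#' in each of `m` and `n` over the 9-term product basis, in the fixed
#' order `[m^2 n^2, m n^2, n^2, m^2 n, m n, n, m^2, m, 1]`.
#'
#' @param m,n positive integers (vectorised; recycled to common length)
#' @return a `length(m) x 9` matrix with the basis columns
#' @examples
#' surface_basis(2, 3)   # 36 18 9 12 6 3 4 2 1
#' @export
surface_basis <- function(m, n) {
  if (any(is.na(m)) || any(is.na(n)) || any(m < 1) || any(n < 1))
    stop("m and n must be >= 1")
  cbind(m2n2 = m^2 * n^2, mn2 = m * n^2, n2 = n^2, m2n = m^2 * n,
        mn = m * n, n = n * (m^0), m2 = m^2 * (n^0), m = m * (n^0),
        const = 1 + 0 * m * n)
}

basis_names <- c("m2n2", "mn2", "n2", "m2n", "mn", "n", "m2", "m", "const")

#' Fit a bilinear-quadratic predictive surface
#'
#' Least-squares fit of a spectral descriptor (or any scalar property)
#' observed on a grid of unit-cell counts `(m, n)` to the 9-term
#' product-quadratic basis of [surface_basis()].  This is the QSPR-style
#' "general equation" step: the fitted surface predicts the descriptor for
#' unit-cell counts outside the computed grid.
#'
#' Identifiability requires at least 9 observations with at least 3
#' distinct values in each of `m` and `n` (the basis is quadratic in each
#' direction); rank deficiency is an error, never a silent minimum-norm
#' fallback.
#'
#' @param data a data.frame with columns `m`, `n` and the response named
#'   by `value`; typically a [descriptor_sweep()] result
#' @param value name of the response column (default `"energy"`)
#' @param property_tag,structure_tag free-text labels stored on the model
#' @return an object of class `"surface_model"`: coefficients over the
#'   named basis, fit diagnostics (`sse`, `r_squared`), residuals and the
#'   training data.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `fitted`, `plot`.
#' @examples
#' d <- expand.grid(m = 1:4, n = 1:4)
#' d$energy <- 2 * d$m * d$n + d$n + 1
#' fit <- fit_surface(d)
#' coef(fit)[c("mn", "n", "const")]
#' @export
fit_surface <- function(data, value = "energy", property_tag = value,
                        structure_tag = "custom") {
  if (!all(c("m", "n", value) %in% names(data)))
    stop("`data` needs columns m, n and '", value, "'")
  m <- data$m; n <- data$n; y <- data[[value]]
  if (length(y) < 9)
    stop("need at least 9 observations to identify the 9-term basis")
  if (length(unique(m)) < 3)
    stop("identifiability: need at least 3 distinct m values (got ",
         length(unique(m)), ")")
  if (length(unique(n)) < 3)
    stop("identifiability: need at least 3 distinct n values (got ",
         length(unique(n)), ")")
  X <- surface_basis(m, n)
  qx <- qr(X)
  if (qx$rank < 9)
    stop("identifiability: design matrix is rank deficient (rank ",
         qx$rank, " of 9)")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  structure(list(coefficients = beta,
                 property_tag = property_tag,
                 structure_tag = structure_tag,
                 sse = sse,
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 residuals = res,
                 data = data.frame(m = m, n = n, value = y)),
            class = "surface_model")
}

#' Built-in published surface models
#'
#' The four printed coefficient sets for the energy and Estrada index of
#' the BiI3 sheet and the BRE network, verbatim, over the basis order of
#' [surface_basis()].
#'
#' @param name one of `"E_BII3"`, `"EE_BII3"`, `"E_BRE"`, `"EE_BRE"`
#' @return a `surface_model` (without fit diagnostics)
#' @examples
#' evaluate_surface(paper_model("E_BII3"), 3, 2)   # 116.989 to 3 dp
#' @export
paper_model <- function(name) {
  sets <- list(
    E_BII3 = c(7e-9, -9e-5, 0.0003, -0.0003, 13.794, 9.5506,
               -0.0014, 5.1553, -0.3239),
    EE_BII3 = c(3.167, -15.839, 19.009, -12.67, 110.86, -44.392,
                9.49, -32.462, 57.857),
    E_BRE = c(2e-7, -2e-5, 2e-5, -0.01, 35.2, 0.98,
              -0.0085, 0.9773, -0.1176),
    EE_BRE = c(0.0542, -0.1387, -0.0665, -0.0145, 70.062, 2.193,
               -0.1985, 2.3475, -1.994))
  if (length(name) != 1 || !name %in% names(sets))
    stop("unknown model '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  cf <- stats::setNames(sets[[name]], basis_names)
  structure(list(coefficients = cf,
                 property_tag = if (startsWith(name, "EE")) "estrada"
                                else "energy",
                 structure_tag = if (endsWith(name, "BRE")) "bre"
                                 else "bii3",
                 sse = NA_real_, r_squared = NA_real_,
                 residuals = NULL, data = NULL),
            class = "surface_model")
}

#' Evaluate a surface model at unit-cell counts (m, n)
#'
#' @param model a `surface_model`
#' @param m,n positive integers (vectorised)
#' @return numeric vector of surface values
#' @export
evaluate_surface <- function(model, m, n) {
  drop(surface_basis(m, n) %*% model$coefficients)
}

#' @export
predict.surface_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("no training data stored; give newdata")
    newdata <- object$data
  }
  evaluate_surface(object, newdata$m, newdata$n)
}

#' @export
coef.surface_model <- function(object, ...) object$coefficients

#' @export
residuals.surface_model <- function(object, ...) object$residuals

#' @export
fitted.surface_model <- function(object, ...) {
  if (is.null(object$data)) stop("model has no training data")
  object$data$value - object$residuals
}

#' @export
print.surface_model <- function(x, digits = 6, ...) {
  cat("Bilinear-quadratic surface model (", x$property_tag, ", ",
      x$structure_tag, ")\n", sep = "")
  print(signif(x$coefficients, digits))
  if (!is.na(x$r_squared))
    cat("SSE:", format(x$sse, digits = 6),
        "  R-squared:", format(x$r_squared, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.surface_model <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              property_tag = object$property_tag,
              structure_tag = object$structure_tag,
              sse = object$sse, r_squared = object$r_squared,
              n_obs = if (is.null(object$data)) 0L else nrow(object$data),
              residual_range = if (is.null(object$residuals)) NULL
                               else range(object$residuals))
  class(out) <- "summary.surface_model"
  out
}

#' @export
print.summary.surface_model <- function(x, ...) {
  cat("Surface model summary (", x$property_tag, ", ", x$structure_tag,
      ")\n", sep = "")
  cat("Observations:", x$n_obs, "\n")
  print(x$coefficients)
  if (!is.na(x$sse)) {
    cat("SSE:", format(x$sse), "  R-squared:",
        format(x$r_squared, digits = 8), "\n")
    cat("Residual range:", format(x$residual_range), "\n")
  }
  invisible(x)
}

#' @export
plot.surface_model <- function(x, ...) {
  if (is.null(x$data)) stop("model has no training data to plot")
  pred <- evaluate_surface(x, x$data$m, x$data$n)
  graphics::plot(x$data$value, pred,
                 xlab = "exact value", ylab = "surface estimate",
                 main = paste("Surface fit:", x$property_tag), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Reduce a surface model to a quadratic in n at fixed m
#'
#' Substituting a fixed horizontal count `m` into the 9-term surface
#' collapses it to `a2 n^2 + a1 n + a0` with
#' `a2 = c1 m^2 + c2 m + c3`, `a1 = c4 m^2 + c5 m + c6`,
#' `a0 = c7 m^2 + c8 m + c9`.
#'
#' @param model a `surface_model`
#' @param m positive integer
#' @return an object of class `"quadratic_in_n"`: list with `a2`, `a1`,
#'   `a0` and the parent tags
#' @examples
#' reduce_at_m(paper_model("E_BII3"), 3)   # 3.0063e-05, 50.9299, 15.1294
#' @export
reduce_at_m <- function(model, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  cf <- unname(model$coefficients)
  structure(list(a2 = cf[1] * m^2 + cf[2] * m + cf[3],
                 a1 = cf[4] * m^2 + cf[5] * m + cf[6],
                 a0 = cf[7] * m^2 + cf[8] * m + cf[9],
                 m = m, property_tag = model$property_tag,
                 structure_tag = model$structure_tag),
            class = "quadratic_in_n")
}

#' Evaluate a reduced quadratic at n
#' @param q a `quadratic_in_n` from [reduce_at_m()]
#' @param n numeric vector
#' @return `a2 n^2 + a1 n + a0`
#' @export
eval_quadratic <- function(q, n) q$a2 * n^2 + q$a1 * n + q$a0

#' @export
print.quadratic_in_n <- function(x, ...) {
  cat(sprintf("(%d, n): %s n^2 + %s n + %s   [%s, %s]\n", x$m,
              format(x$a2, digits = 6), format(x$a1, digits = 6),
              format(x$a0, digits = 6), x$property_tag, x$structure_tag))
  invisible(x)
}

#' Serialize and restore surface models
#'
#' Plain-text key/value format: tags, the basis order and the 9
#' coefficients at full precision (`%.17g`).
#'
#' @param model a `surface_model`
#' @param path file path
#' @return `write_surface_model()` returns `path` invisibly;
#'   `read_surface_model()` a `surface_model`.
#' @export
write_surface_model <- function(model, path) {
  lines <- c(paste0("property_tag: ", model$property_tag),
             paste0("structure_tag: ", model$structure_tag),
             paste0("basis: ", paste(basis_names, collapse = " ")),
             paste0("coefficients: ",
                    paste(sprintf("%.17g", model$coefficients),
                          collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_surface_model
#' @export
read_surface_model <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(ln) != 1) stop("model file missing field '", key, "'")
    sub(paste0("^", key, ": "), "", ln)
  }
  basis <- strsplit(get_field("basis"), " ")[[1]]
  if (!identical(basis, basis_names))
    stop("model file uses an unknown basis order")
  cf <- as.numeric(strsplit(get_field("coefficients"), " ")[[1]])
  if (length(cf) != 9 || anyNA(cf))
    stop("model file must contain 9 finite coefficients")
  structure(list(coefficients = stats::setNames(cf, basis_names),
                 property_tag = get_field("property_tag"),
                 structure_tag = get_field("structure_tag"),
                 sse = NA_real_, r_squared = NA_real_,
                 residuals = NULL, data = NULL),
            class = "surface_model")
}

#' Rounding helpers for table display
#'
#' `round_half_away()` rounds half away from zero (the convention of most
#' hand calculators); `trunc_decimal()` truncates toward zero.  Both are
#' provided because published tables mix the two when printing estimates
#' to 3 decimals.
#'
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_away
#' @export
trunc_decimal <- function(x, digits = 3) {
  p <- 10^digits
  trunc(x * p) / p
}
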