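#' Compare exact and estimated descriptor values
#'
#' Builds the per-row error table used throughout the error analysis:
#' `error = estimated - exact`, `abs_error = |error|`,
#' `ape = 100 * abs_error / denominator` and the signed
#' `rel_error_pct = 100 * error / denominator`, plus the aggregates MAPE
#' (mean of the APEs), mean absolute error and a standard deviation of the
#' absolute errors.
#'
#' The APE denominator is an explicit choice: published tables use the
#' estimated value in some places and the exact value in others, so
#' `denominator_mode` must be stated (default `"estimated"`).  Likewise
#' the standard deviation convention (`"sample"` = n-1 denominator,
#' `"population"` = n) is explicit.
#'
#' @param labels row labels (e.g. `"(3,1)"`), recycled if length 1
#' @param exact,estimated numeric vectors of equal length
#' @param denominator_mode `"estimated"` or `"exact"`
#' @param stdev_mode `"sample"` or `"population"`
#' @return an object of class `"error_report"`: list with `rows` (a
#'   data.frame) and `aggregates` (`mape`, `mean_abs_error`, `stdev`)
#'   plus the modes used
#' @examples
#' r <- compare_estimates("(3,1)", 66.950, 66.966)
#' r$rows$error   # 0.016
#' @export
compare_estimates <- function(labels, exact, estimated,
                              denominator_mode = c("estimated", "exact"),
                              stdev_mode = c("sample", "population")) {
  denominator_mode <- match.arg(denominator_mode)
  stdev_mode <- match.arg(stdev_mode)
  if (length(exact) != length(estimated))
    stop("exact and estimated must have equal length (",
         length(exact), " vs ", length(estimated), ")")
  if (length(exact) == 0) stop("empty comparison")
  if (length(labels) == 1) labels <- rep(labels, length(exact))
  den <- if (denominator_mode == "estimated") estimated else exact
  if (any(den == 0))
    stop("zero denominator in row '", labels[which(den == 0)[1]], "'")
  err <- estimated - exact
  abs_err <- abs(err)
  ape <- 100 * abs_err / abs(den)
  rows <- data.frame(label = labels, exact = exact, estimated = estimated,
                     error = err, abs_error = abs_err, ape = ape,
                     rel_error_pct = 100 * err / den)
  structure(list(rows = rows,
                 denominator_mode = denominator_mode,
                 stdev_mode = stdev_mode,
                 aggregates = c(mape = mape(ape),
                                mean_abs_error = mean_abs_error(err),
                                stdev = if (length(abs_err) >= 2)
                                  stdev(abs_err, stdev_mode)
                                else NA_real_)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 4, ...) {
  cat("Error report (APE denominator:", x$denominator_mode,
      "| stdev:", x$stdev_mode, ")\n")
  rows <- x$rows
  rows$ape <- round(rows$ape, 3)
  rows$rel_error_pct <- round(rows$rel_error_pct, 3)
  print(rows, digits = digits)
  cat(sprintf("MAPE %.3f | mean abs error %.4f | stdev(abs err) %.7f\n",
              x$aggregates["mape"], x$aggregates["mean_abs_error"],
              x$aggregates["stdev"]))
  invisible(x)
}

#' Mean absolute percentage error
#' @param apes numeric vector of absolute percentage errors
#' @return their arithmetic mean
#' @export
mape <- function(apes) {
  if (length(apes) == 0) stop("empty APE list")
  mean(apes)
}

#' Mean absolute error
#' @param values numeric vector of (signed or absolute) errors
#' @return mean of the absolute values
#' @export
mean_abs_error <- function(values) {
  if (length(values) == 0) stop("empty error list")
  mean(abs(values))
}

#' Standard deviation with an explicit denominator convention
#'
#' @param values numeric vector, length >= 2
#' @param mode `"sample"` (n-1 denominator) or `"population"` (n)
#' @return non-negative scalar
#' @export
stdev <- function(values, mode = c("sample", "population")) {
  mode <- match.arg(mode)
  if (length(values) < 2) stop("stdev needs at least 2 values")
  if (mode == "sample") stats::sd(values)
  else sqrt(mean((values - mean(values))^2))
}

#' Gaussian density values for an error summary curve
#'
#' @param mu mean
#' @param sigma standard deviation, strictly positive
#' @param xs numeric vector of evaluation points
#' @return `dnorm(xs, mu, sigma)`
#' @export
normal_curve <- function(mu, sigma, xs) {
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    stop("sigma must be a positive scalar")
  stats::dnorm(xs, mean = mu, sd = sigma)
}

#' Read or write an error report as CSV
#'
#' The CSV carries the `rows` data.frame at full precision;
#' `read_error_report()` rebuilds the report (and its aggregates) from
#' the `exact` and `estimated` columns.
#'
#' @param report an `error_report`
#' @param path file path
#' @param denominator_mode,stdev_mode conventions used when rebuilding
#' @return `write_error_report()` returns `path` invisibly;
#'   `read_error_report()` an `error_report`
#' @export
write_error_report <- function(report, path) {
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_report
#' @export
read_error_report <- function(path,
                              denominator_mode = c("estimated", "exact"),
                              stdev_mode = c("sample", "population")) {
  rows <- utils::read.csv(path)
  compare_estimates(rows$label, rows$exact, rows$estimated,
                    denominator_mode = match.arg(denominator_mode),
                    stdev_mode = match.arg(stdev_mode))
}

#' Published comparison tables shipped with the package
#'
#' The four exact-vs-estimated columns for the energy and Estrada index
#' of the two lattice families, as printed (including their internal
#' inconsistencies: the two Estrada tables are near-duplicates of each
#' other, and a few printed error entries do not equal
#' `estimated - exact`; the columns are shipped verbatim so that the
#' published aggregate statistics can be recomputed from them exactly).
#'
#' @param name one of `"table2_energy_bii3"`, `"table3_estrada_bii3"`,
#'   `"table6_energy_bre"`, `"table7_estrada_bre"`
#' @return a data.frame with columns `m, n, exact, estimated, error,
#'   abs_error, ape`
#' @examples
#' mape(paper_table("table3_estrada_bii3")$ape)   # 0.00515
#' @export
paper_table <- function(name = c("table2_energy_bii3",
                                 "table3_estrada_bii3",
                                 "table6_energy_bre",
                                 "table7_estrada_bre")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".csv"),
                   package = "latticespectra", mustWork = TRUE)
  utils::read.csv(f)
}
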