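#' Calibrate the builtin generators against the published count sequences
#'
#' For each `n`, generates the structure with the builtin rules, computes
#' the inertia indices, nullity and signature from the spectrum, and
#' compares them with the published `m = 3` sequences from
#' [expected_counts()].  The result is a pass/fail table rather than a
#' hard assertion: only `m = 3` is published, the table rows are
#' run-together digit strings with a documented parsing ambiguity for the
#' BiI3 nullity (see the `parsing` argument of [expected_counts()]), and
#' generalisation to other `m` is unconstrained by data.
#'
#' @param structure `"bii3"` or `"bre"`
#' @param m horizontal unit-cell count (published data exists for 3 only)
#' @param n_range vertical unit-cell counts to check (default `1:12`, the
#'   published range)
#' @param parsing passed to [expected_counts()]
#' @param zero_tol passed to [spectrum_of()]
#' @return a data.frame of class `"calibration_report"` with computed and
#'   expected `p`, `eta`, `s` and logical `pass` per row (`NA` expected
#'   values yield `NA` pass)
#' @examples
#' calibration_report("bre", n_range = 1:2)
#' @export
calibration_report <- function(structure = c("bii3", "bre"), m = 3,
                               n_range = 1:12,
                               parsing = c("stoichiometric", "compact"),
                               zero_tol = NULL) {
  structure <- match.arg(structure)
  parsing <- match.arg(parsing)
  rows <- lapply(n_range, function(n) {
    g <- generate_structure(structure, m, n)
    s <- spectrum_of(g, zero_tol = zero_tol)
    i <- inertia_of(s); sr <- signature_rank(s)
    ex <- expected_counts(structure, m, n, parsing)
    ok <- if (is.na(ex$expected_p)) NA
          else (i[["p_plus"]] == ex$expected_p &&
                i[["n_minus"]] == ex$expected_p &&
                i[["eta"]] == ex$expected_eta &&
                sr[["signature"]] == ex$expected_s)
    data.frame(m = m, n = n,
               p = i[["p_plus"]], p_expected = ex$expected_p,
               n_minus = i[["n_minus"]],
               eta = i[["eta"]], eta_expected = ex$expected_eta,
               s = sr[["signature"]], s_expected = ex$expected_s,
               pass = ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "structure") <- structure
  attr(out, "parsing") <- parsing
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration of builtin", attr(x, "structure"),
      "rules against the published sequences (parsing:",
      attr(x, "parsing"), ")\n")
  df <- as.data.frame(x)
  df$pass <- ifelse(is.na(df$pass), "n/a (no published data)",
                    ifelse(df$pass, "PASS", "FAIL"))
  print(df, row.names = FALSE)
  npass <- sum(x$pass %in% TRUE)
  nchk <- sum(!is.na(x$pass))
  cat(sprintf("%d of %d checked rows pass\n", npass, nchk))
  invisible(x)
}
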