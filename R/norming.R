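## Regression-based 12-month change norms --------------------------------------
##
## Each norm is a per-test linear equation mapping baseline performance to
## expected 12-month performance in a robustly normal reference sample, plus
## the residual standard deviation (standard error of the estimate, S_y.x)
## used to standardize observed-minus-expected discrepancies into z-scores.
## Timed tests (Trails A/B) are analyzed as -log10(seconds) so that higher
## always means better and skew is tamed.

timed_tests <- function() c("trails_a", "trails_b")

#' Convert a raw test score to its analysis scale
#'
#' Identity for untimed tests; `-log10(seconds)` for Trail Making A and B, so
#' that on the analysis scale a higher value always indicates better
#' performance.
#'
#' @param test_id one of [np_tests()].
#' @param raw raw score(s); seconds for timed tests. Missing values pass
#'   through.
#' @return Numeric vector on the analysis scale.
#' @export
to_analysis_scale <- function(test_id, raw) {
  test_id <- match.arg(test_id, np_tests())
  if (test_id %in% timed_tests()) {
    if (any(!is.na(raw) & raw <= 0)) {
      stop("completion time must be > 0 seconds for ", test_id, call. = FALSE)
    }
    -log10(raw)
  } else {
    raw
  }
}

new_norm_equation <- function(test_id, intercept, slope, see, n_fit = NA_real_) {
  test_id <- match.arg(test_id, np_tests())
  stopifnot(is.finite(intercept), is.finite(slope))
  if (!is.finite(see) || see < 0) stop("see must be finite and >= 0", call. = FALSE)
  transform <- if (test_id %in% timed_tests()) "NEG_LOG10_SECONDS" else "IDENTITY"
  structure(list(test_id = test_id, intercept = intercept, slope = slope,
                 see = see, transform = transform, n_fit = n_fit),
            class = "np_norm_equation")
}

#' @export
print.np_norm_equation <- function(x, ...) {
  cat(sprintf("<norm %s> predicted = %s%.4f + %.4f * baseline%s, S_y.x = %.4f\n",
              x$test_id,
              if (x$transform == "NEG_LOG10_SECONDS") "-[" else "",
              x$intercept, x$slope,
              if (x$transform == "NEG_LOG10_SECONDS") "(log10 s)]" else "",
              x$see))
  invisible(x)
}

#' The published six-test norm set
#'
#' Regression-based 12-month change norms developed in a robustly normal
#' reference sample (n = 294): for each test, the intercept and slope of the
#' linear equation predicting 12-month performance from baseline performance,
#' and the standard error of the estimate (S_y.x) used as the standardizing
#' denominator. Trail Making equations operate on log10 seconds and are
#' inverted so that higher predicted scores mean better performance.
#'
#' @return A `np_norm_table`: one equation per test.
#' @export
published_norms <- function() {
  eqs <- list(
    new_norm_equation("lm_immediate", 6.883, 0.595, 2.7730),
    new_norm_equation("lm_delayed",   4.810, 0.680, 3.1780),
    new_norm_equation("trails_a",     0.589, 0.598, 0.1009),
    new_norm_equation("trails_b",     0.656, 0.643, 0.1374),
    new_norm_equation("animals",      8.410, 0.623, 4.0650),
    new_norm_equation("vegetables",   4.464, 0.687, 3.2700)
  )
  new_norm_table(eqs, label = "ADNI-robust-normal (published)", version = "1.0")
}

new_norm_table <- function(equations, label, version = "1.0") {
  ids <- vapply(equations, function(e) e$test_id, character(1))
  if (!setequal(ids, np_tests()) || anyDuplicated(ids)) {
    stop("norm table requires exactly one equation per test", call. = FALSE)
  }
  names(equations) <- ids
  structure(list(equations = equations[np_tests()], label = label,
                 version = version),
            class = "np_norm_table")
}

#' @export
print.np_norm_table <- function(x, ...) {
  cat(sprintf("<np_norm_table> %s (v%s)\n", x$label, x$version))
  for (eq in x$equations) print(eq)
  invisible(x)
}

#' Fit a 12-month change norm for one test
#'
#' Ordinary least squares of analysis-scale 12-month follow-up score on
#' analysis-scale baseline score, over complete cases. The standard error of
#' the estimate is `sqrt(RSS / (n - 2))`. For timed tests the fitted equation
#' is stored in the published convention (positive-log regression with a
#' trailing inversion), which is algebraically identical to regressing on the
#' inverted scale.
#'
#' @param test_id one of [np_tests()].
#' @param baseline,followup aligned numeric vectors of analysis-scale scores.
#' @return A `np_norm_equation` with `n_fit` recorded. A perfect fit
#'   (`see == 0`) is flagged with attribute `degenerate = TRUE` and a warning.
#' @export
fit_norm <- function(test_id, baseline, followup) {
  test_id <- match.arg(test_id, np_tests())
  if (length(baseline) != length(followup)) {
    stop("baseline and followup must be aligned", call. = FALSE)
  }
  ok <- stats::complete.cases(baseline, followup)
  x <- baseline[ok]; y <- followup[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete cases to fit a norm (got ", n, ")",
                  call. = FALSE)
  if (stats::var(x) == 0) stop("zero baseline variance; cannot fit norm",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  see <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (test_id %in% timed_tests()) a <- -a  # store in printed (inverted) form
  eq <- new_norm_equation(test_id, a, b, see, n_fit = n)
  if (see < 1e-10) {
    warning("degenerate fit for ", test_id, ": zero residual variance",
            call. = FALSE)
    attr(eq, "degenerate") <- TRUE
  }
  eq
}

#' Predicted 12-month performance from baseline, on the analysis scale
#'
#' Untimed tests: `intercept + slope * baseline_raw`. Timed tests:
#' `-(intercept + slope * log10(seconds))`, identically equal to applying the
#' regression on the inverted `-log10(seconds)` scale with negated intercept.
#' The result is comparable to [to_analysis_scale()] of an observed follow-up
#' score.
#'
#' @param eq a `np_norm_equation`.
#' @param baseline_raw raw baseline score(s); seconds for timed tests.
#' @return Predicted analysis-scale follow-up score(s).
#' @export
predict_followup <- function(eq, baseline_raw) {
  stopifnot(inherits(eq, "np_norm_equation"))
  if (eq$transform == "NEG_LOG10_SECONDS") {
    if (any(!is.na(baseline_raw) & baseline_raw <= 0)) {
      stop("completion time must be > 0 seconds", call. = FALSE)
    }
    -(eq$intercept + eq$slope * log10(baseline_raw))
  } else {
    eq$intercept + eq$slope * baseline_raw
  }
}

#' Fit a full norm table from a reference cohort
#'
#' Extracts each subject's baseline exam and the exam closest to 12 months
#' (within the policy window), converts raw scores to the analysis scale, and
#' fits one change norm per test over complete cases.
#'
#' @param cohort an `np_cohort` of robustly normal reference subjects.
#' @param policy a [scoring_policy()]; only the follow-up window is used.
#' @param label provenance label for the fitted table.
#' @return A `np_norm_table` with `n_fit` per equation.
#' @export
fit_norm_table <- function(cohort, policy = scoring_policy(),
                           label = "locally fitted") {
  pairs <- baseline_followup_pairs(cohort, policy)
  eqs <- lapply(np_tests(), function(tid) {
    col <- test_column(tid)
    fit_norm(tid,
             to_analysis_scale(tid, pairs$baseline[[col]]),
             to_analysis_scale(tid, pairs$followup[[col]]))
  })
  new_norm_table(eqs, label = label)
}

## Serialization: versioned plain-text (Debian-control style records) ----------

#' Write a norm table to a plain-text file
#'
#' One record per equation plus a header record carrying the label and
#' version, in Debian-control (key: value) format; numbers are written with
#' round-trip-safe precision.
#'
#' @param table a `np_norm_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_norm_table <- function(table, path) {
  stopifnot(inherits(table, "np_norm_table"))
  recs <- lapply(table$equations, function(eq) {
    c(test_id = eq$test_id,
      intercept = sprintf("%.17g", eq$intercept),
      slope = sprintf("%.17g", eq$slope),
      see = sprintf("%.17g", eq$see),
      transform = eq$transform,
      n_fit = if (is.na(eq$n_fit)) "NA" else sprintf("%d", as.integer(eq$n_fit)))
  })
  header <- c(label = table$label, version = table$version,
              schema = "np_norm_table")
  con <- file(path, "w")
  on.exit(close(con))
  write.dcf(t(as.matrix(header)), con)
  cat("\n", file = con)
  for (r in recs) {
    write.dcf(t(as.matrix(r)), con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read a norm table written by [write_norm_table()]
#'
#' @param path path to a norm-table file.
#' @return A `np_norm_table`.
#' @export
read_norm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- read.dcf(path)
  recs <- as.data.frame(recs, stringsAsFactors = FALSE)
  if (!"schema" %in% names(recs) || recs$schema[1] != "np_norm_table") {
    stop("not a norm-table file: ", path, call. = FALSE)
  }
  header <- recs[1, ]
  body <- recs[-1, , drop = FALSE]
  eqs <- lapply(seq_len(nrow(body)), function(i) {
    new_norm_equation(body$test_id[i],
                      as.numeric(body$intercept[i]),
                      as.numeric(body$slope[i]),
                      as.numeric(body$see[i]),
                      n_fit = suppressWarnings(as.numeric(body$n_fit[i])))
  })
  new_norm_table(eqs, label = header$label, version = header$version)
}
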