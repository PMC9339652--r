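#' @keywords internal
"_PACKAGE"

## Canonical cohort schema -----------------------------------------------------

#' Cohort file schema
#'
#' Column names, in order, of the long-format cohort table: one row per exam
#' visit, missing values as empty cells. This is the on-disk contract used by
#' [read_cohort()] and [write_cohort()].
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "visit_index", "months_since_baseline", "age_years",
    "sex", "education_years", "diagnosis", "cdr_global",
    "lm_immediate", "lm_delayed", "trails_a_seconds", "trails_b_seconds",
    "animals", "vegetables")
}

#' Identifiers of the six neuropsychological tests
#'
#' Logical Memory Story A immediate and delayed recall, Trail Making A and B
#' (completion time in seconds), and category fluency for animals and
#' vegetables. These ids index norm equations and per-subtest z-scores.
#'
#' @return Character vector of six test ids.
#' @export
np_tests <- function() {
  c("lm_immediate", "lm_delayed", "trails_a", "trails_b",
    "animals", "vegetables")
}

# map test id -> cohort column holding its raw score
test_column <- function(test_id) {
  cols <- c(lm_immediate = "lm_immediate", lm_delayed = "lm_delayed",
            trails_a = "trails_a_seconds", trails_b = "trails_b_seconds",
            animals = "animals", vegetables = "vegetables")
  unname(cols[test_id])
}

diagnosis_levels <- function() c("NORMAL", "IMPAIRED_NOT_MCI", "MCI", "DEMENTIA")
sex_levels <- function() c("MALE", "FEMALE", "UNKNOWN")
cdr_levels <- function() c(0, 0.5, 1, 2, 3)

# raw-score bounds enforced on read; NULL upper = unbounded
score_bounds <- list(
  lm_immediate      = c(0, 25),
  lm_delayed        = c(0, 25),
  trails_a_seconds  = c(0, 150),   # open at 0: time must be > 0
  trails_b_seconds  = c(0, 300),
  animals           = c(0, Inf),
  vegetables        = c(0, Inf)
)

## Construction & validation ---------------------------------------------------

#' Construct a validated cohort object
#'
#' A cohort is a long-format `data.frame` (one row per visit) carrying the
#' columns of [cohort_columns()], validated against the schema invariants:
#' visit 0 at month 0, strictly increasing visit times, non-decreasing age
#' within subject, in-range scores, and known factor levels.
#'
#' @param data data.frame with the cohort columns.
#' @param provenance free-text label recording where the table came from.
#' @param strict if `TRUE` (default) out-of-bounds scores are an error; if
#'   `FALSE` they are set to missing with a warning naming each cell.
#' @return A `np_cohort` object (a data.frame).
#' @export
as_cohort <- function(data, provenance = "unspecified", strict = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(data), cohort_columns())
  if (length(extra) > 0) {
    stop("unknown columns in cohort table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, cohort_columns()]
  data$subject_id <- as.character(data$subject_id)
  for (col in c("visit_index", "months_since_baseline", "age_years",
                "education_years", "cdr_global",
                names(score_bounds))) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data$sex <- as.character(data$sex)
  data$diagnosis <- as.character(data$diagnosis)
  data <- validate_cohort(data, strict = strict)
  structure(data,
            class = c("np_cohort", "data.frame"),
            provenance = provenance,
            schema_version = "1.0")
}

validate_cohort <- function(data, strict = TRUE) {
  fail <- function(...) stop(..., call. = FALSE)
  if (nrow(data) == 0) return(data)

  bad_dx <- !is.na(data$diagnosis) & !(data$diagnosis %in% diagnosis_levels())
  if (any(bad_dx)) {
    fail("invalid diagnosis value(s) at row(s) ",
         paste(utils::head(which(bad_dx), 5), collapse = ", "),
         ": ", paste(unique(data$diagnosis[bad_dx]), collapse = ", "))
  }
  bad_sex <- !is.na(data$sex) & !(data$sex %in% sex_levels())
  if (any(bad_sex)) {
    fail("invalid sex value(s) at row(s) ",
         paste(utils::head(which(bad_sex), 5), collapse = ", "))
  }
  bad_cdr <- !is.na(data$cdr_global) & !(data$cdr_global %in% cdr_levels())
  if (any(bad_cdr)) {
    fail("invalid cdr_global value(s) at row(s) ",
         paste(utils::head(which(bad_cdr), 5), collapse = ", "))
  }
  if (any(!is.na(data$visit_index) & data$visit_index < 0)) {
    fail("negative visit_index")
  }
  if (any(!is.na(data$months_since_baseline) & data$months_since_baseline < 0)) {
    fail("negative months_since_baseline")
  }
  bad_edu <- !is.na(data$education_years) &
    (data$education_years < 0 | data$education_years > 30)
  if (any(bad_edu)) {
    fail("education_years out of [0, 30] at row(s) ",
         paste(utils::head(which(bad_edu), 5), collapse = ", "))
  }

  # score bounds: strict -> error naming row/field; non-strict -> NA + warning
  for (col in names(score_bounds)) {
    b <- score_bounds[[col]]
    x <- data[[col]]
    timed <- col %in% c("trails_a_seconds", "trails_b_seconds")
    bad <- !is.na(x) & (if (timed) x <= b[1] | x > b[2] else x < b[1] | x > b[2])
    if (any(bad)) {
      msg <- sprintf("out-of-bounds %s at row(s) %s (allowed %s%g, %g])",
                     col, paste(utils::head(which(bad), 5), collapse = ", "),
                     if (timed) "(" else "[", b[1], b[2])
      if (strict) fail(msg)
      warning(msg, "; set to missing", call. = FALSE)
      data[[col]][bad] <- NA_real_
    }
  }

  # per-subject ordering invariants
  ord <- order(data$subject_id, data$visit_index)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  sid <- data$subject_id
  same <- sid[-1] == sid[-length(sid)]
  if (nrow(data) > 1) {
    dm <- diff(data$months_since_baseline)
    if (any(same & dm <= 0, na.rm = TRUE)) {
      bad_row <- which(same & dm <= 0)[1] + 1
      fail("months_since_baseline not strictly increasing for subject ",
           sid[bad_row], " (row ", bad_row, ")")
    }
    da <- diff(data$age_years)
    if (any(same & da < 0, na.rm = TRUE)) {
      bad_row <- which(same & da < 0)[1] + 1
      fail("age_years decreases for subject ", sid[bad_row], " (row ", bad_row, ")")
    }
    dup <- same & diff(data$visit_index) == 0
    if (any(dup, na.rm = TRUE)) fail("duplicated visit_index within subject")
  }
  base <- data[data$visit_index == 0, , drop = FALSE]
  if (any(base$months_since_baseline != 0, na.rm = TRUE)) {
    fail("visit_index 0 must have months_since_baseline = 0")
  }
  data
}

#' @export
print.np_cohort <- function(x, ...) {
  cat(sprintf("<np_cohort> %d subjects, %d visits (provenance: %s)\n",
              length(unique(x$subject_id)), nrow(x),
              attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of subjects in a cohort
#' @param cohort an `np_cohort`.
#' @return integer count of unique subjects.
#' @export
n_subjects <- function(cohort) length(unique(cohort$subject_id))

## Reading & writing -----------------------------------------------------------

#' Read a cohort table from a CSV file
#'
#' Reads the long-format visit table (see [cohort_columns()]), validates it,
#' and returns an `np_cohort`. Empty cells become missing values; rows are
#' ordered by subject and visit index.
#'
#' @param path path to a CSV file with the documented header.
#' @param strict if `TRUE`, out-of-bounds scores raise a validation error
#'   naming the row and field; if `FALSE`, they are demoted to missing with a
#'   warning.
#' @return An `np_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  as_cohort(raw, provenance = path, strict = strict)
}

#' Write a cohort table to a CSV file
#'
#' Inverse of [read_cohort()]: real-valued columns are serialized with enough
#' decimal digits that a write-then-read round trip reproduces the cohort
#' exactly.
#'
#' @param cohort an `np_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "np_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- out[[col]]
      s <- sprintf("%.17g", v)           # round-trip-safe decimal text
      s[v == round(v) & !is.na(v) & abs(v) < 1e15] <-
        sprintf("%d", as.integer(round(v[v == round(v) & !is.na(v) & abs(v) < 1e15])))
      s[is.na(v)] <- NA_character_
      out[[col]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
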