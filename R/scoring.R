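## NP decline scoring ----------------------------------------------------------
##
## A subject's 12-month NP decline is the standardized discrepancy between the
## observed 12-month score and the norm-predicted score, per test:
##   z = (actual - predicted) / S_y.x
## averaged (unweighted) over the six tests to give the composite NP decline
## z-score. More negative = more decline. The published ROC-optimal cutoff is
## z <= -0.5808 (approximately the 28th percentile of the reference
## distribution), boundary inclusive.

#' Cutoff specification for NP decline classification
#'
#' @param z_value composite z cutoff (default the published ROC optimum,
#'   -0.5808). The boundary is inclusive: `z <= z_value` classifies as NP+.
#' @param provenance free-text note on where the cutoff came from.
#' @return A `np_cutoff` object.
#' @export
cutoff_spec <- function(z_value = -0.5808, provenance = "published ROC optimum") {
  stopifnot(is.finite(z_value))
  structure(list(z_value = z_value, boundary = "inclusive",
                 provenance = provenance),
            class = "np_cutoff")
}

#' Standardize one subtest discrepancy into a z-score
#'
#' @param actual observed analysis-scale follow-up score(s).
#' @param predicted norm-predicted analysis-scale score(s).
#' @param see standard error of the estimate of the norm equation (> 0).
#' @return `(actual - predicted) / see`; negative means worse than the
#'   normative expectation.
#' @export
subtest_z <- function(actual, predicted, see) {
  if (!is.finite(see) || see <= 0) stop("see must be > 0", call. = FALSE)
  (actual - predicted) / see
}

#' Classify a composite z against a cutoff
#'
#' @param z composite NP decline z-score(s).
#' @param cutoff a [cutoff_spec()].
#' @return Character vector: `"NP_PLUS"` if `z <= cutoff` (inclusive),
#'   `"NP_MINUS"` otherwise, `"INDETERMINATE"` for missing z.
#' @export
classify <- function(z, cutoff = cutoff_spec()) {
  stopifnot(inherits(cutoff, "np_cutoff"))
  out <- ifelse(is.na(z), "INDETERMINATE",
                ifelse(z <= cutoff$z_value, "NP_PLUS", "NP_MINUS"))
  out
}

#' Scoring policy: follow-up window and missing-subtest rule
#'
#' @param followup_target_months nominal follow-up interval (12).
#' @param followup_window_months half-width of the acceptable window around
#'   the target; the in-window visit closest to the target is used.
#' @param min_subtests minimum subtests required for a composite (default all
#'   6, matching the definition of the composite; may be relaxed to >= 4 for
#'   realistic incomplete batteries).
#' @param cutoff a [cutoff_spec()].
#' @return A `np_scoring_policy` list.
#' @export
scoring_policy <- function(followup_target_months = 12,
                           followup_window_months = 6,
                           min_subtests = 6,
                           cutoff = cutoff_spec()) {
  stopifnot(followup_target_months > 0, followup_window_months >= 0,
            min_subtests >= 1, min_subtests <= 6)
  structure(list(followup_target_months = followup_target_months,
                 followup_window_months = followup_window_months,
                 min_subtests = min_subtests, cutoff = cutoff),
            class = "np_scoring_policy")
}

# One row per subject with a baseline exam and an in-window follow-up exam:
# returns list(baseline = df, followup = df) of aligned visit rows, plus
# subjects lacking either (attr "unmatched").
baseline_followup_pairs <- function(cohort, policy = scoring_policy()) {
  df <- as.data.frame(cohort)
  base <- df[df$visit_index == 0, , drop = FALSE]
  target <- policy$followup_target_months
  win <- policy$followup_window_months
  cand <- df[df$visit_index > 0 &
               abs(df$months_since_baseline - target) <= win, , drop = FALSE]
  if (nrow(cand) > 0) {
    dist <- abs(cand$months_since_baseline - target)
    # closest to target; ties broken toward the earlier visit
    cand <- cand[order(cand$subject_id, dist, cand$months_since_baseline), ,
                 drop = FALSE]
    cand <- cand[!duplicated(cand$subject_id), , drop = FALSE]
  }
  ids <- intersect(base$subject_id, cand$subject_id)
  base <- base[match(ids, base$subject_id), , drop = FALSE]
  fup <- cand[match(ids, cand$subject_id), , drop = FALSE]
  unmatched <- setdiff(unique(df$subject_id), ids)
  structure(list(baseline = base, followup = fup), unmatched = unmatched)
}

#' Score every subject in a cohort for 12-month NP decline
#'
#' Implements the three-step procedure: (1) enter each baseline raw score into
#' its norm equation to predict 12-month performance; (2) divide the
#' discrepancy between actual and predicted 12-month performance by the
#' equation's standard error of the estimate; (3) average the standardized
#' scores over the available tests to form the composite NP decline z-score,
#' then classify against the cutoff.
#'
#' Subjects without a baseline exam, without an in-window follow-up exam, with
#' a dementia diagnosis at the follow-up exam, or with fewer than
#' `min_subtests` scoreable tests are `INDETERMINATE` (reason recorded).
#'
#' @param cohort an `np_cohort`.
#' @param norms a `np_norm_table` (default [published_norms()]).
#' @param policy a [scoring_policy()].
#' @return A data.frame (class `np_scores`), one row per subject: per-subtest
#'   z columns `z_<test>`, `n_subtests_used`, `composite_z`, `np_status`,
#'   `cutoff_used`, `baseline_visit_index`, `followup_visit_index`,
#'   `followup_months`, `indeterminate_reason`.
#' @export
score_cohort <- function(cohort, norms = published_norms(),
                         policy = scoring_policy()) {
  stopifnot(inherits(norms, "np_norm_table"),
            inherits(policy, "np_scoring_policy"))
  pairs <- baseline_followup_pairs(cohort, policy)
  base <- pairs$baseline; fup <- pairs$followup

  zmat <- matrix(NA_real_, nrow = nrow(base), ncol = length(np_tests()),
                 dimnames = list(NULL, paste0("z_", np_tests())))
  for (tid in np_tests()) {
    eq <- norms$equations[[tid]]
    col <- test_column(tid)
    b <- base[[col]]; f <- fup[[col]]
    ok <- !is.na(b) & !is.na(f)
    if (tid %in% timed_tests()) ok <- ok & b > 0 & f > 0
    z <- rep(NA_real_, nrow(base))
    if (any(ok)) {
      z[ok] <- subtest_z(to_analysis_scale(tid, f[ok]),
                         predict_followup(eq, b[ok]),
                         eq$see)
    }
    zmat[, paste0("z_", tid)] <- z
  }

  n_used <- rowSums(!is.na(zmat))
  demented_fup <- !is.na(fup$diagnosis) & fup$diagnosis == "DEMENTIA"
  composite <- ifelse(n_used >= policy$min_subtests & !demented_fup,
                      rowMeans(zmat, na.rm = TRUE), NA_real_)
  status <- classify(composite, policy$cutoff)
  reason <- rep(NA_character_, nrow(base))
  reason[demented_fup] <- "demented at follow-up exam"
  reason[!demented_fup & n_used < policy$min_subtests] <- "too few scoreable subtests"

  res <- data.frame(subject_id = base$subject_id,
                    as.data.frame(zmat),
                    n_subtests_used = n_used,
                    composite_z = composite,
                    np_status = status,
                    cutoff_used = policy$cutoff$z_value,
                    baseline_visit_index = base$visit_index,
                    followup_visit_index = fup$visit_index,
                    followup_months = fup$months_since_baseline,
                    indeterminate_reason = reason,
                    stringsAsFactors = FALSE)

  unmatched <- attr(pairs, "unmatched")
  if (length(unmatched) > 0) {
    extra <- res[0, ][seq_along(unmatched), ]
    extra$subject_id <- unmatched
    extra$n_subtests_used <- 0
    extra$np_status <- "INDETERMINATE"
    extra$cutoff_used <- policy$cutoff$z_value
    extra$indeterminate_reason <- "no qualifying baseline/follow-up exam pair"
    res <- rbind(res, extra)
  }
  res <- res[order(res$subject_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("np_scores", "data.frame")
  res
}

#' Score a single subject
#'
#' @param cohort an `np_cohort`.
#' @param subject_id id of the subject to score.
#' @inheritParams score_cohort
#' @return One-row `np_scores` data.frame.
#' @export
score_subject <- function(cohort, subject_id, norms = published_norms(),
                          policy = scoring_policy()) {
  sub <- cohort[cohort$subject_id == subject_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown subject: ", subject_id, call. = FALSE)
  class(sub) <- class(cohort)
  attributes(sub)$provenance <- attr(cohort, "provenance")
  score_cohort(sub, norms = norms, policy = policy)
}

## ROC cutoff derivation -------------------------------------------------------

#' ROC-optimal NP decline cutoff (Youden's J)
#'
#' Scans candidate thresholds (the observed composite z values) for the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1, where a subject is
#' test-positive when `z <= threshold`. Ties are broken toward the more
#' negative threshold. The AUC is the rank-statistic (Mann-Whitney)
#' probability that a converter's z lies below a non-converter's.
#'
#' @param composite_z numeric vector of composite NP decline z-scores.
#' @param converted logical (or 0/1) event indicators, aligned with
#'   `composite_z`.
#' @return A list: `cutoff` (a [cutoff_spec()]), `youden_j`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_optimal_cutoff <- function(composite_z, converted) {
  ok <- stats::complete.cases(composite_z, converted)
  z <- composite_z[ok]; y <- as.logical(converted[ok])
  if (!any(y) || all(y)) {
    stop("both converters and non-converters are required", call. = FALSE)
  }
  thr <- sort(unique(z))
  n1 <- sum(y); n0 <- sum(!y)
  # counts of cases/controls at or below each threshold
  sens <- cumsum(tabulate(match(sort(z[y]), thr), nbins = length(thr))) / n1
  fpr  <- cumsum(tabulate(match(sort(z[!y]), thr), nbins = length(thr))) / n0
  j <- sens - fpr
  best <- which.max(j)  # which.max returns the first (most negative) maximum
  r <- rank(c(z[y], z[!y]))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- 1 - auc  # converters are expected to lie LOWER
  list(cutoff = cutoff_spec(thr[best], provenance = "Youden J re-derivation"),
       youden_j = j[best],
       sensitivity = sens[best],
       specificity = 1 - fpr[best],
       auc = auc)
}

#' Percentile of a cutoff in a reference distribution
#'
#' @param reference_z numeric vector of reference composite z-scores, or
#'   `NULL` to use the standard-normal model.
#' @param cutoff a [cutoff_spec()].
#' @return Percentile in 0-100: the empirical fraction of the reference at or
#'   below the cutoff (inclusive, matching [classify()]), or `100 * pnorm(z*)`
#'   under the standard-normal model.
#' @export
percentile_of_cutoff <- function(reference_z = NULL, cutoff = cutoff_spec()) {
  stopifnot(inherits(cutoff, "np_cutoff"))
  if (is.null(reference_z)) {
    100 * stats::pnorm(cutoff$z_value)
  } else {
    z <- reference_z[!is.na(reference_z)]
    if (length(z) == 0) stop("empty reference distribution", call. = FALSE)
    100 * mean(z <= cutoff$z_value)
  }
}
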