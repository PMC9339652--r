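## Prognostic evaluation of NP decline -----------------------------------------
##
## Eligibility mirrors the study conventions: age >= 60 at baseline, a
## non-dementia baseline diagnosis, at least 3 exams, more than 12 months of
## total follow-up, and no dementia within 12 months of baseline. Diagnostic
## groups are taken from the 12-month exam; the survival clock starts there
## (NP decline is only knowable at the 12-month exam).

#' Eligibility configuration
#'
#' @param min_age_years minimum baseline age (60).
#' @param min_exams minimum number of exams (3).
#' @param min_total_followup_months total follow-up must *exceed* this (12).
#' @param require_nondemented_at_followup if `TRUE` subjects demented at the
#'   ~12-month exam are unscoreable and dropped downstream.
#' @param followup_target_months,followup_window_months the 12-month exam
#'   window, shared with [scoring_policy()].
#' @return A `np_eligibility_config` list.
#' @export
eligibility_config <- function(min_age_years = 60,
                               min_exams = 3,
                               min_total_followup_months = 12,
                               require_nondemented_at_followup = TRUE,
                               followup_target_months = 12,
                               followup_window_months = 6) {
  stopifnot(min_age_years >= 0, min_exams >= 0,
            min_total_followup_months >= 0)
  structure(list(min_age_years = min_age_years, min_exams = min_exams,
                 min_total_followup_months = min_total_followup_months,
                 require_nondemented_at_followup = require_nondemented_at_followup,
                 followup_target_months = followup_target_months,
                 followup_window_months = followup_window_months),
            class = "np_eligibility_config")
}

eligibility_rules <- function() {
  c("age", "baseline_diagnosis", "exam_count", "followup_duration",
    "dementia_within_12m")
}

#' Apply eligibility rules to a cohort
#'
#' Rules are checked in a fixed order (age, baseline diagnosis, exam count,
#' follow-up duration, dementia within 12 months); each excluded subject is
#' charged to the first rule it fails, so the exclusion ledger partitions the
#' excluded subjects.
#'
#' @param cohort an `np_cohort`.
#' @param cfg an [eligibility_config()].
#' @return A list: `cohort` (eligible subset, still an `np_cohort`), `ledger`
#'   (data.frame of rule / n_excluded, plus an `eligible` row), and
#'   `exclusions` (per-subject first-failing rule).
#' @export
apply_eligibility <- function(cohort, cfg = eligibility_config()) {
  stopifnot(inherits(cfg, "np_eligibility_config"))
  df <- as.data.frame(cohort)
  ids <- unique(df$subject_id)
  if (length(ids) == 0) {
    ledger <- data.frame(rule = c(eligibility_rules(), "eligible"),
                         n = 0L, stringsAsFactors = FALSE)
    return(list(cohort = cohort, ledger = ledger,
                exclusions = character(0)))
  }
  base <- df[df$visit_index == 0, , drop = FALSE]
  base <- base[match(ids, base$subject_id), , drop = FALSE]
  n_exams <- as.vector(table(factor(df$subject_id, levels = ids)))
  total_fup <- tapply(df$months_since_baseline, factor(df$subject_id, levels = ids),
                      max)
  dem <- df[df$diagnosis == "DEMENTIA" & !is.na(df$diagnosis), , drop = FALSE]
  first_dem <- tapply(dem$months_since_baseline,
                      factor(dem$subject_id, levels = ids), min)
  first_dem[is.na(first_dem)] <- Inf

  fails <- cbind(
    age = is.na(base$age_years) | base$age_years < cfg$min_age_years,
    baseline_diagnosis = is.na(base$diagnosis) |
      !(base$diagnosis %in% c("NORMAL", "IMPAIRED_NOT_MCI", "MCI")),
    exam_count = n_exams < cfg$min_exams,
    followup_duration = as.vector(total_fup) <= cfg$min_total_followup_months,
    dementia_within_12m = as.vector(first_dem) <= cfg$followup_target_months
  )
  first_fail <- apply(fails, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_character_ else eligibility_rules()[w[1]]
  })
  names(first_fail) <- ids
  eligible_ids <- ids[is.na(first_fail)]
  out <- cohort[cohort$subject_id %in% eligible_ids, , drop = FALSE]
  counts <- table(factor(first_fail, levels = eligibility_rules()))
  ledger <- data.frame(rule = c(eligibility_rules(), "eligible"),
                       n = c(as.vector(counts), length(eligible_ids)),
                       stringsAsFactors = FALSE)
  list(cohort = out, ledger = ledger,
       exclusions = first_fail[!is.na(first_fail)])
}

## Survival records ------------------------------------------------------------

#' Build survival records from a scored, eligible cohort
#'
#' Time origin is the ~12-month exam (the visit at which NP decline becomes
#' known); optionally the baseline exam. Event time is months from the origin
#' to the first DEMENTIA diagnosis; censoring time is months to the last
#' dementia-free visit. Subjects scored `INDETERMINATE`, or with no follow-up
#' beyond the origin, are dropped with a recorded count.
#'
#' @param cohort an `np_cohort` (after [apply_eligibility()]).
#' @param scores an `np_scores` table from [score_cohort()].
#' @param time_origin `"followup"` (the 12-month exam; default) or
#'   `"baseline"`.
#' @return A data.frame of records: `subject_id`, `time_months`, `event`,
#'   `age_years` (baseline), `sex`, `education_years`, `np_decline_z`,
#'   `np_status`, `diagnosis_12m`; attribute `dropped` counts the reasons.
#' @export
build_survival_records <- function(cohort, scores, time_origin = c("followup",
                                                                   "baseline")) {
  time_origin <- match.arg(time_origin)
  df <- as.data.frame(cohort)
  sc <- as.data.frame(scores)
  sc <- sc[sc$subject_id %in% unique(df$subject_id), , drop = FALSE]
  n_indet <- sum(sc$np_status == "INDETERMINATE")
  sc <- sc[sc$np_status != "INDETERMINATE", , drop = FALSE]

  base <- df[df$visit_index == 0, , drop = FALSE]
  base <- base[match(sc$subject_id, base$subject_id), , drop = FALSE]
  origin <- if (time_origin == "followup") sc$followup_months else 0

  f <- factor(df$subject_id, levels = sc$subject_id)
  dem <- df[!is.na(df$diagnosis) & df$diagnosis == "DEMENTIA", , drop = FALSE]
  first_dem <- tapply(dem$months_since_baseline,
                      factor(dem$subject_id, levels = sc$subject_id), min)
  first_dem <- as.vector(first_dem)
  nondem <- df[is.na(df$diagnosis) | df$diagnosis != "DEMENTIA", , drop = FALSE]
  last_free <- as.vector(tapply(nondem$months_since_baseline,
                                factor(nondem$subject_id, levels = sc$subject_id),
                                max))

  event <- !is.na(first_dem)
  time <- ifelse(event, first_dem, last_free) - origin
  keep <- !is.na(time) & time > 0
  n_no_fup <- sum(!keep)

  rec <- data.frame(subject_id = sc$subject_id,
                    time_months = time,
                    event = event,
                    age_years = base$age_years,
                    sex = base$sex,
                    education_years = base$education_years,
                    np_decline_z = sc$composite_z,
                    np_status = sc$np_status,
                    diagnosis_12m = followup_diagnosis(df, sc),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "dropped") <- c(indeterminate = n_indet,
                            no_followup_after_origin = n_no_fup)
  rec
}

# diagnosis at the follow-up exam used for scoring
followup_diagnosis <- function(df, sc) {
  key <- paste(df$subject_id, df$visit_index)
  want <- paste(sc$subject_id, sc$followup_visit_index)
  df$diagnosis[match(want, key)]
}

## Conversion table ------------------------------------------------------------

#' Conversion table: diagnosis x NP decline status
#'
#' Six-cell summary (3 diagnostic strata x NP+/NP-) with counts, converter
#' counts and conversion proportions, plus a within-diagnosis 2x2 chi-squared
#' test (NP status x converted; 1 df, no continuity correction).
#'
#' @param records output of [build_survival_records()].
#' @param correct apply Yates continuity correction (default `FALSE`,
#'   matching large-sample usage).
#' @return A list: `cells` (data.frame) and `tests` (data.frame of
#'   chi-squared statistics per diagnosis). Undefined statistics (empty
#'   margin) are `NA` with a warning.
#' @export
conversion_table <- function(records, correct = FALSE) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  dxs <- intersect(c("NORMAL", "IMPAIRED_NOT_MCI", "MCI"),
                   unique(records$diagnosis_12m))
  cells <- expand.grid(diagnosis = dxs, np_status = c("NP_MINUS", "NP_PLUS"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$diagnosis, dxs)), ]
  cells$n <- NA_integer_; cells$converters <- NA_integer_
  cells$conversion_proportion <- NA_real_
  tests <- data.frame(diagnosis = dxs, chi_squared = NA_real_, df = 1L,
                      p_value = NA_real_, n = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    sel <- records$diagnosis_12m == cells$diagnosis[i] &
      records$np_status == cells$np_status[i]
    cells$n[i] <- sum(sel)
    cells$converters[i] <- sum(records$event[sel])
    cells$conversion_proportion[i] <-
      if (sum(sel) > 0) mean(records$event[sel]) else NA_real_
  }
  for (j in seq_along(dxs)) {
    sub <- records[records$diagnosis_12m == dxs[j], , drop = FALSE]
    tab <- table(factor(sub$np_status, levels = c("NP_MINUS", "NP_PLUS")),
                 factor(sub$event, levels = c(FALSE, TRUE)))
    tests$n[j] <- sum(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("chi-squared undefined for stratum ", dxs[j],
              " (empty margin)", call. = FALSE)
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    tests$chi_squared[j] <- unname(ct$statistic)
    tests$p_value[j] <- ct$p.value
  }
  list(cells = cells, tests = tests)
}

## Cox proportional hazards ----------------------------------------------------

#' Cox model for NP decline as a dementia predictor
#'
#' Proportional-hazards fit (Efron ties) of time to dementia on NP decline,
#' controlling for age, sex and years of education. The continuous predictor
#' enters as `-z` ("decline units"), so a hazard ratio above 1 means decline
#' is harmful, matching the direction of a roughly two-fold published risk;
#' the raw per-z coefficient is also reported. The model chi-squared is the
#' likelihood-ratio statistic against the covariates-only null (1 df).
#'
#' @param records output of [build_survival_records()].
#' @param predictor `"z"` (continuous, per decline unit) or `"status"`
#'   (binary NP+ vs NP-).
#' @param stratum optional diagnosis filter (e.g. `"NORMAL"`).
#' @return A `np_cox_result` list: `hazard_ratio`, `ci_lower`, `ci_upper`,
#'   `chi_squared`, `minus2_loglik`, `p_value`, `n`, `n_events`,
#'   `raw_coefficient`, `coefficients` (full table), `fit`.
#' @export
fit_cox <- function(records, predictor = c("z", "status"), stratum = NULL) {
  predictor <- match.arg(predictor)
  if (!is.null(stratum)) {
    records <- records[records$diagnosis_12m %in% stratum, , drop = FALSE]
  }
  records <- records[stats::complete.cases(
    records[, c("time_months", "event", "np_decline_z", "age_years",
                "sex", "education_years")]), , drop = FALSE]
  # UNKNOWN sex cannot enter the sex covariate; drop with a note
  n_unk <- sum(records$sex == "UNKNOWN")
  if (n_unk > 0) {
    message(n_unk, " record(s) with UNKNOWN sex excluded from Cox model")
    records <- records[records$sex != "UNKNOWN", , drop = FALSE]
  }
  if (sum(records$event) < 2) {
    stop("need at least 2 events to fit a Cox model (got ",
         sum(records$event), ")", call. = FALSE)
  }
  records$decline <- if (predictor == "z") {
    -records$np_decline_z
  } else {
    as.integer(records$np_status == "NP_PLUS")
  }
  records$sex <- factor(records$sex, levels = c("FEMALE", "MALE"))
  covs <- c("age_years", "sex", "education_years")
  if (nlevels(droplevels(records$sex)) < 2) {
    covs <- setdiff(covs, "sex")
    message("single sex level; sex covariate dropped")
  }
  fml <- stats::reformulate(c("decline", covs),
                            response = "survival::Surv(time_months, event)")
  fit <- tryCatch(
    survival::coxph(fml, data = records, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(survival::coxph(fml, data = records, ties = "efron"))
    })
  fit0 <- survival::coxph(stats::reformulate(
    covs, response = "survival::Surv(time_months, event)"),
    data = records, ties = "efron")
  ll1 <- fit$loglik[2]; ll0 <- fit0$loglik[2]
  chi2 <- 2 * (ll1 - ll0)
  beta <- unname(stats::coef(fit)["decline"])
  se <- sqrt(diag(fit$var))[which(names(stats::coef(fit)) == "decline")]
  structure(list(
    predictor = predictor,
    hazard_ratio = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    chi_squared = chi2,
    minus2_loglik = -2 * ll1,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    n = fit$n, n_events = fit$nevent,
    raw_coefficient = if (predictor == "z") -beta else beta,
    coefficients = summary(fit)$coefficients,
    fit = fit), class = "np_cox_result")
}

#' @export
print.np_cox_result <- function(x, ...) {
  cat(sprintf(
    "<np_cox_result> HR per %s = %.3f (95%% CI %.3f-%.3f), chi2(1) = %.3f, p = %.3g\n  n = %d, events = %d, -2logLik = %.3f\n",
    if (x$predictor == "z") "decline unit" else "NP+ status",
    x$hazard_ratio, x$ci_lower, x$ci_upper, x$chi_squared, x$p_value,
    x$n, x$n_events, x$minus2_loglik))
  invisible(x)
}

## Factorial ANCOVA ------------------------------------------------------------

#' Factorial ANCOVA on the composite NP decline z-score
#'
#' Linear model of composite z on two crossed factors - the 12-month
#' diagnostic stratum and, by default, the dementia outcome (the alternative
#' pairing with NP status is available) - their interaction, and the
#' covariates age, sex and years of education. Reports type-III F tests (sum
#' contrasts), covariate-adjusted cell means, and all pairwise cell contrasts
#' with Bonferroni-adjusted p-values.
#'
#' @param records output of [build_survival_records()].
#' @param second_factor `"outcome"` (dementia vs no dementia; default) or
#'   `"np_status"`.
#' @return A list: `anova` (type-III table), `adjusted_means` (emmeans grid),
#'   `pairwise` (Bonferroni-adjusted contrasts), `fit` (the `lm`).
#' @export
ancova_factorial <- function(records, second_factor = c("outcome", "np_status")) {
  second_factor <- match.arg(second_factor)
  d <- records[records$sex != "UNKNOWN", , drop = FALSE]
  d$diagnosis <- factor(d$diagnosis_12m,
                        levels = intersect(c("NORMAL", "IMPAIRED_NOT_MCI", "MCI"),
                                           unique(d$diagnosis_12m)))
  d$f2 <- if (second_factor == "outcome") {
    factor(ifelse(d$event, "DEMENTIA", "NO_DEMENTIA"),
           levels = c("NO_DEMENTIA", "DEMENTIA"))
  } else {
    factor(d$np_status, levels = c("NP_MINUS", "NP_PLUS"))
  }
  d$sex <- factor(d$sex)
  cell_n <- table(d$diagnosis, d$f2)
  if (sum(cell_n > 0) < 2) stop("need at least 2 nonempty cells", call. = FALSE)
  fit <- stats::lm(np_decline_z ~ diagnosis * f2 + age_years + sex +
                     education_years,
                   data = d,
                   contrasts = list(diagnosis = "contr.sum", f2 = "contr.sum",
                                    sex = "contr.sum"))
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("rank-deficient ANCOVA design; collinear term(s): ",
         paste(names(alias)[alias], collapse = ", "), call. = FALSE)
  }
  a3 <- car::Anova(fit, type = 3)
  emm <- emmeans::emmeans(fit, ~ diagnosis * f2)
  pw <- emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni")
  list(anova = a3,
       adjusted_means = as.data.frame(emm),
       pairwise = as.data.frame(pw),
       fit = fit)
}

## Progression curves ----------------------------------------------------------

#' Stratified cumulative progression to dementia
#'
#' Kaplan-Meier-type cumulative incidence (1 - S(t)) per diagnosis x NP
#' status group, evaluated on a regular follow-up grid with the number at
#' risk and cumulative events per interval.
#'
#' @param records output of [build_survival_records()].
#' @param grid_months spacing of the reporting grid (12).
#' @return A data.frame: `diagnosis`, `np_status`, `time_months`, `n_risk`,
#'   `cum_events`, `cumulative_progression`.
#' @export
progression_curves <- function(records, grid_months = 12) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  grps <- unique(records[, c("diagnosis_12m", "np_status")])
  grps <- grps[order(match(grps$diagnosis_12m,
                           c("NORMAL", "IMPAIRED_NOT_MCI", "MCI")),
                     grps$np_status), , drop = FALSE]
  times <- seq(0, max(records$time_months), by = grid_months)
  out <- lapply(seq_len(nrow(grps)), function(i) {
    sub <- records[records$diagnosis_12m == grps$diagnosis_12m[i] &
                     records$np_status == grps$np_status[i], , drop = FALSE]
    sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = sub)
    sm <- summary(sf, times = times, extend = TRUE)
    data.frame(diagnosis = grps$diagnosis_12m[i],
               np_status = grps$np_status[i],
               time_months = sm$time,
               n_risk = sm$n.risk,
               cum_events = cumsum(sm$n.event),
               cumulative_progression = 1 - sm$surv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## CDR-based sensitivity outcome -----------------------------------------------

#' Rebuild survival records under the CDR progression criterion
#'
#' Sensitivity analysis replacing the clinical dementia diagnosis with
#' progression on the Clinical Dementia Rating: among subjects with global
#' CDR 0 at the ~12-month exam, the event is the first subsequent visit with
#' CDR >= 0.5. Subjects with missing or nonzero CDR at the 12-month exam are
#' dropped with a recorded count.
#'
#' @inheritParams build_survival_records
#' @return A data.frame of records, as [build_survival_records()]; attribute
#'   `dropped` includes the CDR-based exclusions.
#' @export
cdr_survival_records <- function(cohort, scores) {
  df <- as.data.frame(cohort)
  sc <- as.data.frame(scores)
  sc <- sc[sc$subject_id %in% unique(df$subject_id) &
             sc$np_status != "INDETERMINATE", , drop = FALSE]
  n_indet <- sum(scores$np_status == "INDETERMINATE")

  key <- paste(df$subject_id, df$visit_index)
  want <- paste(sc$subject_id, sc$followup_visit_index)
  cdr_12 <- df$cdr_global[match(want, key)]
  keep0 <- !is.na(cdr_12) & cdr_12 == 0
  n_cdr_excl <- sum(!keep0)
  sc <- sc[keep0, , drop = FALSE]

  origin <- sc$followup_months
  f <- factor(df$subject_id, levels = sc$subject_id)
  prog <- df[!is.na(df$cdr_global) & df$cdr_global >= 0.5, , drop = FALSE]
  first_prog <- as.vector(tapply(prog$months_since_baseline,
                                 factor(prog$subject_id, levels = sc$subject_id),
                                 min))
  free <- df[!is.na(df$cdr_global) & df$cdr_global < 0.5, , drop = FALSE]
  last_free <- as.vector(tapply(free$months_since_baseline,
                                factor(free$subject_id, levels = sc$subject_id),
                                max))
  event <- !is.na(first_prog) & (is.na(origin) | first_prog > origin)
  time <- ifelse(event, first_prog, last_free) - origin
  keep <- !is.na(time) & time > 0

  base <- df[df$visit_index == 0, , drop = FALSE]
  base <- base[match(sc$subject_id, base$subject_id), , drop = FALSE]
  rec <- data.frame(subject_id = sc$subject_id,
                    time_months = time,
                    event = event,
                    age_years = base$age_years,
                    sex = base$sex,
                    education_years = base$education_years,
                    np_decline_z = sc$composite_z,
                    np_status = sc$np_status,
                    diagnosis_12m = followup_diagnosis(df, sc),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "dropped") <- c(indeterminate = n_indet,
                            cdr_nonzero_or_missing_at_12m = n_cdr_excl,
                            no_followup_after_origin = sum(!keep))
  rec
}
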