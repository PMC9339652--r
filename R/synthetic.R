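## Synthetic longitudinal cohorts ----------------------------------------------
##
## Registry data of this kind are access-controlled, so the pipeline is
## exercised on simulated cohorts that reproduce the statistical structure the
## analysis assumes: a classical true-score model per test (latent ability +
## measurement noise), a practice gain and regression to the mean between
## baseline and the 12-month exam, a shared latent decline process loading on
## all six tests, and dementia onset from a proportional-hazards model with
## log-hazard linear in the latent decline magnitude, adjudicated only at
## scheduled visits.

#' Per-test generative model specifications
#'
#' One row per test: latent ability mean/SD on the analysis scale,
#' reliability (share of observed variance due to latent ability), the
#' expected 12-month practice gain for stable individuals, the
#' regression-to-the-mean strength (`retest_slope`), raw-score bounds, and
#' the loading of the shared latent decline process.
#'
#' Defaults are calibrated analytically so that the implied population
#' baseline-to-12-month regression for each test equals the published norm
#' equation: with reliability \eqn{r} and published slope \eqn{b},
#' `retest_slope = b / r`; the observed baseline SD follows from the
#' published standard error of the estimate
#' (`resid var = sigma_x^2 (1 - r)(retest_slope^2 r + 1)`); the practice
#' gain follows from the published intercept at the chosen ability mean. The
#' ability means are plausible test-range values, labelled synthetic: they
#' are not estimates from any real reference sample.
#'
#' @param reliability test-score reliability shared across tests (default
#'   0.70).
#' @return A data.frame with one row per test.
#' @export
default_test_models <- function(reliability = 0.70) {
  stopifnot(reliability > 0, reliability <= 1)
  pub <- published_norms()
  means <- c(lm_immediate = 13, lm_delayed = 12,
             trails_a = -log10(35), trails_b = -log10(85),
             animals = 20, vegetables = 14)
  floors   <- c(lm_immediate = 0, lm_delayed = 0, trails_a = 1, trails_b = 1,
                animals = 0, vegetables = 0)   # raw scale (seconds for timed)
  ceilings <- c(lm_immediate = 25, lm_delayed = 25, trails_a = 150,
                trails_b = 300, animals = 60, vegetables = 60)
  rows <- lapply(np_tests(), function(tid) {
    eq <- pub$equations[[tid]]
    slope <- eq$slope
    icpt <- if (eq$transform == "NEG_LOG10_SECONDS") -eq$intercept else eq$intercept
    retest <- slope / reliability
    sigma_x <- eq$see / sqrt((1 - reliability) * (retest^2 * reliability + 1))
    mx <- means[[tid]]
    data.frame(test_id = tid,
               true_score_mean = mx,
               true_score_sd = sqrt(reliability) * sigma_x,
               reliability = reliability,
               practice_gain = icpt - mx * (1 - slope),
               retest_slope = retest,
               score_floor = floors[[tid]],
               score_ceiling = ceilings[[tid]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulation configuration
#'
#' Defaults represent the study conditions: a reference sample of 294
#' robustly normal subjects, a study cohort of 6,794 with the three 12-month
#' diagnostic strata in proportions 69.1% / 6.9% / 24.0%, annual visits with
#' +/- 2 months jitter, follow-up truncated at 156 months, and dementia
#' hazard doubling per composite-z unit of latent decline.
#'
#' @param n_reference reference-sample size.
#' @param n_study study-cohort size.
#' @param stratum_fractions proportions over NORMAL / IMPAIRED_NOT_MCI / MCI
#'   (in that order; must sum to 1).
#' @param stratum_ability_shift baseline latent-ability shift per stratum, in
#'   latent-SD units.
#' @param decline_fraction per-stratum probability that a subject carries the
#'   latent decline process.
#' @param decline_rate_mean,decline_rate_sd latent 12-month decrement, in
#'   composite-z units (draws truncated at 0).
#' @param decline_loading per-test loading of the latent decline (scalar or
#'   one value per test, in [np_tests()] order).
#' @param baseline_hazard dementia events per person-month for a NORMAL
#'   subject without decline.
#' @param log_hazard_per_decline_unit log hazard ratio per composite-z unit
#'   of latent decline (default `log(2)`).
#' @param stratum_log_hazard additive log-hazard per stratum.
#' @param max_followup_months administrative censoring time (156).
#' @param visit_interval_months scheduled inter-visit interval (12).
#' @param visit_jitter_months half-width of uniform visit-time jitter (2).
#' @param censoring_rate dropout hazard per month after the 12-month exam.
#' @param age_mean,age_sd,age_min,age_max baseline age sampling (truncated
#'   normal).
#' @param education_mean,education_sd years of education (truncated normal,
#'   0-30).
#' @param male_fraction probability of MALE sex.
#' @param test_models per-test generative specs, see [default_test_models()].
#' @return A `np_sim_config` list.
#' @export
sim_config <- function(n_reference = 294,
                       n_study = 6794,
                       stratum_fractions = c(NORMAL = 0.691,
                                             IMPAIRED_NOT_MCI = 0.069,
                                             MCI = 0.240),
                       stratum_ability_shift = c(NORMAL = 0,
                                                 IMPAIRED_NOT_MCI = -0.39,
                                                 MCI = -1.0),
                       decline_fraction = c(NORMAL = 0.24,
                                            IMPAIRED_NOT_MCI = 0.26,
                                            MCI = 0.32),
                       decline_rate_mean = 1.0,
                       decline_rate_sd = 0.4,
                       decline_loading = 1.0,
                       baseline_hazard = 0.001,
                       log_hazard_per_decline_unit = log(2),
                       stratum_log_hazard = c(NORMAL = 0,
                                              IMPAIRED_NOT_MCI = 0.9,
                                              MCI = 1.8),
                       max_followup_months = 156,
                       visit_interval_months = 12,
                       visit_jitter_months = 2,
                       censoring_rate = 0.02,
                       age_mean = 74, age_sd = 7.8,
                       age_min = 60, age_max = 104,
                       education_mean = 15.5, education_sd = 3.2,
                       male_fraction = 0.385,
                       test_models = default_test_models()) {
  stopifnot(n_reference >= 0, n_study >= 0)
  strata <- c("NORMAL", "IMPAIRED_NOT_MCI", "MCI")
  name_by_stratum <- function(x) {
    stopifnot(length(x) == 3)
    if (is.null(names(x))) names(x) <- strata
    x[strata]
  }
  stratum_fractions <- name_by_stratum(stratum_fractions)
  stratum_ability_shift <- name_by_stratum(stratum_ability_shift)
  decline_fraction <- name_by_stratum(decline_fraction)
  stratum_log_hazard <- name_by_stratum(stratum_log_hazard)
  if (abs(sum(stratum_fractions) - 1) > 1e-8) {
    stop("stratum_fractions must sum to 1", call. = FALSE)
  }
  if (any(stratum_fractions < 0) || any(decline_fraction < 0) ||
      any(decline_fraction > 1)) {
    stop("invalid proportions in simulation config", call. = FALSE)
  }
  stopifnot(baseline_hazard >= 0, censoring_rate >= 0,
            max_followup_months > 0, visit_interval_months > 0,
            visit_jitter_months >= 0, decline_rate_sd >= 0,
            all(test_models$score_floor < test_models$score_ceiling),
            all(test_models$reliability > 0 & test_models$reliability <= 1),
            all(test_models$retest_slope > 0 & test_models$retest_slope <= 1))
  structure(as.list(environment())[setdiff(ls(), c("strata", "name_by_stratum"))],
            class = "np_sim_config")
}

# truncated-normal sampler via inverse CDF (clamping would bias the mean)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

clamp_raw <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# analysis scale -> raw score, clamped to the test's raw bounds
to_raw_scale <- function(tid, spec, x_analysis) {
  if (tid %in% timed_tests()) {
    clamp_raw(10^(-x_analysis), spec$score_floor, spec$score_ceiling)
  } else {
    clamp_raw(x_analysis, spec$score_floor, spec$score_ceiling)
  }
}

draw_demographics <- function(n, config) {
  list(age = rtruncnorm(n, config$age_mean, config$age_sd,
                        config$age_min, config$age_max),
       sex = ifelse(stats::runif(n) < config$male_fraction, "MALE", "FEMALE"),
       education = rtruncnorm(n, config$education_mean, config$education_sd,
                              0, 30))
}

# Baseline + 12-month observed scores (analysis scale) for n subjects.
# ability_shift_sd: per-subject latent shift in latent-SD units (stratum
# severity); decline_shift: per-subject latent decrement in composite-z units.
draw_test_scores <- function(n, config, ability_shift_sd = rep(0, n),
                             decline_shift = rep(0, n)) {
  tm <- config$test_models
  loadings <- rep(config$decline_loading, length.out = length(np_tests()))
  names(loadings) <- np_tests()
  pub <- published_norms()
  base <- matrix(NA_real_, n, length(np_tests()),
                 dimnames = list(NULL, np_tests()))
  fup <- base
  for (tid in np_tests()) {
    spec <- tm[tm$test_id == tid, ]
    noise_sd <- spec$true_score_sd * sqrt(1 / spec$reliability - 1)
    mu <- spec$true_score_mean + ability_shift_sd * spec$true_score_sd
    ability <- stats::rnorm(n, mu, spec$true_score_sd)
    base[, tid] <- ability + stats::rnorm(n, 0, noise_sd)
    latent12 <- mu + spec$retest_slope * (ability - mu) + spec$practice_gain -
      decline_shift * pub$equations[[tid]]$see * loadings[[tid]]
    fup[, tid] <- latent12 + stats::rnorm(n, 0, noise_sd)
  }
  list(baseline = base, followup = fup)
}

raw_score_matrix <- function(config, analysis_scores) {
  tm <- config$test_models
  out <- sapply(np_tests(), function(tid)
    to_raw_scale(tid, tm[tm$test_id == tid, ], analysis_scores[, tid]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, np_tests()))
  out
}

empty_cohort_frame <- function() {
  as.data.frame(stats::setNames(
    replicate(length(cohort_columns()), character(0), simplify = FALSE),
    cohort_columns()))
}

## Reference cohort ------------------------------------------------------------

#' Generate a robustly normal reference cohort
#'
#' Every subject is cognitively NORMAL (CDR 0) at both exams, with a baseline
#' exam and a ~12-month retest generated from the classical true-score model
#' with practice gain and regression to the mean; no dementia events. This is
#' the sample on which change norms are fitted.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return An `np_cohort` with 2 visits per subject.
#' @export
generate_reference_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "np_sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_reference
  if (n == 0) {
    return(as_cohort(empty_cohort_frame(),
                     provenance = "synthetic reference (empty)"))
  }
  demo <- draw_demographics(n, config)
  sc <- draw_test_scores(n, config)
  m12 <- config$visit_interval_months +
    stats::runif(n, -config$visit_jitter_months, config$visit_jitter_months)
  raw_b <- raw_score_matrix(config, sc$baseline)
  raw_f <- raw_score_matrix(config, sc$followup)
  ids <- sprintf("REF%05d", seq_len(n))
  visit_frame <- function(idx, months, raw) {
    data.frame(subject_id = ids, visit_index = idx,
               months_since_baseline = months,
               age_years = demo$age + months / 12,
               sex = demo$sex, education_years = demo$education,
               diagnosis = "NORMAL", cdr_global = 0,
               lm_immediate = raw[, "lm_immediate"],
               lm_delayed = raw[, "lm_delayed"],
               trails_a_seconds = raw[, "trails_a"],
               trails_b_seconds = raw[, "trails_b"],
               animals = raw[, "animals"],
               vegetables = raw[, "vegetables"],
               stringsAsFactors = FALSE)
  }
  df <- rbind(visit_frame(0, 0, raw_b), visit_frame(1, m12, raw_f))
  as_cohort(df, provenance = sprintf("synthetic reference (seed %d)", seed))
}

## Study cohort ----------------------------------------------------------------

#' Generate a NACC-like study cohort
#'
#' Subjects belong to one of three diagnostic strata (NORMAL, impaired
#' without MCI, MCI) held at baseline and the 12-month exam. A per-stratum
#' fraction carries a latent decline process that lowers all six 12-month
#' scores by a shared amount (in units of each test's standard error of the
#' estimate, so one decline unit is about one composite-z unit). Dementia
#' onset is drawn in continuous time from an exponential proportional-hazards
#' model whose log hazard is linear in the latent decline magnitude (plus a
#' stratum offset), then snapped to the next scheduled visit, where the
#' diagnosis becomes DEMENTIA and CDR rises to 1. Dropout censors the visit
#' schedule after the 12-month exam; administrative censoring applies at
#' `max_followup_months`.
#'
#' The test battery is recorded at the baseline and ~12-month exams (the two
#' that feed the decline metric); later surveillance visits carry diagnosis
#' and CDR only.
#'
#' @inheritParams generate_reference_cohort
#' @return An `np_cohort`.
#' @export
generate_study_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "np_sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_study
  if (n == 0) {
    return(as_cohort(empty_cohort_frame(),
                     provenance = "synthetic study (empty)"))
  }
  strata <- names(config$stratum_fractions)
  stratum <- sample(strata, n, replace = TRUE, prob = config$stratum_fractions)
  demo <- draw_demographics(n, config)

  decliner <- stats::runif(n) < config$decline_fraction[stratum]
  delta <- pmax(0, stats::rnorm(n, config$decline_rate_mean,
                                config$decline_rate_sd)) * decliner

  sc <- draw_test_scores(n, config,
                         ability_shift_sd = config$stratum_ability_shift[stratum],
                         decline_shift = delta)
  raw_b <- raw_score_matrix(config, sc$baseline)
  raw_f <- raw_score_matrix(config, sc$followup)

  # continuous-time dementia onset from baseline
  loghaz <- config$stratum_log_hazard[stratum] +
    config$log_hazard_per_decline_unit * delta
  onset <- if (config$baseline_hazard > 0) {
    stats::rexp(n, rate = config$baseline_hazard * exp(loghaz))
  } else {
    rep(Inf, n)
  }

  # visit schedule: 0, 12, 24, ... +/- jitter, capped at max follow-up
  iv <- config$visit_interval_months
  n_sched <- floor(config$max_followup_months / iv)
  sched <- outer(rep(1, n), seq_len(n_sched) * iv) +
    matrix(stats::runif(n * n_sched, -config$visit_jitter_months,
                        config$visit_jitter_months), n, n_sched)
  sched <- cbind(0, pmin(sched, config$max_followup_months))

  # dropout after the 12-month exam; everyone keeps at least visits 0 and 1
  censor_after <- sched[, 2] + if (config$censoring_rate > 0) {
    stats::rexp(n, config$censoring_rate)
  } else {
    rep(Inf, n)
  }
  k_cens <- pmax(rowSums(sched <= censor_after), 2L)
  dem_col <- rowSums(sched < onset) + 1L          # first visit at/after onset
  has_event <- is.finite(onset) & dem_col <= k_cens & dem_col <= ncol(sched)
  k <- ifelse(has_event, dem_col, pmin(k_cens, ncol(sched)))

  # expand to one row per kept visit
  subj <- rep(seq_len(n), k)
  vidx <- sequence(k)                             # 1-based visit column
  times <- sched[cbind(subj, vidx)]
  is_last <- vidx == k[subj]
  is_dem <- is_last & has_event[subj]

  # pre-dementia CDR by stratum (per-subject constant)
  u_cdr <- stats::runif(n)
  cdr_pre <- ifelse(stratum == "NORMAL", 0,
                    ifelse(stratum == "IMPAIRED_NOT_MCI",
                           ifelse(u_cdr < 0.5, 0, 0.5),
                           ifelse(u_cdr < 0.8, 0.5, 0)))

  battery <- matrix(NA_real_, length(subj), 6,
                    dimnames = list(NULL, np_tests()))
  battery[vidx == 1, ] <- raw_b[subj[vidx == 1], , drop = FALSE]
  fup_row <- vidx == 2 & !is_dem                  # no battery at a dementia exam
  battery[fup_row, ] <- raw_f[subj[fup_row], , drop = FALSE]

  df <- data.frame(
    subject_id = sprintf("STU%05d", subj),
    visit_index = vidx - 1L,
    months_since_baseline = times,
    age_years = demo$age[subj] + times / 12,
    sex = demo$sex[subj],
    education_years = demo$education[subj],
    diagnosis = ifelse(is_dem, "DEMENTIA", stratum[subj]),
    cdr_global = ifelse(is_dem, 1, cdr_pre[subj]),
    lm_immediate = battery[, "lm_immediate"],
    lm_delayed = battery[, "lm_delayed"],
    trails_a_seconds = battery[, "trails_a"],
    trails_b_seconds = battery[, "trails_b"],
    animals = battery[, "animals"],
    vegetables = battery[, "vegetables"],
    stringsAsFactors = FALSE)
  as_cohort(df, provenance = sprintf("synthetic study (seed %d)", seed))
}

## Records-level survival simulator (oracle harness) ---------------------------

#' Simulate analysis-ready survival records directly
#'
#' Generates survival records without passing through the cohort generator:
#' composite NP decline z-scores from the stable/decliner mixture,
#' covariates, and event/censoring times from an exponential
#' proportional-hazards model whose log hazard is linear in the *measured*
#' decline (`-z`). Because the hazard is defined on the measured predictor, a
#' Cox fit on `-z` recovers `log_hazard_per_decline_unit` without
#' measurement-error attenuation; this is the harness used to verify the
#' survival-model stage in isolation.
#'
#' @param n number of records.
#' @param config a [sim_config()]; hazard, stratum, decline-mixture,
#'   censoring and demographic settings are taken from it.
#' @param seed integer seed.
#' @param age_log_hr,male_log_hr,education_log_hr true covariate log hazard
#'   ratios (per year, MALE vs FEMALE, per year).
#' @return A data.frame of survival records (same shape as
#'   [build_survival_records()] output).
#' @export
simulate_survival_records <- function(n, config = sim_config(), seed = 1L,
                                      age_log_hr = 0.03, male_log_hr = 0.2,
                                      education_log_hr = -0.03) {
  stopifnot(inherits(config, "np_sim_config"), n >= 1)
  set.seed(as.integer(seed))
  strata <- names(config$stratum_fractions)
  stratum <- sample(strata, n, replace = TRUE, prob = config$stratum_fractions)
  demo <- draw_demographics(n, config)
  decliner <- stats::runif(n) < config$decline_fraction[stratum]
  delta <- pmax(0, stats::rnorm(n, config$decline_rate_mean,
                                config$decline_rate_sd)) * decliner
  # measured composite z: true decline plus the mean of six unit-variance
  # subtest measurement errors
  z <- -delta + stats::rnorm(n, 0, 1 / sqrt(6))
  loghaz <- log(config$baseline_hazard) +
    config$stratum_log_hazard[stratum] +
    config$log_hazard_per_decline_unit * (-z) +
    age_log_hr * (demo$age - config$age_mean) +
    male_log_hr * (demo$sex == "MALE") +
    education_log_hr * (demo$education - config$education_mean)
  t_event <- stats::rexp(n, exp(loghaz))
  horizon <- config$max_followup_months - config$visit_interval_months
  t_cens <- pmin(if (config$censoring_rate > 0)
    stats::rexp(n, config$censoring_rate) else rep(Inf, n), horizon)
  time <- pmax(pmin(t_event, t_cens), 1e-6)
  data.frame(subject_id = sprintf("SIM%05d", seq_len(n)),
             time_months = time,
             event = t_event <= t_cens,
             age_years = demo$age, sex = demo$sex,
             education_years = demo$education,
             np_decline_z = z,
             np_status = classify(z),
             diagnosis_12m = stratum,
             stringsAsFactors = FALSE)
}
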