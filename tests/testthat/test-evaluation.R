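# Eligibility, survival-record construction, conversion contrasts, Cox models,
# ANCOVA, progression curves, and the CDR sensitivity outcome.

test_that("eligibility charges each exclusion to its first failing rule", {
  co <- eligibility_fixture()
  res <- apply_eligibility(co)
  expected <- eligibility_expected_counts()
  got <- setNames(res$ledger$n, res$ledger$rule)
  expect_equal(got[names(expected)], expected)
  # conservation: excluded + eligible = input subjects
  expect_equal(sum(res$ledger$n), n_subjects(co))
  expect_equal(length(res$exclusions) + got[["eligible"]], n_subjects(co))
  expect_setequal(unique(res$cohort$subject_id), c("E02", "E08", "E11"))
  # every exclusion has exactly one rule
  expect_true(all(res$exclusions %in% setdiff(res$ledger$rule, "eligible")))
})

test_that("survival records use the 12-month exam as time origin", {
  df <- rbind(
    # converts at month 36, follow-up exam at 12 -> time 24, event
    visit_row("C1", 0, 0, 70, lm1 = 10, lm2 = 9, ta = 30, tb = 80, an = 21, veg = 15),
    visit_row("C1", 1, 12, 71, lm1 = 10, lm2 = 9, ta = 25, tb = 78, an = 20, veg = 14),
    visit_row("C1", 2, 24, 72), visit_row("C1", 3, 36, 73, diagnosis = "DEMENTIA", cdr = 1),
    # censored at month 60 -> time 48, no event
    visit_row("C2", 0, 0, 66, lm1 = 12, lm2 = 11, ta = 28, tb = 70, an = 23, veg = 16),
    visit_row("C2", 1, 12, 67, lm1 = 12, lm2 = 11, ta = 29, tb = 72, an = 22, veg = 15),
    visit_row("C2", 2, 36, 69), visit_row("C2", 3, 60, 71)
  )
  co <- as_cohort(df)
  s <- score_cohort(co)
  rec <- build_survival_records(co, s)
  r1 <- rec[rec$subject_id == "C1", ]
  expect_equal(r1$time_months, 24); expect_true(r1$event)
  expect_equal(r1$diagnosis_12m, "NORMAL")
  r2 <- rec[rec$subject_id == "C2", ]
  expect_equal(r2$time_months, 48); expect_false(r2$event)

  # baseline origin available behind the flag
  recb <- build_survival_records(co, s, time_origin = "baseline")
  expect_equal(recb$time_months[recb$subject_id == "C1"], 36)

  # indeterminate subjects are dropped with a recorded count
  df2 <- rbind(df, visit_row("C3", 0, 0, 70), visit_row("C3", 1, 12, 71),
               visit_row("C3", 2, 30, 72.5))
  co2 <- as_cohort(df2)
  rec2 <- build_survival_records(co2, score_cohort(co2))
  expect_false("C3" %in% rec2$subject_id)
  expect_equal(unname(attr(rec2, "dropped")["indeterminate"]), 1)
})

test_that("conversion table matches the hand-computed 2x2 chi-squared", {
  # 30/100 converters among NP+ vs 10/100 among NP-: expected counts
  # 20/80/20/80 give chi2 = 12.5 on 1 df
  rec <- data.frame(
    subject_id = sprintf("s%03d", 1:200),
    time_months = 24, event = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 10, 90)),
    age_years = 75, sex = "FEMALE", education_years = 14,
    np_decline_z = rep(c(-1, 0), c(100, 100)),
    np_status = rep(c("NP_PLUS", "NP_MINUS"), each = 100),
    diagnosis_12m = "NORMAL", stringsAsFactors = FALSE)
  ct <- conversion_table(rec)
  expect_equal(ct$tests$chi_squared[ct$tests$diagnosis == "NORMAL"], 12.5)
  expect_equal(ct$tests$df[1], 1L)
  cells <- ct$cells
  expect_equal(cells$conversion_proportion[cells$np_status == "NP_PLUS"], 0.30)
  expect_equal(cells$conversion_proportion[cells$np_status == "NP_MINUS"], 0.10)
  # cross-check: proportions recomputable directly from the records
  expect_equal(cells$converters[cells$np_status == "NP_PLUS"],
               sum(rec$event[rec$np_status == "NP_PLUS"]))

  # identical conversion in NP+ and NP- gives chi2 = 0
  rec0 <- rec
  rec0$event <- rep(c(TRUE, FALSE), 100)
  ct0 <- conversion_table(rec0)
  expect_equal(ct0$tests$chi_squared[1], 0)

  # empty cell -> undefined statistic with warning
  rec1 <- rec[rec$np_status == "NP_PLUS", ]
  expect_warning(ct1 <- conversion_table(rec1), "empty margin")
  expect_true(is.na(ct1$tests$chi_squared[1]))
})

test_that("hazard linked to decline orders NP+ above NP- in every stratum", {
  r <- simulate_survival_records(20000, seed = 77)
  ct <- conversion_table(r)
  for (dx in unique(ct$cells$diagnosis)) {
    p_plus <- ct$cells$conversion_proportion[ct$cells$diagnosis == dx &
                                               ct$cells$np_status == "NP_PLUS"]
    p_minus <- ct$cells$conversion_proportion[ct$cells$diagnosis == dx &
                                                ct$cells$np_status == "NP_MINUS"]
    expect_gt(p_plus, p_minus)
  }
})

test_that("Cox model recovers a null decline effect and demands events", {
  cfg0 <- sim_config(log_hazard_per_decline_unit = 0)
  r <- simulate_survival_records(4000, cfg0, seed = 55)
  cx <- fit_cox(r, predictor = "z")
  se <- cx$coefficients["decline", "se(coef)"]
  expect_lt(abs(log(cx$hazard_ratio)), 3 * se)
  expect_gt(cx$p_value, 1e-4)

  r0 <- r; r0$event <- FALSE
  expect_error(fit_cox(r0), "at least 2 events")
  expect_error(fit_cox(r, stratum = "NO_SUCH"), "at least 2 events")
})

test_that("continuous-z and binary Cox models agree in direction; HR > 1 means harm", {
  r <- simulate_survival_records(6000, seed = 66)
  cz <- fit_cox(r, predictor = "z")
  cs <- fit_cox(r, predictor = "status")
  expect_gt(cz$hazard_ratio, 1)
  expect_gt(cs$hazard_ratio, 1)
  expect_gt(cz$chi_squared, 0)
  expect_true(cz$ci_lower < cz$hazard_ratio & cz$hazard_ratio < cz$ci_upper)
  # raw per-z coefficient is the negated decline coefficient
  expect_equal(cz$raw_coefficient, -log(cz$hazard_ratio), tolerance = 1e-12)
  # stratum filtering works
  cn <- fit_cox(r, stratum = "NORMAL")
  expect_lt(cn$n, cz$n)
})

test_that("factorial ANCOVA reduces to ANOVA under null covariates and detects shifts", {
  set.seed(31)
  n <- 1200
  rec <- data.frame(
    subject_id = sprintf("a%04d", 1:n),
    time_months = 24,
    event = runif(n) < 0.3,
    age_years = rnorm(n, 74, 7), sex = sample(c("MALE", "FEMALE"), n, TRUE),
    education_years = rnorm(n, 15, 3),
    diagnosis_12m = sample(c("NORMAL", "IMPAIRED_NOT_MCI", "MCI"), n, TRUE),
    stringsAsFactors = FALSE)
  # covariates have zero true effect; converters shifted by -0.3
  rec$np_decline_z <- rnorm(n, 0, 0.5) - 0.3 * rec$event
  rec$np_status <- classify(rec$np_decline_z)
  a <- ancova_factorial(rec)
  # adjusted means equal raw cell means within MC tolerance
  raw <- aggregate(np_decline_z ~ diagnosis_12m + event, rec, mean)
  for (i in seq_len(nrow(a$adjusted_means))) {
    am <- a$adjusted_means[i, ]
    rawm <- raw$np_decline_z[raw$diagnosis_12m == as.character(am$diagnosis) &
                               raw$event == (am$f2 == "DEMENTIA")]
    expect_lt(abs(am$emmean - rawm), 0.1)
  }
  # the converter shift is detected
  f2row <- grep("^f2$", rownames(a$anova))
  expect_lt(a$anova[f2row, "Pr(>F)"], 1e-6)
  # pairwise table covers all 15 cell contrasts with Bonferroni adjustment
  expect_equal(nrow(a$pairwise), choose(6, 2))
})

test_that("progression curves handle degenerate inputs and order risk groups", {
  rec <- data.frame(subject_id = c("x1", "x2"), time_months = c(24, 36),
                    event = c(FALSE, FALSE), age_years = 70, sex = "FEMALE",
                    education_years = 12, np_decline_z = c(-1, 0),
                    np_status = c("NP_PLUS", "NP_MINUS"),
                    diagnosis_12m = "NORMAL", stringsAsFactors = FALSE)
  pc <- progression_curves(rec)
  expect_true(all(pc$cumulative_progression == 0))

  rec$event <- c(TRUE, TRUE); rec$time_months <- c(24, 24)
  rec$np_status <- "NP_PLUS"
  pc2 <- progression_curves(rec)
  g <- pc2[pc2$np_status == "NP_PLUS", ]
  expect_true(all(g$cumulative_progression[g$time_months < 24] == 0))
  expect_equal(max(g$cumulative_progression), 1)
  expect_equal(min(g$cumulative_progression[g$time_months >= 24]), 1)

  # generative ordering: MCI/NP+ lies above NORMAL/NP- throughout
  r <- simulate_survival_records(12000, seed = 88)
  pc3 <- progression_curves(r)
  hi <- pc3[pc3$diagnosis == "MCI" & pc3$np_status == "NP_PLUS", ]
  lo <- pc3[pc3$diagnosis == "NORMAL" & pc3$np_status == "NP_MINUS", ]
  tmax <- min(max(hi$time_months), max(lo$time_months))
  sel <- hi$time_months > 0 & hi$time_months <= tmax
  expect_true(all(hi$cumulative_progression[sel] >=
                    lo$cumulative_progression[match(hi$time_months[sel],
                                                    lo$time_months)]))
})

test_that("CDR sensitivity outcome follows CDR paths from a 0 at the 12-month exam", {
  df <- rbind(
    # CDR 0, 0, 0.5 at months 12/24/36 -> event at 36 (time 24 from origin)
    visit_row("K1", 0, 0, 70, lm1 = 10, lm2 = 9, ta = 30, tb = 80, an = 21, veg = 15),
    visit_row("K1", 1, 12, 71, cdr = 0, lm1 = 10, lm2 = 9, ta = 25, tb = 78, an = 20, veg = 14),
    visit_row("K1", 2, 24, 72, cdr = 0),
    visit_row("K1", 3, 36, 73, cdr = 0.5, diagnosis = "MCI"),
    # CDR 0.5 at the 12-month exam -> excluded from the sensitivity set
    visit_row("K2", 0, 0, 75, lm1 = 12, lm2 = 10, ta = 33, tb = 90, an = 19, veg = 13),
    visit_row("K2", 1, 12, 76, cdr = 0.5, diagnosis = "MCI", lm1 = 11, lm2 = 10,
              ta = 35, tb = 95, an = 18, veg = 12),
    visit_row("K2", 2, 30, 77.5, cdr = 0.5, diagnosis = "MCI"),
    # CDR all 0 -> censored at last visit
    visit_row("K3", 0, 0, 68, lm1 = 13, lm2 = 12, ta = 27, tb = 65, an = 24, veg = 17),
    visit_row("K3", 1, 12, 69, cdr = 0, lm1 = 13, lm2 = 12, ta = 28, tb = 68, an = 23, veg = 16),
    visit_row("K3", 2, 48, 72, cdr = 0)
  )
  co <- as_cohort(df)
  s <- score_cohort(co)
  rec <- cdr_survival_records(co, s)
  expect_setequal(rec$subject_id, c("K1", "K3"))
  k1 <- rec[rec$subject_id == "K1", ]
  expect_true(k1$event); expect_equal(k1$time_months, 24)
  k3 <- rec[rec$subject_id == "K3", ]
  expect_false(k3$event); expect_equal(k3$time_months, 36)
  expect_equal(unname(attr(rec, "dropped")["cdr_nonzero_or_missing_at_12m"]), 1)
})
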