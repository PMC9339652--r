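# NP decline scoring: subtest z-scores, the composite, cutoff classification,
# ROC cutoff re-derivation, and percentile mapping.

test_that("subtest z standardizes the discrepancy by the see", {
  expect_equal(subtest_z(10, 10, 2.5), 0)
  expect_equal(subtest_z(8, 12.833, 2.7730), (8 - 12.833) / 2.7730)
  expect_error(subtest_z(1, 0, 0), "see must be > 0")
  expect_error(subtest_z(1, 0, -1), "see must be > 0")
})

test_that("composite is the unweighted mean and permutation invariant", {
  zs <- c(0.5, -0.5, 0.25, -0.25, 1.0, -1.0)
  expect_equal(mean(zs), 0)  # symmetric set used below through score_cohort
  df <- rbind(visit_row("P1", 0, 0, 70, lm1 = 10, lm2 = 9, ta = 30, tb = 80,
                        an = 21, veg = 15),
              visit_row("P1", 1, 12, 71, lm1 = 10, lm2 = 9, ta = 25, tb = 78,
                        an = 20, veg = 14))
  co <- as_cohort(df)
  s <- score_cohort(co)
  zcols <- paste0("z_", np_tests())
  expect_equal(s$composite_z, mean(unlist(s[1, zcols])))
  expect_equal(s$n_subtests_used, 6)
})

test_that("classification boundary is inclusive and published cutoff applies", {
  cut <- cutoff_spec()
  expect_equal(cut$z_value, -0.5808)
  expect_equal(classify(-0.5808, cut), "NP_PLUS")   # at the boundary
  expect_equal(classify(0, cut), "NP_MINUS")
  expect_equal(classify(-10, cut), "NP_PLUS")
  expect_equal(classify(NA, cut), "INDETERMINATE")
  # all six subtest z equal to -0.6 -> composite -0.6 -> NP+
  expect_equal(classify(-0.6, cut), "NP_PLUS")
})

test_that("missing subtests follow the policy: all six by default, relaxable", {
  df <- rbind(visit_row("M1", 0, 0, 70, lm1 = 10, lm2 = 9, ta = 30, tb = 80,
                        an = 21, veg = 15),
              visit_row("M1", 1, 12, 71, lm1 = 10, lm2 = 9, ta = 25, tb = 78,
                        an = 20))  # vegetables missing at follow-up
  co <- as_cohort(df)
  s6 <- score_cohort(co)
  expect_equal(s6$np_status, "INDETERMINATE")
  expect_true(is.na(s6$composite_z))
  expect_equal(s6$n_subtests_used, 5)
  expect_match(s6$indeterminate_reason, "too few")

  s5 <- score_cohort(co, policy = scoring_policy(min_subtests = 5))
  expect_false(is.na(s5$composite_z))
  expect_equal(s5$composite_z,
               mean(unlist(s5[1, paste0("z_", np_tests())]), na.rm = TRUE))
})

test_that("subjects without a usable follow-up exam are indeterminate", {
  df <- rbind(
    visit_row("N1", 0, 0, 70, lm1 = 10),            # no later visit in window
    visit_row("N1", 1, 30, 72.5, lm1 = 11),
    visit_row("N2", 0, 0, 75, lm1 = 9),
    visit_row("N2", 1, 12, 76, diagnosis = "DEMENTIA", cdr = 1, lm1 = 5)
  )
  co <- as_cohort(df)
  s <- score_cohort(co)
  expect_equal(s$np_status[s$subject_id == "N1"], "INDETERMINATE")
  expect_match(s$indeterminate_reason[s$subject_id == "N1"], "no qualifying")
  expect_equal(s$np_status[s$subject_id == "N2"], "INDETERMINATE")
  expect_match(s$indeterminate_reason[s$subject_id == "N2"], "demented")
})

test_that("the follow-up window picks the visit closest to 12 months", {
  df <- rbind(visit_row("W1", 0, 0, 70, lm1 = 10, lm2 = 9, ta = 30, tb = 80,
                        an = 21, veg = 15),
              visit_row("W1", 1, 7, 70.6, lm1 = 12, lm2 = 11, ta = 28, tb = 75,
                        an = 22, veg = 16),
              visit_row("W1", 2, 13, 71.1, lm1 = 11, lm2 = 10, ta = 29, tb = 77,
                        an = 21, veg = 15),
              visit_row("W1", 3, 26, 72.2, lm1 = 10, lm2 = 9, ta = 31, tb = 80,
                        an = 20, veg = 14))
  s <- score_cohort(as_cohort(df))
  expect_equal(s$followup_visit_index, 2)
  expect_equal(s$followup_months, 13)
})

test_that("a lower follow-up score never raises any z (monotonicity)", {
  base <- list(lm1 = 12, lm2 = 10, ta = 35, tb = 90, an = 20, veg = 14)
  mk <- function(f) {
    df <- rbind(do.call(visit_row, c(list("X", 0, 0, 70), base)),
                do.call(visit_row, c(list("X", 1, 12, 71), f)))
    score_cohort(as_cohort(df))
  }
  good <- mk(list(lm1 = 13, lm2 = 11, ta = 33, tb = 85, an = 21, veg = 15))
  # worse on every test: lower recalls/fluency, longer completion times
  bad <- mk(list(lm1 = 11, lm2 = 9, ta = 40, tb = 110, an = 17, veg = 12))
  zc <- paste0("z_", np_tests())
  expect_true(all(unlist(bad[1, zc]) < unlist(good[1, zc])))
  expect_lt(bad$composite_z, good$composite_z)
})

test_that("scoring a reference population is calibrated per subtest", {
  cfg <- sim_config(n_reference = 4000)
  norms <- fit_norm_table(generate_reference_cohort(cfg, seed = 41))
  s <- score_cohort(generate_reference_cohort(cfg, seed = 42), norms)
  zc <- s[, paste0("z_", np_tests())]
  expect_true(all(abs(colMeans(zc, na.rm = TRUE)) < 0.08))
  expect_true(all(abs(apply(zc, 2, sd, na.rm = TRUE) - 1) < 0.08))
})

test_that("ROC cutoff maximizes Youden's J with ties toward more negative z", {
  # perfect separation: converters all strictly below non-converters
  z <- c(-2, -1.5, -1.2, 0.3, 0.8, 1.1)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_optimal_cutoff(z, y)
  expect_equal(r$youden_j, 1)
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff$z_value, -1.2)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)

  # labels independent of z: J near 0, AUC near 0.5 (permutation oracle)
  set.seed(99)
  z0 <- rnorm(10000); y0 <- runif(10000) < 0.3
  r0 <- roc_optimal_cutoff(z0, y0)
  expect_lt(abs(r0$auc - 0.5), 0.02)
  expect_lt(r0$youden_j, 0.06)

  expect_error(roc_optimal_cutoff(rnorm(5), rep(TRUE, 5)), "both")
})

test_that("ROC cutoff recovers the analytic crossing of two Gaussians", {
  # equal-prior N(-1,1) converters vs N(1,1) non-converters: the density
  # crossing, hence the Youden optimum, is at 0
  set.seed(123)
  n <- 20000
  z <- c(rnorm(n / 2, -1, 1), rnorm(n / 2, 1, 1))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  r <- roc_optimal_cutoff(z, y)
  expect_lt(abs(r$cutoff$z_value - 0), 0.12)
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  z <- rnorm(800) - ifelse(runif(800) < 0.3, 1.2, 0)
  y <- runif(800) < plogis(-1 - z)
  if (!any(y) || all(y)) skip("degenerate draw")
  r <- roc_optimal_cutoff(z, y)
  pr <- pROC::roc(response = y, predictor = z, direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  best <- pROC::coords(pr, "best", best.method = "youden", transpose = FALSE)
  expect_equal(r$sensitivity + r$specificity,
               max(best$sensitivity + best$specificity), tolerance = 1e-9)
})

test_that("percentile of a cutoff matches the classification rule exactly", {
  expect_equal(percentile_of_cutoff(c(-1, 0, 1), cutoff_spec(0)), 100 * 2 / 3)
  expect_equal(percentile_of_cutoff(c(-1, 0, 1), cutoff_spec(-5)), 0)
  # analytic model
  expect_equal(percentile_of_cutoff(NULL, cutoff_spec(-0.5808)),
               100 * pnorm(-0.5808))
  # coherence: fraction NP+ equals percentile/100, boundary inclusive on both
  set.seed(5)
  z <- round(rnorm(500), 1)  # rounding forces boundary ties
  cut <- cutoff_spec(z[17])
  expect_equal(mean(classify(z, cut) == "NP_PLUS"),
               percentile_of_cutoff(z, cut) / 100)
})
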