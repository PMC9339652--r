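# In-code fixtures shared across test files.

# one visit row with sensible defaults; override any field
visit_row <- function(subject_id, visit_index, months, age, sex = "FEMALE",
                      education = 14, diagnosis = "NORMAL", cdr = 0,
                      lm1 = NA, lm2 = NA, ta = NA, tb = NA,
                      an = NA, veg = NA) {
  data.frame(subject_id = subject_id, visit_index = visit_index,
             months_since_baseline = months, age_years = age,
             sex = sex, education_years = education,
             diagnosis = diagnosis, cdr_global = cdr,
             lm_immediate = lm1, lm_delayed = lm2,
             trails_a_seconds = ta, trails_b_seconds = tb,
             animals = an, vegetables = veg,
             stringsAsFactors = FALSE)
}

# two-subject cohort with a complete battery at baseline and ~12 months;
# subject W001 is the worked-example case (LM-I 10 -> 10, Trails-A 30 -> 25 s, ...)
worked_example_cohort <- function() {
  df <- rbind(
    visit_row("W001", 0, 0,    72.0, lm1 = 10, lm2 = 9, ta = 30, tb = 80,
              an = 21, veg = 15),
    visit_row("W001", 1, 12.0, 73.0, lm1 = 10, lm2 = 9, ta = 25, tb = 78,
              an = 20, veg = 14),
    visit_row("W002", 0, 0,    68.0, sex = "MALE", lm1 = 14, lm2 = 13,
              ta = 28, tb = 70, an = 24, veg = 17),
    visit_row("W002", 1, 11.5, 69.0, sex = "MALE", lm1 = 15, lm2 = 14,
              ta = 27, tb = 66, an = 25, veg = 18)
  )
  as_cohort(df, provenance = "worked example")
}

# hand-arithmetic oracle for the worked-example subject W001: plain formulas,
# no package functions
worked_example_expected_z <- function() {
  c(lm_immediate = (10 - (6.883 + 0.595 * 10)) / 2.7730,
    lm_delayed   = (9 - (4.810 + 0.680 * 9)) / 3.1780,
    trails_a     = (-log10(25) - (-(0.589 + 0.598 * log10(30)))) / 0.1009,
    trails_b     = (-log10(78) - (-(0.656 + 0.643 * log10(80)))) / 0.1374,
    animals      = (20 - (8.410 + 0.623 * 21)) / 4.0650,
    vegetables   = (14 - (4.464 + 0.687 * 15)) / 3.2700)
}

# 12-subject fixture exercising every eligibility rule; hand-counted oracle:
#   age 2, baseline_diagnosis 1, exam_count 2, followup_duration 2,
#   dementia_within_12m 2, eligible 3
eligibility_fixture <- function() {
  df <- rbind(
    # E01: aged 59 at baseline -> age
    visit_row("E01", 0, 0, 59), visit_row("E01", 1, 12, 60),
    visit_row("E01", 2, 24, 61),
    # E02: eligible (age exactly 60)
    visit_row("E02", 0, 0, 60), visit_row("E02", 1, 12, 61),
    visit_row("E02", 2, 24, 62),
    # E03: demented at baseline -> baseline_diagnosis
    visit_row("E03", 0, 0, 75, diagnosis = "DEMENTIA", cdr = 1),
    visit_row("E03", 1, 12, 76, diagnosis = "DEMENTIA", cdr = 1),
    visit_row("E03", 2, 24, 77, diagnosis = "DEMENTIA", cdr = 1),
    # E04: aged 58 AND only 2 exams -> age (first failing rule)
    visit_row("E04", 0, 0, 58), visit_row("E04", 1, 13, 59),
    # E05: only 2 exams -> exam_count
    visit_row("E05", 0, 0, 70), visit_row("E05", 1, 14, 71),
    # E06: 3 exams but total follow-up exactly 12 months -> followup_duration
    visit_row("E06", 0, 0, 66), visit_row("E06", 1, 6, 66.5),
    visit_row("E06", 2, 12, 67),
    # E07: demented at month 11 (still 3 exams, 24 months) -> dementia_within_12m
    visit_row("E07", 0, 0, 71), visit_row("E07", 1, 11, 72, diagnosis = "DEMENTIA", cdr = 1),
    visit_row("E07", 2, 24, 73, diagnosis = "DEMENTIA", cdr = 1),
    # E08: eligible MCI subject converting late
    visit_row("E08", 0, 0, 74, diagnosis = "MCI", cdr = 0.5),
    visit_row("E08", 1, 12, 75, diagnosis = "MCI", cdr = 0.5),
    visit_row("E08", 2, 30, 76.5, diagnosis = "DEMENTIA", cdr = 1),
    # E09: a single exam -> exam_count
    visit_row("E09", 0, 0, 80),
    # E10: 4 exams but all within 10 months -> followup_duration
    visit_row("E10", 0, 0, 69), visit_row("E10", 1, 3, 69.2),
    visit_row("E10", 2, 6, 69.5), visit_row("E10", 3, 10, 69.8),
    # E11: eligible
    visit_row("E11", 0, 0, 77, diagnosis = "IMPAIRED_NOT_MCI"),
    visit_row("E11", 1, 12, 78, diagnosis = "IMPAIRED_NOT_MCI"),
    visit_row("E11", 2, 26, 79, diagnosis = "IMPAIRED_NOT_MCI"),
    # E12: demented at exactly month 12 -> dementia_within_12m
    visit_row("E12", 0, 0, 73), visit_row("E12", 1, 12, 74, diagnosis = "DEMENTIA", cdr = 1),
    visit_row("E12", 2, 25, 75, diagnosis = "DEMENTIA", cdr = 1)
  )
  as_cohort(df, provenance = "eligibility fixture")
}

eligibility_expected_counts <- function() {
  c(age = 2, baseline_diagnosis = 1, exam_count = 2, followup_duration = 2,
    dementia_within_12m = 2, eligible = 3)
}

# small config for fast simulations in tests (overridable defaults)
small_config <- function(...) {
  args <- list(n_reference = 200, n_study = 400)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
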