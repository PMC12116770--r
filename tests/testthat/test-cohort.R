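mk_dx <- function(pid, dates, codes, setting = "outpatient") {
  data.frame(patient_id = pid, service_date = as.Date(dates), code = codes,
             code_system = ifelse(grepl("^[0-9]", codes), "icd9", "icd10cm"),
             setting = setting, primary = TRUE, stringsAsFactors = FALSE)
}

test_that("index date is the earliest in-window schizophrenia code by prefix", {
  crit <- cohort_criteria()
  dx <- mk_dx("p1", c("2017-01-10", "2016-03-15"), c("F20.9", "F20.0"))
  expect_equal(find_index_date(dx, crit), as.Date("2016-03-15"))
  # outside the window
  expect_true(is.na(find_index_date(mk_dx("p1", "2015-06-01", "F20.9"), crit)))
  # after the window end
  expect_true(is.na(find_index_date(mk_dx("p1", "2022-03-15", "F20.9"), crit)))
  # prefix matching across code systems and dotting, incl. leap day
  expect_equal(find_index_date(mk_dx("p1", "2020-02-29", "F20.9"), crit),
               as.Date("2020-02-29"))
  expect_equal(find_index_date(mk_dx("p1", "2018-05-01", "29590"), crit),
               as.Date("2018-05-01"))
  # non-schizophrenia codes never index
  expect_true(is.na(find_index_date(mk_dx("p1", "2018-05-01", "F25.0"), crit)))
  # oracle: brute-force scan over every record
  dx <- mk_dx("p1", c("2015-12-31", "2016-01-01", "2019-06-01", "2021-01-01"),
              c("F20.1", "I10", "295.30", "F20.9"))
  ok <- as.Date(character(0))
  for (i in seq_len(nrow(dx))) {
    code <- gsub("[.]", "", toupper(dx$code[i]))
    if ((startsWith(code, "295") || startsWith(code, "F20")) &&
        dx$service_date[i] >= crit$window_start &&
        dx$service_date[i] <= crit$window_end)
      ok <- c(ok, dx$service_date[i])
  }
  expect_equal(find_index_date(dx, crit), min(ok))
})

test_that("EHR criteria record every failure with reason codes", {
  crit <- cohort_criteria()
  pats <- data.frame(patient_id = c("good", "one_enc", "dem", "aut", "young",
                                    "late_dem"),
                     birth_year = c(1980, 1980, 1980, 1980, 2003, 1980),
                     stringsAsFactors = FALSE)
  anchor <- function(p) mk_dx(p, "2016-06-01", "Z00.00")
  two_enc <- function(p) mk_dx(p, c("2018-06-01", "2018-09-01"),
                               c("F20.9", "F20.0"))
  dx <- rbind(
    two_enc("good"), anchor("good"),
    mk_dx("one_enc", "2018-06-01", "F20.9"), anchor("one_enc"),
    two_enc("dem"), anchor("dem"), mk_dx("dem", "2018-01-15", "F03.90"),
    two_enc("aut"), anchor("aut"), mk_dx("aut", "2021-12-01", "F84.0"),
    two_enc("young"), anchor("young"),
    # dementia coded after index: prior_to_index timing means not excluded
    two_enc("late_dem"), anchor("late_dem"),
    mk_dx("late_dem", "2019-03-01", "F03.90"))
  el <- apply_ehr_criteria(list(patients = pats, diagnoses = dx), crit)
  row <- function(p) el[el$patient_id == p, ]
  expect_true(row("good")$eligible_ehr)
  expect_equal(row("good")$reasons, "")
  expect_equal(row("good")$index_date, as.Date("2018-06-01"))
  expect_match(row("one_enc")$reasons, "insufficient_sz_encounters")
  expect_match(row("dem")$reasons, "excluded_dx:dementia")
  expect_match(row("aut")$reasons, "excluded_dx:autism")
  expect_match(row("young")$reasons, "under_18")
  expect_true(row("late_dem")$eligible_ehr)
  # multiple failures are all recorded
  pats2 <- data.frame(patient_id = "multi", birth_year = 2004)
  dx2 <- rbind(mk_dx("multi", "2020-06-01", "F20.9"),
               mk_dx("multi", "2020-01-15", "G40.909"))
  el2 <- apply_ehr_criteria(list(patients = pats2, diagnoses = dx2), crit)
  expect_match(el2$reasons, "under_18")
  expect_match(el2$reasons, "insufficient_sz_encounters")
  expect_match(el2$reasons, "no_pre_index_activity")
  expect_match(el2$reasons, "excluded_dx:epilepsy")
  # no schizophrenia code at all
  el3 <- apply_ehr_criteria(list(
    patients = data.frame(patient_id = "none", birth_year = 1970),
    diagnoses = mk_dx("none", "2018-01-01", "I10")), crit)
  expect_match(el3$reasons, "no_index_diagnosis")
})

test_that("qualifying encounters need distinct service dates by default", {
  crit <- cohort_criteria()
  pats <- data.frame(patient_id = "p", birth_year = 1980)
  dup <- rbind(mk_dx("p", c("2018-06-01", "2018-06-01"), c("F20.9", "F20.0")),
               mk_dx("p", "2016-06-01", "Z00.00"))
  el <- apply_ehr_criteria(list(patients = pats, diagnoses = dup), crit)
  expect_match(el$reasons, "insufficient_sz_encounters")
  loose <- cohort_criteria(distinct_encounter_dates = FALSE)
  el2 <- apply_ehr_criteria(list(patients = pats, diagnoses = dup), loose)
  expect_true(el2$eligible_ehr)
})

test_that("continuous enrollment honours spans, gaps, and the gap allowance", {
  idx <- as.Date("2018-01-15")
  iv <- function(b, s, e) data.frame(patient_id = "p", start = as.Date(s),
                                     end = as.Date(e), benefit = b)
  full <- rbind(iv("medical", "2018-01-01", "2019-02-01"),
                iv("pharmacy", "2018-01-01", "2019-02-01"))
  expect_true(check_continuous_enrollment(full, idx))
  # pharmacy ends at month 11
  short <- rbind(iv("medical", "2018-01-01", "2019-02-01"),
                 iv("pharmacy", "2018-01-01", "2018-12-10"))
  expect_false(check_continuous_enrollment(short, idx))
  # a benefit entirely missing
  expect_false(check_continuous_enrollment(full[full$benefit == "medical", ], idx))
  # abutting medical intervals with zero-day gap still qualify
  abut <- rbind(iv("medical", "2018-01-01", "2018-06-30"),
                iv("medical", "2018-07-01", "2019-02-01"),
                iv("pharmacy", "2018-01-01", "2019-02-01"))
  expect_true(check_continuous_enrollment(abut, idx))
  # a one-day hole fails at allowance 0 but passes with a 30-day allowance
  hole <- rbind(iv("medical", "2018-01-01", "2018-06-29"),
                iv("medical", "2018-07-01", "2019-02-01"),
                iv("pharmacy", "2018-01-01", "2019-02-01"))
  expect_false(check_continuous_enrollment(hole, idx))
  expect_true(check_continuous_enrollment(hole, idx, gap_days = 30))
  # interval-union oracle on a randomized instance
  withr::with_seed(77, {
    for (rep in 1:20) {
      k <- sample(1:4, 1)
      s <- idx - 10 + sort(sample(0:400, k))
      e <- s + sample(30:200, k, replace = TRUE)
      med <- data.frame(patient_id = "p", start = s, end = e,
                        benefit = "medical")
      days <- seq(idx, add_months(idx, 12), by = "day")
      covered <- vapply(days, function(d) any(s <= d & e >= d), logical(1))
      want <- all(covered)
      got <- check_continuous_enrollment(
        rbind(med, iv("pharmacy", "2017-01-01", "2019-06-01")), idx)
      expect_equal(got, want)
    }
  })
})

test_that("baseline characteristics pick BMI nearest index with pre-index tie-break", {
  pats <- data.frame(patient_id = "p", birth_year = 1980, gender = "Male",
                     race = "White", ethnicity = "Non-Hispanic",
                     region = "South", payer = "Medicaid", cci = 2L,
                     stringsAsFactors = FALSE)
  el <- data.frame(patient_id = "p", index_date = as.Date("2019-06-01"),
                   stringsAsFactors = FALSE)
  dx <- mk_dx("p", "2019-01-01", "F41.1")
  meas <- function(dates, bmis)
    data.frame(patient_id = "p", obs_date = as.Date(dates), bmi = bmis)
  # +10d beats -30d
  bl <- baseline_characteristics(
    list(patients = pats, diagnoses = dx,
         measurements = meas(c("2019-05-02", "2019-06-11"), c(31, 28))), el)
  expect_equal(bl$bmi, 28)
  # exact tie at +-10d goes to the pre-index value
  bl <- baseline_characteristics(
    list(patients = pats, diagnoses = dx,
         measurements = meas(c("2019-05-22", "2019-06-11"), c(31, 28))), el)
  expect_equal(bl$bmi, 31)
  # observations beyond +-12 months are invisible
  bl <- baseline_characteristics(
    list(patients = pats, diagnoses = dx,
         measurements = meas("2018-05-01", 33)), el)
  expect_true(is.na(bl$bmi))
  expect_equal(bl$cci, 2L)
  expect_equal(bl$age, 39L)
})

test_that("comorbidity flags use the 12-month pre-index half-open window", {
  pats <- data.frame(patient_id = c("in", "early", "on_index"),
                     birth_year = 1980, cci = 0L, stringsAsFactors = FALSE)
  el <- data.frame(patient_id = c("in", "early", "on_index"),
                   index_date = as.Date("2019-06-01"), stringsAsFactors = FALSE)
  dx <- rbind(mk_dx("in", "2018-07-01", "F41.1"),      # 11 months before
              mk_dx("early", "2018-05-01", "F41.1"),   # 13 months before
              mk_dx("on_index", "2019-06-01", "F41.1")) # on index: excluded
  bl <- baseline_characteristics(
    list(patients = pats, diagnoses = dx,
         measurements = NULL), el)
  expect_true(bl$anxiety[bl$patient_id == "in"])
  expect_false(bl$anxiety[bl$patient_id == "early"])
  expect_false(bl$anxiety[bl$patient_id == "on_index"])
})

test_that("cohorts agree with the generator's eligibility draws and obey the subset law", {
  ds <- generate_dataset(smoke_config(n_patients = 120), seed = 19)
  co <- build_cohorts(ds)
  expect_equal(co$eligibility$eligible_ehr, ds$gold$eligible_ehr)
  expect_equal(co$eligibility$eligible_linked, ds$gold$eligible_linked)
  expect_true(all(co$linked_cohort %in% co$ehr_cohort))
  att <- co$attrition
  expect_equal(att$n_remaining[att$criterion == "assessed"], 120)
  expect_equal(att$n_remaining[att$criterion == "ehr_cohort"],
               length(co$ehr_cohort))
  expect_equal(att$n_remaining[att$criterion == "linked_cohort"],
               length(co$linked_cohort))
})

test_that("eligibility is invariant to input row order", {
  ds <- generate_dataset(smoke_config(n_patients = 80), seed = 23)
  co1 <- build_cohorts(ds)
  withr::with_seed(5, {
    ds$diagnoses <- ds$diagnoses[sample(nrow(ds$diagnoses)), ]
    ds$coverage <- ds$coverage[sample(nrow(ds$coverage)), ]
    ds$notes <- ds$notes[sample(nrow(ds$notes)), ]
  })
  co2 <- build_cohorts(ds)
  expect_equal(co2$eligibility$eligible_ehr, co1$eligibility$eligible_ehr)
  expect_equal(co2$eligibility$eligible_linked, co1$eligibility$eligible_linked)
  expect_equal(co2$eligibility$index_date, co1$eligibility$index_date)
})

test_that("degenerate eligibility configs produce full or empty cohorts", {
  all_in <- smoke_config(
    n_patients = 40,
    demographics = list(under_18_rate = 0),
    eligibility = list(encounters_rate = 1, activity_rate = 1,
                       exclusion_dx_rate = 0, benign_exclusion_code_rate = 0,
                       enrollment_rate = 1))
  ds <- generate_dataset(all_in, seed = 2)
  co <- build_cohorts(ds)
  expect_equal(length(co$ehr_cohort), 40)
  expect_equal(length(co$linked_cohort), 40)
  no_claims <- override_config(all_in, eligibility = list(enrollment_rate = 0))
  ds2 <- generate_dataset(no_claims, seed = 2)
  co2 <- build_cohorts(ds2)
  expect_equal(length(co2$ehr_cohort), 40)
  expect_equal(length(co2$linked_cohort), 0)
})
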