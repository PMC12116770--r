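# Retrospective cohort construction: index dates, inclusion/exclusion
# criteria with per-patient reason codes, continuous-enrollment checks,
# baseline characteristics, and attrition accounting.

#' Cohort selection criteria
#'
#' Defaults mirror the study design this package operationalizes: adults
#' (18+) with at least two outpatient schizophrenia encounters (ICD-9 295.xx
#' or ICD-10-CM F20.x) on or after the window start, an index date at the
#' first in-window schizophrenia diagnosis, at least 12 months of EHR
#' activity before index, no exclusionary neurological/developmental
#' diagnosis (stroke, dementia, prion disease, multiple sclerosis, traumatic
#' brain injury, Parkinson's disease, frontotemporal disease prior to index;
#' autism spectrum disorder, epilepsy, intellectual disability at any time),
#' and — for the linked-claims subcohort — 12 months of continuous medical
#' and pharmacy enrollment after index.
#'
#' @param window_start,window_end index-date window bounds.
#' @param min_sz_outpatient_encounters minimum outpatient schizophrenia
#'   encounters (distinct service dates).
#' @param pre_index_activity_months required months of EHR activity before
#'   index.
#' @param post_index_enrollment_months required months of continuous
#'   enrollment after index (linked cohort).
#' @param min_age_years minimum age at index.
#' @param schizophrenia_code_prefixes diagnosis-code prefixes defining
#'   schizophrenia.
#' @param exclusion_code_sets named list: condition -> code prefixes.
#' @param exclusion_timing named character: condition -> `"prior_to_index"`
#'   or `"any_time"`; conditions missing from the map default to
#'   `"prior_to_index"`.
#' @param enrollment_gap_days maximum allowed coverage gap, in days.
#' @param distinct_encounter_dates must qualifying encounters fall on
#'   distinct service dates?
#' @return A `cog_criteria` list.
#' @export
cohort_criteria <- function(window_start = as.Date("2016-01-01"),
                            window_end = as.Date("2022-02-28"),
                            min_sz_outpatient_encounters = 2L,
                            pre_index_activity_months = 12L,
                            post_index_enrollment_months = 12L,
                            min_age_years = 18L,
                            schizophrenia_code_prefixes = c("295", "F20"),
                            exclusion_code_sets = default_exclusion_code_sets(),
                            exclusion_timing = default_exclusion_timing(),
                            enrollment_gap_days = 0L,
                            distinct_encounter_dates = TRUE) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end))
    stop_cogehr("window_start must precede window_end")
  stopifnot(min_sz_outpatient_encounters >= 1,
            pre_index_activity_months >= 1,
            post_index_enrollment_months >= 1)
  structure(list(window_start = window_start, window_end = window_end,
                 min_sz_outpatient_encounters = as.integer(min_sz_outpatient_encounters),
                 pre_index_activity_months = as.integer(pre_index_activity_months),
                 post_index_enrollment_months = as.integer(post_index_enrollment_months),
                 min_age_years = as.integer(min_age_years),
                 schizophrenia_code_prefixes = schizophrenia_code_prefixes,
                 exclusion_code_sets = exclusion_code_sets,
                 exclusion_timing = exclusion_timing,
                 enrollment_gap_days = as.integer(enrollment_gap_days),
                 distinct_encounter_dates = isTRUE(distinct_encounter_dates)),
            class = "cog_criteria")
}

#' @rdname cohort_criteria
#' @export
default_exclusion_code_sets <- function() {
  list(dementia = c("F01", "F02", "F03", "G30"),
       frontotemporal_disease = c("G31.0"),
       prion_disease = c("A81"),
       multiple_sclerosis = c("G35"),
       parkinsons_disease = c("G20"),
       stroke = c("I63"),
       traumatic_brain_injury = c("S06"),
       autism_spectrum_disorder = c("F84"),
       epilepsy = c("G40"),
       intellectual_disability = c("F70", "F71", "F72", "F73", "F78", "F79"))
}

#' @rdname cohort_criteria
#' @export
default_exclusion_timing <- function() {
  c(dementia = "prior_to_index", frontotemporal_disease = "prior_to_index",
    prion_disease = "prior_to_index", multiple_sclerosis = "prior_to_index",
    parkinsons_disease = "prior_to_index", stroke = "prior_to_index",
    traumatic_brain_injury = "prior_to_index",
    autism_spectrum_disorder = "any_time", epilepsy = "any_time",
    intellectual_disability = "any_time")
}

#' Find the index date for one patient
#'
#' The earliest schizophrenia-coded diagnosis (prefix match) with service
#' date inside the criteria window; `NA` if none.
#'
#' @param dx data frame of one patient's diagnosis records (`service_date`,
#'   `code`).
#' @param crit a `cog_criteria`.
#' @return A `Date` of length 1, `NA` if no in-window schizophrenia code.
#' @export
find_index_date <- function(dx, crit = cohort_criteria()) {
  d <- as.Date(dx$service_date)
  is_sz <- icd_prefix_match(dx$code, crit$schizophrenia_code_prefixes)
  ok <- is_sz & d >= crit$window_start & d <= crit$window_end
  if (!any(ok)) return(as.Date(NA))
  min(d[ok])
}

#' Apply the EHR-stage eligibility criteria to all patients
#'
#' Checks, in order: an index date exists; age at index meets the minimum;
#' enough outpatient schizophrenia encounters on/after the window start;
#' earliest EHR activity (any diagnosis or note) at least
#' `pre_index_activity_months` before index; no exclusionary diagnosis under
#' its timing rule.  All failures are recorded, not just the first.
#'
#' @param bundle list with data frames `patients` (`patient_id`,
#'   `birth_year`), `diagnoses` (`patient_id`, `service_date`, `code`,
#'   `setting`), and optionally `notes` (`patient_id`, `note_date`).
#' @param crit a `cog_criteria`.
#' @return Data frame with one row per patient: `patient_id`, `index_date`,
#'   `eligible_ehr`, `reasons` (semicolon-joined failure codes, empty when
#'   eligible).
#' @export
apply_ehr_criteria <- function(bundle, crit = cohort_criteria()) {
  pats <- bundle$patients
  dx <- bundle$diagnoses
  dx$service_date <- as.Date(dx$service_date)
  ids <- as.character(pats$patient_id)
  n <- length(ids)

  norm <- normalize_icd(dx$code)
  is_sz <- icd_prefix_match(dx$code, crit$schizophrenia_code_prefixes)

  # index: earliest in-window schizophrenia code
  inwin <- is_sz & dx$service_date >= crit$window_start &
    dx$service_date <= crit$window_end
  idx_tab <- tapply(dx$service_date[inwin], dx$patient_id[inwin], min)
  index_date <- as.Date(rep(NA, n), origin = "1970-01-01")
  hit <- match(names(idx_tab), ids)
  index_date[hit] <- as.Date(idx_tab, origin = "1970-01-01")

  # qualifying outpatient encounters on/after window start
  qual <- is_sz & dx$setting == "outpatient" &
    dx$service_date >= crit$window_start
  enc <- if (crit$distinct_encounter_dates) {
    u <- unique(dx[qual, c("patient_id", "service_date")])
    table(factor(u$patient_id, levels = ids))
  } else table(factor(dx$patient_id[qual], levels = ids))
  enc_n <- as.integer(enc[ids])

  # earliest EHR activity: any diagnosis or note event
  act_dates <- dx$service_date
  act_pid <- as.character(dx$patient_id)
  if (!is.null(bundle$notes) && nrow(bundle$notes)) {
    act_dates <- c(act_dates, as.Date(bundle$notes$note_date))
    act_pid <- c(act_pid, as.character(bundle$notes$patient_id))
  }
  first_tab <- tapply(act_dates, act_pid, min)
  first_act <- as.Date(rep(NA, n), origin = "1970-01-01")
  hit <- match(names(first_tab), ids)
  first_act[hit] <- as.Date(first_tab, origin = "1970-01-01")

  age_at_index <- as.integer(format(index_date, "%Y")) -
    pats$birth_year[match(ids, pats$patient_id)]

  # exclusionary conditions under their timing rule
  excl_hits <- vector("list", n)
  for (cond in names(crit$exclusion_code_sets)) {
    m <- icd_prefix_match(dx$code, crit$exclusion_code_sets[[cond]])
    if (!any(m)) next
    timing <- crit$exclusion_timing[[cond]] %||% "prior_to_index"
    sub <- dx[m, , drop = FALSE]
    pid_i <- match(as.character(sub$patient_id), ids)
    keep <- if (identical(timing, "prior_to_index"))
      !is.na(index_date[pid_i]) & sub$service_date < index_date[pid_i]
    else rep(TRUE, nrow(sub))
    for (i in unique(pid_i[keep]))
      excl_hits[[i]] <- c(excl_hits[[i]], cond)
  }

  reasons <- character(n)
  eligible <- logical(n)
  act_cut <- add_months(index_date, -crit$pre_index_activity_months)
  for (i in seq_len(n)) {
    r <- character(0)
    if (is.na(index_date[i])) r <- c(r, "no_index_diagnosis")
    else if (!is.na(age_at_index[i]) && age_at_index[i] < crit$min_age_years)
      r <- c(r, sprintf("under_%d", crit$min_age_years))
    if (enc_n[i] < crit$min_sz_outpatient_encounters)
      r <- c(r, "insufficient_sz_encounters")
    if (!is.na(index_date[i]) &&
        (is.na(first_act[i]) || first_act[i] > act_cut[i]))
      r <- c(r, "no_pre_index_activity")
    if (!is.null(excl_hits[[i]]))
      r <- c(r, paste0("excluded_dx:", sort(unique(excl_hits[[i]]))))
    reasons[i] <- paste(r, collapse = ";")
    eligible[i] <- length(r) == 0
  }
  data.frame(patient_id = ids, index_date = index_date,
             age_at_index = age_at_index, n_sz_outpatient = enc_n,
             eligible_ehr = eligible, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Check continuous enrollment after an index date
#'
#' True iff medical AND pharmacy coverage each span
#' `[index, index + months]` with no gap exceeding the allowance.
#'
#' @param intervals one patient's coverage intervals (`start`, `end`
#'   inclusive dates, `benefit` in `medical`/`pharmacy`).
#' @param index index date.
#' @param months required months of coverage.
#' @param gap_days maximum allowed gap between intervals, in days.
#' @return Logical scalar.
#' @export
check_continuous_enrollment <- function(intervals, index, months = 12L,
                                        gap_days = 0L) {
  index <- as.Date(index)
  if (is.na(index)) return(FALSE)
  target_end <- add_months(index, months)
  for (ben in c("medical", "pharmacy")) {
    iv <- intervals[intervals$benefit == ben, , drop = FALSE]
    if (!nrow(iv)) return(FALSE)
    runs <- merge_intervals(as.Date(iv$start), as.Date(iv$end), gap_days)
    if (!any(runs$start <= index & runs$end >= target_end)) return(FALSE)
  }
  TRUE
}

merge_intervals <- function(s, e, gap_days = 0L) {
  o <- order(s); s <- s[o]; e <- e[o]
  rs <- s[1]; re <- e[1]
  out_s <- as.Date(character(0)); out_e <- as.Date(character(0))
  for (k in seq_along(s)[-1]) {
    if (as.integer(s[k] - re) - 1L <= gap_days) re <- max(re, e[k])
    else { out_s <- c(out_s, rs); out_e <- c(out_e, re); rs <- s[k]; re <- e[k] }
  }
  data.frame(start = c(out_s, rs), end = c(out_e, re))
}

#' Baseline characteristics at index
#'
#' Demographics at index, comorbidity flags over the 12 months before index
#' (at least one qualifying code in `[index - 12mo, index)`), BMI as the
#' closest recorded value within 12 months before or after index (ties go to
#' the pre-index value), and the Charlson Comorbidity Index score carried on
#' the patient record.
#'
#' @param bundle list with `patients`, `diagnoses`, `measurements`.
#' @param eligibility data frame from [apply_ehr_criteria()] (or any frame
#'   with `patient_id`, `index_date`); rows without an index are dropped.
#' @param comorbidity_code_sets named list: condition -> code prefixes.
#' @return Data frame: one row per indexed patient with demographics, `cci`,
#'   `bmi`, and one logical flag per comorbidity.
#' @export
baseline_characteristics <- function(bundle, eligibility,
                                     comorbidity_code_sets =
                                       default_comorbidity_code_sets()) {
  el <- eligibility[!is.na(eligibility$index_date), , drop = FALSE]
  pats <- bundle$patients
  m <- match(el$patient_id, pats$patient_id)
  out <- data.frame(patient_id = el$patient_id,
                    index_date = as.Date(el$index_date),
                    stringsAsFactors = FALSE)
  out$age <- as.integer(format(out$index_date, "%Y")) - pats$birth_year[m]
  for (v in c("gender", "race", "ethnicity", "region", "payer"))
    if (v %in% names(pats)) out[[v]] <- pats[[v]][m]
  out$cci <- pats$cci[m]

  # BMI closest to index within +-12 months; tie -> pre-index value
  ms <- bundle$measurements
  out$bmi <- NA_real_
  if (!is.null(ms) && nrow(ms)) {
    ms$obs_date <- as.Date(ms$obs_date)
    for (i in seq_len(nrow(out))) {
      sub <- ms[ms$patient_id == out$patient_id[i], , drop = FALSE]
      if (!nrow(sub)) next
      idx <- out$index_date[i]
      lo <- add_months(idx, -12L); hi <- add_months(idx, 12L)
      sub <- sub[sub$obs_date >= lo & sub$obs_date <= hi, , drop = FALSE]
      if (!nrow(sub)) next
      dist <- abs(as.integer(sub$obs_date - idx))
      best <- dist == min(dist)
      if (sum(best) > 1) {  # tie: prefer the pre-index observation
        pre <- best & sub$obs_date <= idx
        best <- if (any(pre)) pre else best
      }
      out$bmi[i] <- sub$bmi[which(best)[1]]
    }
  }

  dx <- bundle$diagnoses
  dx$service_date <- as.Date(dx$service_date)
  lo <- add_months(out$index_date, -12L)
  for (cond in names(comorbidity_code_sets)) {
    mcol <- icd_prefix_match(dx$code, comorbidity_code_sets[[cond]])
    flag <- logical(nrow(out))
    if (any(mcol)) {
      sub <- dx[mcol, , drop = FALSE]
      pid_i <- match(as.character(sub$patient_id), out$patient_id)
      ok <- !is.na(pid_i) & sub$service_date >= lo[pid_i] &
        sub$service_date < out$index_date[pid_i]
      flag[unique(pid_i[ok])] <- TRUE
    }
    out[[cond]] <- flag
  }
  out
}

#' @rdname baseline_characteristics
#' @export
default_comorbidity_code_sets <- function() {
  list(anxiety = c("F41.1", "F41.3", "F41.8", "F41.9", "300.0"),
       bipolar_disorder = c("F31", "296.4", "296.5", "296.6", "296.7"),
       depression = c("F32", "F33", "311"),
       panic_disorder = c("F41.0", "300.01"),
       ptsd = c("F43.1", "309.81"),
       substance_use_disorder = c("F10", "F11", "F12", "F13", "F14", "F15",
                                  "F16", "F18", "F19", "303", "304", "305"))
}

#' Build the EHR and linked-claims cohorts with attrition accounting
#'
#' Applies the EHR criteria, then the continuous-enrollment requirement for
#' the linked subcohort.  The linked cohort is always a subset of the EHR
#' cohort.  The attrition table counts patients dropped at each ordered
#' criterion among those still standing.
#'
#' @param ds a `cog_dataset` (or any list with the same tables).
#' @param crit a `cog_criteria`.
#' @return List with `eligibility` (per-patient results incl.
#'   `eligible_linked`), `ehr_cohort` / `linked_cohort` (patient id
#'   vectors), and `attrition` (criterion, n_remaining, n_dropped).
#' @export
build_cohorts <- function(ds, crit = cohort_criteria()) {
  el <- apply_ehr_criteria(ds, crit)
  enr <- logical(nrow(el))
  cov_split <- split(ds$coverage, as.character(ds$coverage$patient_id))
  for (i in seq_len(nrow(el))) {
    if (!el$eligible_ehr[i]) next
    iv <- cov_split[[el$patient_id[i]]]
    enr[i] <- !is.null(iv) &&
      check_continuous_enrollment(iv, el$index_date[i],
                                  crit$post_index_enrollment_months,
                                  crit$enrollment_gap_days)
  }
  el$eligible_linked <- el$eligible_ehr & enr

  has <- function(tag) grepl(tag, el$reasons, fixed = TRUE)
  steps <- list(
    c("no_index_diagnosis", "no schizophrenia index in window"),
    c(sprintf("under_%d", crit$min_age_years), "under minimum age at index"),
    c("insufficient_sz_encounters", "fewer than required outpatient encounters"),
    c("no_pre_index_activity", "insufficient pre-index EHR activity"),
    c("excluded_dx:", "exclusionary diagnosis"))
  standing <- rep(TRUE, nrow(el))
  att <- data.frame(criterion = "assessed", n_remaining = nrow(el),
                    n_dropped = 0L, stringsAsFactors = FALSE)
  for (sp in steps) {
    drop <- standing & has(sp[1])
    standing <- standing & !drop
    att <- rbind(att, data.frame(criterion = sp[2],
                                 n_remaining = sum(standing),
                                 n_dropped = sum(drop)))
  }
  drop <- standing & !el$eligible_linked
  att <- rbind(att,
               data.frame(criterion = "ehr_cohort", n_remaining = sum(standing),
                          n_dropped = 0L),
               data.frame(criterion = "no continuous post-index enrollment",
                          n_remaining = sum(standing & el$eligible_linked),
                          n_dropped = sum(drop)),
               data.frame(criterion = "linked_cohort",
                          n_remaining = sum(el$eligible_linked),
                          n_dropped = 0L))
  list(eligibility = el,
       ehr_cohort = el$patient_id[el$eligible_ehr],
       linked_cohort = el$patient_id[el$eligible_linked],
       attrition = att)
}
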