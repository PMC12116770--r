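# Synthetic linked EHR + claims generator with gold labels.
#
# The generator emulates the statistical structure the analysis assumes:
# documented impairment at a configurable prevalence (optionally coupled to
# note count), per-domain clean-phrase embedding whose conditional-on-
# documented marginals equal the configured targets, decoy sentences under
# negation/question/goal/family-history constructions, per-patient
# eligibility draws realized as consistent records, and group-specific
# negative binomial utilization streams over the 12 months post-index.

.clean_templates <- c(
  "Patient exhibits %s during today's visit.",
  "Exam reveals %s.",
  "Patient reports %s over the past month.",
  "Clinician observed %s at this encounter.",
  "%s evident on mental status examination.")

.qualified_templates <- c(   # entries needing an impairment qualifier
  "%s are impaired.",
  "%s remain poor.",
  "%s appear limited.")

.decoy_templates <- list(
  negation = c("Denies %s.", "No %s reported.", "Without %s at this time."),
  question = c("Any %s?", "Does the patient have %s?", "Is there %s?"),
  goal = c("Goal: address %s.", "Plan to work on %s.",
           "Will work on %s with patient."),
  family_history = c("Mother has %s.", "Father struggled with %s.",
                     "Family history of %s."))

.filler_sentences <- c(
  "Vital signs stable.",
  "Medication refilled at this visit.",
  "Patient arrived on time for the appointment.",
  "Sleep reported as adequate.",
  "Appetite within normal limits.",
  "Follow-up scheduled in four weeks.",
  "Patient tolerated the session well.",
  "Labs reviewed with the patient.",
  "Blood pressure 122/78.",
  "Continues current medication regimen.",
  "Patient is living with a roommate.",
  "Attends day program twice weekly.",
  "Weight stable since last visit.",
  "Discussed diet and exercise.")

capitalize_sentence <- function(x) {
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

# Build one sentence per event (vectorized).  type is one of clean /
# negation / question / goal / family_history; qualified marks entries whose
# clean mention needs an impairment qualifier in the sentence.
event_sentences <- function(type, phrase, qualified) {
  n <- length(phrase)
  out <- character(n)
  key <- ifelse(type == "clean" & qualified, "clean_qualified", type)
  # decoys of qualifier-gated entries carry a qualifier so the phrase would
  # match were it not excluded
  phrase <- ifelse(type != "clean" & qualified, paste("poor", phrase), phrase)
  pools <- c(list(clean = .clean_templates,
                  clean_qualified = .qualified_templates),
             .decoy_templates)
  for (k in unique(key)) {
    idx <- which(key == k)
    tpl <- sample(pools[[k]], length(idx), replace = TRUE)
    out[idx] <- sprintf(tpl, phrase[idx])
  }
  capitalize_sentence(out)
}

#' Render a synthetic clinical note from planted events
#'
#' Planted clean phrases appear in affirmative declarative sentences; decoys
#' appear under their designated trigger construction (negation / question /
#' goal / family history); filler sentences contain no lexicon phrase.
#' Optionally the note is wrapped in HTML paragraph markup.
#'
#' @param events data frame with columns `type` (one of `"clean"`,
#'   `"negation"`, `"question"`, `"goal"`, `"family_history"`), `phrase`
#'   (the surface phrase) and optionally `qualified` (logical; clean
#'   sentences then carry an impairment qualifier).  May have zero rows.
#' @param n_filler number of filler sentences to interleave.
#' @param markup wrap the note in HTML markup?
#' @return A single string: the raw note text.
#' @export
#' @examples
#' render_note(data.frame(type = "clean", phrase = "poor memory"))
render_note <- function(events, n_filler = 3, markup = FALSE) {
  ev <- if (is.null(events) || nrow(events) == 0) character(0)
        else event_sentences(events$type, events$phrase,
                             events$qualified %||% rep(FALSE, nrow(events)))
  fill <- sample(.filler_sentences, n_filler, replace = n_filler > length(.filler_sentences))
  sentences <- sample(c(ev, fill))
  if (markup)
    paste0("<html><body><p>", paste(sentences, collapse = "</p>\n<p>"),
           "</p></body></html>")
  else paste(sentences, collapse = " ")
}

#' Generate a synthetic linked EHR + claims dataset
#'
#' Reproducible for a fixed seed.  Each documented patient's notes embed at
#' least one clean phrase per planted domain; decoy sentences are inserted at
#' the configured confounder rates for documented and undocumented patients
#' alike; every patient satisfies or violates the cohort criteria according
#' to explicit per-patient eligibility draws recorded in the gold labels; and
#' claims counts are drawn from the group-specific negative binomial laws
#' (variance `mu + mu^2/size`) over the 12 months after the index date.
#'
#' @param cfg a `cog_config` (see [calibrated_config()]).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param include_notes generate clinical note text?  Disable for analyses
#'   that only need the structured tables (much faster at large n).
#' @return A `cog_dataset`: list of data frames `patients`, `diagnoses`,
#'   `notes`, `coverage`, `claims`, `measurements`, `gold`, `gold_mentions`,
#'   plus the `config` and `seed` used.
#' @export
generate_dataset <- function(cfg, seed = 1L, include_notes = TRUE) {
  cfg <- as_generator_config(cfg)
  with_local_seed(seed, generate_dataset_impl(cfg, seed, include_notes))
}

generate_dataset_impl <- function(cfg, seed, include_notes) {
  n <- cfg$n_patients
  ids <- if (n > 0) sprintf("P%06d", seq_len(n)) else character(0)
  ws <- cfg$date_window$start; we <- cfg$date_window$end
  lex <- default_lexicon()

  # ---- index dates, demographics, notes-per-patient ----------------------
  index_date <- ws + if (n > 0) sample.int(as.integer(we - ws) + 1L, n,
                                           replace = TRUE) - 1L else integer(0)
  dgr <- cfg$demographics
  draw_cat <- function(spec) {
    if (n == 0) return(character(0))
    sample(names(spec), n, replace = TRUE, prob = as.numeric(unlist(spec)))
  }
  gender <- draw_cat(dgr$gender); race <- draw_cat(dgr$race)
  ethnicity <- draw_cat(dgr$ethnicity); region <- draw_cat(dgr$region)
  payer <- draw_cat(dgr$payer)
  under18 <- stats::runif(n) < dgr$under_18_rate
  age <- pmin(pmax(stats::rnorm(n, dgr$age$mean, dgr$age$sd),
                   dgr$age$min), dgr$age$max)
  age[under18] <- stats::runif(sum(under18), 12, 17.5)
  birth_year <- as.integer(format(index_date, "%Y")) - floor(age)

  npp <- cfg$notes_per_patient
  n_notes <- pmax(npp$min %||% 1L,
                  stats::rnbinom(n, mu = npp$mu, size = npp$size))

  # ---- documented impairment and domain planting -------------------------
  doms <- cog_domains()
  targets <- vapply(doms, function(d) cfg$domain_marginals[[d]], 0)
  cal <- calibrate_embedding(targets)
  doc <- cfg$documentation
  dmat <- matrix(FALSE, n, 5, dimnames = list(NULL, doms))
  if (identical(doc$mode, "fixed") && isTRUE(doc$exact_counts)) {
    k_doc <- round(n * doc$prevalence)
    documented <- rep(FALSE, n)
    documented[sample.int(n, k_doc)] <- TRUE
    latent <- documented
    # domain sets conditional on being non-empty: same conditional marginals
    todo <- which(documented)
    while (length(todo)) {
      draw <- matrix(stats::runif(length(todo) * 5), ncol = 5) <
        matrix(cal$raw, length(todo), 5, byrow = TRUE)
      dmat[todo, ] <- draw
      todo <- todo[rowSums(draw) == 0]
    }
  } else {
    p_doc <- if (identical(doc$mode, "note_coupled")) {
      cc <- coupling_coefficients(doc$coupling)
      stats::plogis(cc["intercept"] + cc["slope"] * log(pmax(1, n_notes)))
    } else rep(doc$prevalence, n)
    latent <- stats::runif(n) < pmin(1, p_doc / cal$detect_fraction)
    il <- which(latent)
    if (length(il))
      dmat[il, ] <- matrix(stats::runif(length(il) * 5), ncol = 5) <
        matrix(cal$raw, length(il), 5, byrow = TRUE)
    documented <- rowSums(dmat) > 0
  }
  group <- ifelse(documented, "impaired", "unimpaired")

  # ---- clinical and demographic covariates -------------------------------
  by_group <- function(spec, field) {
    vapply(group, function(g) as.numeric(spec[[g]][[field]]), 0, USE.NAMES = FALSE)
  }
  nb_size_from_sd <- function(mu, sd) {
    v <- sd^2
    ifelse(v > mu, mu^2 / (v - mu), 1e6)  # ~Poisson when variance <= mean
  }
  cci <- as.integer(
    stats::rnbinom(n, mu = by_group(cfg$cci, "mean"),
                   size = nb_size_from_sd(by_group(cfg$cci, "mean"),
                                          by_group(cfg$cci, "sd"))))
  com_flags <- lapply(cfg$comorbidity_prevalences, function(spec) {
    p <- ifelse(documented, spec$impaired, spec$unimpaired)
    stats::runif(n) < p
  })

  # ---- eligibility draws --------------------------------------------------
  el <- cfg$eligibility
  enc_ok <- stats::runif(n) < el$encounters_rate
  act_ok <- stats::runif(n) < el$activity_rate
  excl_dx <- stats::runif(n) < el$exclusion_dx_rate
  benign_dx <- !excl_dx & stats::runif(n) < el$benign_exclusion_code_rate
  enr_ok <- stats::runif(n) < el$enrollment_rate
  eligible_ehr <- !under18 & enc_ok & act_ok & !excl_dx
  eligible_linked <- eligible_ehr & enr_ok

  patients <- data.frame(
    patient_id = ids, birth_year = birth_year, gender = gender, race = race,
    ethnicity = ethnicity, region = region, payer = payer, cci = cci,
    stringsAsFactors = FALSE)

  # ---- diagnosis records --------------------------------------------------
  codes <- cfg$dx_codes
  dx <- list()
  add_dx <- function(pid, date, code, setting, primary) {
    data.frame(patient_id = pid, service_date = date, code = code,
               code_system = ifelse(grepl("^[0-9]", code), "icd9", "icd10cm"),
               setting = rep_len(setting, length(pid)),
               primary = rep_len(primary, length(pid)),
               stringsAsFactors = FALSE)
  }
  # schizophrenia encounters: >= 2 outpatient when enc_ok, else exactly 1;
  # the first is the index date
  n_sz <- ifelse(enc_ok, 2L + stats::rpois(n, 1), 1L)
  sz_pid <- rep(ids, n_sz)
  sz_first <- sequence(n_sz) == 1L
  sz_date <- rep(index_date, n_sz) +
    ifelse(sz_first, 0L, sample.int(300L, sum(n_sz), replace = TRUE))
  dx$sz <- add_dx(sz_pid, sz_date,
                  sample(unlist(codes$schizophrenia), sum(n_sz), replace = TRUE),
                  "outpatient", TRUE)
  # activity anchor: a general outpatient encounter; >= 12 months pre-index
  # when act_ok, inside the 12-month pre-index window otherwise
  anchor_off <- ifelse(act_ok, 366L + sample.int(365L, n, replace = TRUE),
                       30L + sample.int(270L, n, replace = TRUE))
  dx$anchor <- add_dx(ids, index_date - anchor_off,
                      rep("Z00.00", n), "outpatient", FALSE)
  # comorbidity codes in the 12-month pre-index window
  for (cond in names(com_flags)) {
    idx <- which(com_flags[[cond]])
    if (!length(idx)) next
    pool <- unlist(codes$comorbidity[[cond]])
    dx[[cond]] <- add_dx(ids[idx],
                         index_date[idx] - sample.int(360L, length(idx), replace = TRUE),
                         sample(pool, length(idx), replace = TRUE),
                         "outpatient", FALSE)
  }
  # exclusionary diagnoses, timed so the patient is genuinely excluded
  prior_conditions <- c("dementia", "frontotemporal_disease", "prion_disease",
                        "multiple_sclerosis", "parkinsons_disease", "stroke",
                        "traumatic_brain_injury")
  anytime_conditions <- c("autism_spectrum_disorder", "epilepsy",
                          "intellectual_disability")
  idx <- which(excl_dx)
  if (length(idx)) {
    cond <- sample(names(codes$exclusion), length(idx), replace = TRUE)
    off <- ifelse(cond %in% prior_conditions,
                  -sample.int(350L, length(idx), replace = TRUE),
                  sample(-350L:350L, length(idx), replace = TRUE))
    code <- vapply(cond, function(cn)
      sample(unlist(codes$exclusion[[cn]]), 1L), "")
    dx$excl <- add_dx(ids[idx], index_date[idx] + off, code,
                      "outpatient", FALSE)
  }
  # benign codes: prior-to-index-type condition coded after index (does not
  # exclude under the timing rule)
  idx <- which(benign_dx)
  if (length(idx)) {
    cond <- sample(intersect(prior_conditions, names(codes$exclusion)),
                   length(idx), replace = TRUE)
    code <- vapply(cond, function(cn)
      sample(unlist(codes$exclusion[[cn]]), 1L), "")
    dx$benign <- add_dx(ids[idx],
                        index_date[idx] + 10L + sample.int(290L, length(idx), replace = TRUE),
                        code, "outpatient", FALSE)
  }
  diagnoses <- do.call(rbind, dx)
  rownames(diagnoses) <- NULL

  # ---- coverage intervals -------------------------------------------------
  cov_end_full <- add_months(index_date, 12L) + 30L
  cov_start <- index_date - 30L
  coverage <- rbind(
    data.frame(patient_id = ids, start = cov_start,
               end = cov_end_full, benefit = rep_len("medical", n),
               stringsAsFactors = FALSE),
    data.frame(patient_id = ids, start = cov_start,
               end = as.Date(ifelse(enr_ok, cov_end_full,
                                    add_months(index_date, 11L)),
                             origin = "1970-01-01"),
               benefit = rep_len("pharmacy", n), stringsAsFactors = FALSE))
  rownames(coverage) <- NULL

  # ---- claims -------------------------------------------------------------
  claims <- generate_claims(cfg, ids, index_date, documented)

  # ---- BMI measurements ---------------------------------------------------
  n_meas <- if (n > 0) sample(1:3, n, replace = TRUE) else integer(0)
  m_pid <- rep(seq_len(n), n_meas)
  measurements <- data.frame(
    patient_id = ids[m_pid],
    obs_date = index_date[m_pid] + sample(-360L:360L, length(m_pid), replace = TRUE),
    bmi = round(stats::rnorm(length(m_pid),
                             by_group(cfg$bmi, "mean")[m_pid],
                             by_group(cfg$bmi, "sd")[m_pid]), 1),
    stringsAsFactors = FALSE)

  # ---- notes --------------------------------------------------------------
  if (include_notes && n > 0) {
    nt <- generate_notes(cfg, ids, index_date, act_ok, n_notes, dmat, lex)
    notes <- nt$notes; gold_mentions <- nt$gold_mentions
  } else {
    notes <- data.frame(note_id = character(0), patient_id = character(0),
                        note_date = as.Date(character(0)), text = character(0),
                        stringsAsFactors = FALSE)
    gold_mentions <- data.frame(patient_id = character(0), note_id = character(0),
                                entry_id = character(0), domain = character(0),
                                type = character(0), stringsAsFactors = FALSE)
  }

  domains_str <- if (n > 0)
    apply(dmat, 1, function(r) paste(doms[r], collapse = ";"))
  else character(0)
  gold <- data.frame(
    patient_id = ids, latent_impaired = latent, impaired = documented,
    domains = domains_str,
    n_notes = as.integer(n_notes), index_date = index_date,
    eligible_age = !under18, eligible_encounters = enc_ok,
    eligible_activity = act_ok, no_exclusion_dx = !excl_dx,
    eligible_enrollment = enr_ok,
    eligible_ehr = eligible_ehr, eligible_linked = eligible_linked,
    stringsAsFactors = FALSE)

  structure(list(patients = patients, diagnoses = diagnoses, notes = notes,
                 coverage = coverage, claims = claims,
                 measurements = measurements, gold = gold,
                 gold_mentions = gold_mentions,
                 config = unclass(cfg), seed = as.integer(seed)),
            class = "cog_dataset")
}

# Negative binomial utilization streams and treatment-pattern indicators,
# realized as dated claim records over [index, index + 12 months).
generate_claims <- function(cfg, ids, index_date, documented) {
  n <- length(ids)
  if (n == 0)
    return(data.frame(claim_id = character(0), patient_id = character(0),
                      service_date = as.Date(character(0)),
                      claim_type = character(0), dx_primary = character(0),
                      dx_other = character(0),
                      length_of_stay_days = integer(0),
                      service_class = character(0), stringsAsFactors = FALSE))
  ut <- cfg$utilization
  grp <- function(spec, field) ifelse(documented, spec$impaired[[field]],
                                      spec$unimpaired[[field]])
  draw_counts <- function(metric)
    if (n == 0) integer(0) else
    stats::rnbinom(n, mu = grp(ut[[metric]], "mu"),
                   size = grp(ut[[metric]], "size"))
  n_op <- draw_counts("outpatient"); n_ph <- draw_counts("pharmacy")
  n_er <- draw_counts("er"); n_ip <- draw_counts("inpatient")

  tr <- cfg$treatment_rates
  flag <- function(nm) stats::runif(n) < ifelse(documented, tr[[nm]]$impaired,
                                                tr[[nm]]$unimpaired)
  psycho_classes <- c("psychotherapy", "cbt", "family_therapy",
                      "psychosocial_rehab", "group_therapy")
  pharm_classes <- c("fga", "sga", "mood_stabilizer", "antidepressant")
  psycho <- vapply(psycho_classes, function(nm) flag(nm), logical(n))
  pharm <- vapply(pharm_classes, function(nm) flag(nm), logical(n))
  if (n == 1) { psycho <- matrix(psycho, 1); pharm <- matrix(pharm, 1)
                colnames(psycho) <- psycho_classes; colnames(pharm) <- pharm_classes }

  # therapy session days among patients receiving any psychosocial service
  any_psycho <- rowSums(psycho) > 0
  t_days <- integer(n)
  idx <- which(any_psycho)
  if (length(idx))
    t_days[idx] <- 1L + stats::rnbinom(length(idx),
                                       mu = pmax(0.1, grp(ut$therapy_days, "mu")[idx] - 1),
                                       size = ut$therapy_days$impaired$size)
  t_days <- pmin(t_days, n_op)  # therapy sessions are outpatient visits

  mk_dates <- function(cnt) {
    pid <- rep(seq_len(n), cnt)
    list(pid = pid,
         date = index_date[pid] + floor(stats::runif(length(pid), 0, 365)))
  }

  # outpatient: first t_days claims per patient carry a psychosocial class
  op <- mk_dates(n_op)
  op_class <- rep(NA_character_, length(op$pid))
  seq_in <- sequence(n_op)
  mark <- seq_in <= t_days[op$pid]
  if (any(mark)) {
    op_class[mark] <- vapply(op$pid[mark], function(i)
      sample(psycho_classes[psycho[i, ]], 1L), "")
  }
  somatic <- unlist(cfg$dx_codes$somatic)
  psych_pool <- unlist(cfg$dx_codes$psychiatric)
  sz_pool <- unlist(cfg$dx_codes$schizophrenia)
  claims_op <- data.frame(
    patient_id = ids[op$pid], service_date = op$date, claim_type = rep_len("outpatient", length(op$pid)),
    dx_primary = sample(c(somatic, psych_pool), length(op$pid), replace = TRUE),
    dx_other = NA_character_, length_of_stay_days = NA_integer_,
    service_class = op_class, stringsAsFactors = FALSE)

  # pharmacy: guarantee one claim per flagged drug class, rest sampled
  ph <- mk_dates(n_ph)
  ph_class <- rep("other", length(ph$pid))
  seq_ph <- sequence(n_ph)
  for (j in seq_along(pharm_classes)) {
    nth <- apply(pharm[, seq_len(j), drop = FALSE], 1, sum)  # position of class j
    sel <- pharm[ph$pid, j] & seq_ph == nth[ph$pid]
    ph_class[sel] <- pharm_classes[j]
  }
  rest <- seq_ph > rowSums(pharm)[ph$pid]
  if (any(rest)) {
    has_any <- rowSums(pharm) > 0
    pick <- stats::runif(sum(rest)) < 0.8
    ph_class[rest] <- ifelse(pick & has_any[ph$pid[rest]],
                             vapply(ph$pid[rest], function(i)
                               if (any(pharm[i, ])) sample(pharm_classes[pharm[i, ]], 1L)
                               else "other", ""),
                             "other")
  }
  claims_ph <- data.frame(
    patient_id = ids[ph$pid], service_date = ph$date, claim_type = rep_len("pharmacy", length(ph$pid)),
    dx_primary = NA_character_, dx_other = NA_character_,
    length_of_stay_days = NA_integer_, service_class = ph_class,
    stringsAsFactors = FALSE)

  # emergency department: psychiatric primary dx at the configured fraction
  er <- mk_dates(n_er)
  er_psych <- stats::runif(length(er$pid)) <
    ifelse(documented[er$pid], ut$er_psychiatric_fraction$impaired,
           ut$er_psychiatric_fraction$unimpaired)
  claims_er <- data.frame(
    patient_id = ids[er$pid], service_date = er$date, claim_type = rep_len("er", length(er$pid)),
    dx_primary = ifelse(er_psych,
                        sample(psych_pool, length(er$pid), replace = TRUE),
                        sample(somatic, length(er$pid), replace = TRUE)),
    dx_other = NA_character_, length_of_stay_days = NA_integer_,
    service_class = NA_character_, stringsAsFactors = FALSE)

  # inpatient: schizophrenia/schizoaffective primary dx at the configured
  # fraction; length of stay >= 1 day
  ip <- mk_dates(n_ip)
  ip_sz <- stats::runif(length(ip$pid)) <
    ifelse(documented[ip$pid], ut$inpatient_primary_sz_fraction$impaired,
           ut$inpatient_primary_sz_fraction$unimpaired)
  los_mu <- ifelse(documented[ip$pid], ut$los_per_admission$impaired$mean,
                   ut$los_per_admission$unimpaired$mean)
  los <- as.integer(1L + stats::rnbinom(length(ip$pid),
                                        mu = pmax(0.1, los_mu - 1),
                                        size = ut$los_per_admission$size))
  claims_ip <- data.frame(
    patient_id = ids[ip$pid], service_date = ip$date, claim_type = rep_len("inpatient", length(ip$pid)),
    dx_primary = ifelse(ip_sz, sample(c(sz_pool, "F25.0"), length(ip$pid), replace = TRUE),
                        sample(somatic, length(ip$pid), replace = TRUE)),
    dx_other = sample(psych_pool, length(ip$pid), replace = TRUE),
    length_of_stay_days = los, service_class = NA_character_,
    stringsAsFactors = FALSE)

  claims <- rbind(claims_op, claims_ph, claims_er, claims_ip)
  if (nrow(claims)) {
    claims <- claims[order(claims$patient_id, claims$service_date,
                           claims$claim_type), , drop = FALSE]
    claims$claim_id <- sprintf("C%08d", seq_len(nrow(claims)))
  } else claims$claim_id <- character(0)
  rownames(claims) <- NULL
  claims[, c("claim_id", "patient_id", "service_date", "claim_type",
             "dx_primary", "dx_other", "length_of_stay_days", "service_class")]
}

# Assemble note text: planted clean phrases, decoys at the confounder rates,
# neutral fillers, optional HTML wrapping.  Returns the notes table and the
# gold mention inventory.
generate_notes <- function(cfg, ids, index_date, act_ok, n_notes, dmat, lex) {
  n <- length(ids)
  doms <- cog_domains()
  entries <- compile_lexicon(lex)     # entry table incl. examples
  weights <- cfg$category_weights %||% list()

  N <- sum(n_notes)
  note_pid <- rep(seq_len(n), n_notes)
  first_note <- c(0L, cumsum(n_notes))[seq_len(n)]   # 0-based offset
  low <- ifelse(act_ok, -540L, -300L)
  note_date <- index_date[note_pid] +
    floor(stats::runif(N, low[note_pid], 366))
  note_id <- sprintf("N%07d", seq_len(N))

  ev <- list()
  # clean events: one per planted (patient, domain)
  for (d in doms) {
    pats <- which(dmat[, d])
    if (!length(pats)) next
    cand <- which(entries$domain == d)
    w <- vapply(entries$category[cand], function(cn)
      as.numeric(weights[[d]][[cn]] %||% 1), 0)
    pick <- cand[sample.int(length(cand), length(pats), replace = TRUE,
                            prob = w)]
    note_row <- first_note[pats] +
      floor(stats::runif(length(pats)) * n_notes[pats]) + 1L
    ev[[d]] <- data.frame(note_row = note_row, entry = pick, type = "clean",
                          stringsAsFactors = FALSE)
  }
  # decoys: per note, per rule class, at the configured rates
  for (tp in c("negation", "question", "goal", "family_history")) {
    rate <- cfg$confounder_rates[[tp]] %||% 0
    if (rate <= 0) next
    rows <- which(stats::runif(N) < rate)
    if (!length(rows)) next
    ev[[tp]] <- data.frame(note_row = rows,
                           entry = sample.int(nrow(entries), length(rows),
                                              replace = TRUE),
                           type = tp, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(note_row = integer(0), entry = integer(0),
                            type = character(0), stringsAsFactors = FALSE)

  ev_text <- if (nrow(events))
    event_sentences(events$type, entries$example[events$entry],
                    entries$requires_qualifier[events$entry])
  else character(0)

  n_fill <- sample(2:5, N, replace = TRUE)
  fill_text <- sample(.filler_sentences, sum(n_fill), replace = TRUE)
  sent <- data.frame(
    note_row = c(events$note_row, rep(seq_len(N), n_fill)),
    text = c(ev_text, fill_text), stringsAsFactors = FALSE)
  sent <- sent[order(sent$note_row, stats::runif(nrow(sent))), , drop = FALSE]
  sent_by_note <- split(sent$text, factor(sent$note_row, levels = seq_len(N)))

  markup <- stats::runif(N) < cfg$markup_probability
  text <- vapply(seq_len(N), function(k) {
    s <- sent_by_note[[k]]
    if (markup[k])
      paste0("<html><body><p>", paste(s, collapse = "</p>\n<p>"),
             "</p></body></html>")
    else paste(s, collapse = " ")
  }, "")

  notes <- data.frame(note_id = note_id, patient_id = ids[note_pid],
                      note_date = note_date, text = text,
                      stringsAsFactors = FALSE)
  gold_mentions <- data.frame(
    patient_id = ids[note_pid[events$note_row]],
    note_id = note_id[events$note_row],
    entry_id = entries$entry_id[events$entry],
    domain = entries$domain[events$entry],
    type = events$type, stringsAsFactors = FALSE)
  list(notes = notes, gold_mentions = gold_mentions)
}

#' @export
print.cog_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cog_dataset> %d patients, %d notes, %d dx records, ",
                     "%d claims (seed %d)\n"),
              nrow(x$patients), nrow(x$notes), nrow(x$diagnoses),
              nrow(x$claims), x$seed))
  invisible(x)
}
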