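# Healthcare resource utilization: per-patient-per-year metrics over the
# 12-month post-index window, stratified summaries with simple statistical
# comparisons, and negative binomial regression with marginally standardized
# adjusted rates.

.psycho_classes <- c("psychotherapy", "cbt", "family_therapy",
                     "psychosocial_rehab", "group_therapy")
.pharm_classes <- c("fga", "sga", "mood_stabilizer", "antidepressant")

#' Count relapse episodes for one patient
#'
#' A relapse episode is either an emergency-room claim with any psychiatric
#' diagnosis, or an inpatient claim with a primary schizophrenia or
#' schizoaffective diagnosis.  Each qualifying claim counts as one episode
#' (no same-stay merging).
#'
#' @param claims one patient's claim records (`claim_type`, `dx_primary`,
#'   `dx_other`, `service_date`).
#' @param window `Date` vector of length 2: half-open window
#'   `[window[1], window[2])`; `NULL` counts all claims.
#' @param psych_prefixes code prefixes defining a psychiatric diagnosis
#'   (default: the ICD-10 mental-disorders chapter plus ICD-9 290-319).
#' @param sz_primary_prefixes primary-diagnosis prefixes for
#'   schizophrenia/schizoaffective disorder.
#' @return Integer count of relapse episodes.
#' @export
detect_relapse_episodes <- function(claims, window = NULL,
                                    psych_prefixes = c("F", "29", "30", "31"),
                                    sz_primary_prefixes = c("F20", "F25", "295")) {
  if (!nrow(claims)) return(0L)
  if (!is.null(window)) {
    d <- as.Date(claims$service_date)
    claims <- claims[d >= window[1] & d < window[2], , drop = FALSE]
    if (!nrow(claims)) return(0L)
  }
  any_psych <- icd_prefix_match(claims$dx_primary, psych_prefixes) |
    (!is.na(claims$dx_other) & icd_prefix_match(claims$dx_other, psych_prefixes))
  er_relapse <- claims$claim_type == "er" & any_psych
  ip_relapse <- claims$claim_type == "inpatient" &
    icd_prefix_match(claims$dx_primary, sz_primary_prefixes)
  sum(er_relapse | ip_relapse, na.rm = TRUE)
}

#' Per-patient-per-year utilization metrics
#'
#' Counts claims restricted to the half-open window `[index, index + 12mo)`
#' for every patient; with the fixed 12-month window the PPPY rate equals
#' the raw count.  Length of stay per admission is defined only for patients
#' with at least one admission (`NA` otherwise, excluded from that metric's
#' mean).  Claims outside the window are ignored; their number is recorded
#' in the `"n_outside_window"` attribute for audit.
#'
#' @param claims claims table for the cohort.
#' @param index_dates data frame with `patient_id`, `index_date`.
#' @param months follow-up window length in months.
#' @return Data frame with one row per patient: count metrics
#'   (`claims_total`, `outpatient`, `inpatient_admissions`, `er`,
#'   `pharmacy`, `hospitalized_days`, `los_per_admission`,
#'   `relapse_episodes`, `therapy_days`) and logical treatment indicators
#'   (`any_psychosocial`, the psychosocial classes, `any_psych_pharmacy`,
#'   the pharmacy classes).
#' @export
pppy_metrics <- function(claims, index_dates, months = 12L) {
  ids <- as.character(index_dates$patient_id)
  idx <- as.Date(index_dates$index_date)
  w_end <- add_months(idx, months)
  cl <- claims
  cl$service_date <- as.Date(cl$service_date)
  pid_i <- match(as.character(cl$patient_id), ids)
  inwin <- !is.na(pid_i) & cl$service_date >= idx[pid_i] &
    cl$service_date < w_end[pid_i]
  n_outside <- sum(!inwin & !is.na(pid_i))
  cl <- cl[inwin, , drop = FALSE]
  pid_i <- pid_i[inwin]
  fpid <- factor(pid_i, levels = seq_along(ids))

  cnt <- function(mask) as.integer(table(fpid[mask]))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  out$claims_total <- as.integer(table(fpid))
  out$outpatient <- cnt(cl$claim_type == "outpatient")
  out$inpatient_admissions <- cnt(cl$claim_type == "inpatient")
  out$er <- cnt(cl$claim_type == "er")
  out$pharmacy <- cnt(cl$claim_type == "pharmacy")
  hd <- tapply(ifelse(cl$claim_type == "inpatient",
                      cl$length_of_stay_days, 0L), fpid, sum)
  out$hospitalized_days <- as.integer(ifelse(is.na(hd), 0L, hd))
  out$los_per_admission <- ifelse(out$inpatient_admissions > 0,
                                  out$hospitalized_days / out$inpatient_admissions,
                                  NA_real_)
  out$relapse_episodes <- vapply(split(cl, fpid), detect_relapse_episodes,
                                 integer(1))
  # therapy_days = distinct service dates with a psychosocial-class claim
  is_therapy <- !is.na(cl$service_class) & cl$service_class %in% .psycho_classes
  td <- tapply(seq_len(nrow(cl)), fpid, function(ii)
    length(unique(cl$service_date[ii][is_therapy[ii]])))
  out$therapy_days <- as.integer(ifelse(is.na(td), 0L, td))
  for (sc in .psycho_classes)
    out[[sc]] <- as.integer(table(fpid[!is.na(cl$service_class) &
                                         cl$service_class == sc])) > 0
  out$any_psychosocial <- Reduce(`|`, out[.psycho_classes])
  for (sc in .pharm_classes)
    out[[sc]] <- as.integer(table(fpid[!is.na(cl$service_class) &
                                         cl$service_class == sc])) > 0
  out$any_psych_pharmacy <- Reduce(`|`, out[.pharm_classes])
  attr(out, "n_outside_window") <- n_outside
  out
}

#' Stratified utilization summaries with simple comparisons
#'
#' Means/SDs per stratum with Welch two-sided t-tests for count metrics, and
#' proportions with Pearson chi-square tests (no continuity correction by
#' default) for treatment indicators.  No multiplicity adjustment is
#' applied.  An empty stratum yields summaries with comparison p-values
#' flagged `NA`.
#'
#' @param metrics data frame from [pppy_metrics()] plus a logical `impaired`
#'   column.
#' @param correct continuity-correct the chi-square tests?
#' @return List with `means` (metric, stratum means/SDs/n, p_value) and
#'   `proportions` (indicator, stratum proportions/n, p_value).
#' @export
summarize_strata <- function(metrics, correct = FALSE) {
  stopifnot("impaired" %in% names(metrics))
  g1 <- metrics[metrics$impaired, , drop = FALSE]
  g0 <- metrics[!metrics$impaired, , drop = FALSE]
  num_metrics <- c("claims_total", "hospitalized_days", "los_per_admission",
                   "inpatient_admissions", "er", "outpatient", "pharmacy",
                   "relapse_episodes", "therapy_days")
  num_metrics <- intersect(num_metrics, names(metrics))
  means <- do.call(rbind, lapply(num_metrics, function(mname) {
    x1 <- g1[[mname]]; x0 <- g0[[mname]]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    p <- if (length(x1) > 1 && length(x0) > 1 &&
             (stats::var(x1) + stats::var(x0)) > 0)
      stats::t.test(x1, x0)$p.value else NA_real_
    data.frame(metric = mname,
               mean_impaired = mean(x1), sd_impaired = stats::sd(x1),
               n_impaired = length(x1),
               mean_unimpaired = mean(x0), sd_unimpaired = stats::sd(x0),
               n_unimpaired = length(x0), p_value = p,
               stringsAsFactors = FALSE)
  }))
  ind <- intersect(c("any_psychosocial", .psycho_classes,
                     "any_psych_pharmacy", .pharm_classes), names(metrics))
  proportions <- do.call(rbind, lapply(ind, function(iname) {
    x1 <- g1[[iname]]; x0 <- g0[[iname]]
    tab <- rbind(c(sum(x1), sum(!x1)), c(sum(x0), sum(!x0)))
    p <- if (nrow(g1) > 0 && nrow(g0) > 0 && all(colSums(tab) > 0))
      tryCatch(suppressWarnings(
        stats::chisq.test(tab, correct = correct)$p.value),
        error = function(e) NA_real_)
    else NA_real_
    data.frame(indicator = iname,
               prop_impaired = mean(x1), n_impaired = nrow(g1),
               prop_unimpaired = mean(x0), n_unimpaired = nrow(g0),
               p_value = p, stringsAsFactors = FALSE)
  }))
  list(means = means, proportions = proportions)
}

#' Fit a negative binomial regression for admission counts
#'
#' Maximum-likelihood negative binomial fit (log link, NB2) of a nonnegative
#' count outcome on an impairment indicator and covariates, via
#' [MASS::glm.nb()].  Character/factor covariates enter as indicator sets
#' with the largest category as reference.  The fit fails loudly on
#' non-convergence or degenerate outcomes (e.g. all zeros) rather than
#' returning silent estimates.
#'
#' @param outcome nonnegative integer vector of counts.
#' @param design data frame of covariates; must contain a logical or 0/1
#'   `impaired` column.
#' @return A `cog_nb_fit`: list with `model` (the `glm.nb` object),
#'   `coefficients` (term, estimate, se, z, p_value), `theta`, `theta_se`,
#'   `p_impaired` (Wald p-value of the impairment term) and `converged`.
#' @export
fit_nb_regression <- function(outcome, design) {
  outcome <- as.numeric(outcome)
  if (any(is.na(outcome)) || any(outcome < 0) ||
      any(outcome != round(outcome)))
    stop_cogehr("outcome must be nonnegative integer counts")
  if (all(outcome == 0))
    stop_cogehr("degenerate outcome: all counts are zero")
  if (!"impaired" %in% names(design))
    stop_cogehr("design must contain an 'impaired' column")
  df <- as.data.frame(design, stringsAsFactors = FALSE)
  df$impaired <- as.logical(df$impaired)
  for (cl in names(df)) {
    if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
    if (is.factor(df[[cl]])) {
      tab <- table(df[[cl]])
      if (length(tab) < 2)
        stop_cogehr("degenerate design: covariate '%s' has a single level", cl)
      df[[cl]] <- stats::relevel(df[[cl]], ref = names(which.max(tab)))
    }
  }
  df$.y <- outcome
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(.y ~ ., data = df, maxit = 100)),
    error = function(e)
      stop_cogehr("negative binomial fit failed: %s", conditionMessage(e)))
  if (!isTRUE(fit$converged))
    stop_cogehr("negative binomial fit did not converge")
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
    stop_cogehr(paste0("separation or degenerate design: coefficient(s) ",
                       "diverged (%s)"),
                paste(names(stats::coef(fit))[abs(stats::coef(fit)) > 15 |
                                                !is.finite(stats::coef(fit))],
                      collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 3], p_value = co[, 4],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  imp_row <- grep("^impaired", coefs$term)
  structure(list(model = fit, coefficients = coefs,
                 theta = fit$theta, theta_se = fit$SE.theta,
                 p_impaired = if (length(imp_row)) coefs$p_value[imp_row[1]]
                              else NA_real_,
                 converged = TRUE),
            class = "cog_nb_fit")
}

#' @export
print.cog_nb_fit <- function(x, ...) {
  cat(sprintf("<cog_nb_fit> theta = %.3f; impairment term p = %.3g\n",
              x$theta, x$p_impaired))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Marginally standardized adjusted rates
#'
#' G-computation over the fitted model: every patient's expected count is
#' predicted with the impairment indicator forced to `TRUE`, then to
#' `FALSE`, holding their own covariates; the two averages are the adjusted
#' rates and their ratio the adjusted rate ratio.
#'
#' @param fit a `cog_nb_fit` from [fit_nb_regression()].
#' @param design the cohort covariate data frame used in the fit (or any
#'   standardization population with the same columns).
#' @return Named list: `adjusted_rate_impaired`, `adjusted_rate_unimpaired`,
#'   `ratio`.
#' @export
adjusted_rates <- function(fit, design) {
  stopifnot(inherits(fit, "cog_nb_fit"))
  df <- as.data.frame(design, stringsAsFactors = FALSE)
  for (cl in names(df)) if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  d1 <- df; d1$impaired <- TRUE
  d0 <- df; d0$impaired <- FALSE
  r1 <- mean(stats::predict(fit$model, newdata = d1, type = "response"))
  r0 <- mean(stats::predict(fit$model, newdata = d0, type = "response"))
  list(adjusted_rate_impaired = r1, adjusted_rate_unimpaired = r0,
       ratio = r1 / r0)
}
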