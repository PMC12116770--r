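# Generator configuration: loading, validation, and the embedding-probability
# calibration that makes conditional domain marginals recoverable.

#' Load a generator configuration from YAML
#'
#' @param path path to a generator config YAML file.
#' @return A validated `cog_config` object (a named list).
#' @seealso [calibrated_config()], [smoke_config()], [generate_dataset()]
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop_cogehr("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  as_generator_config(cfg)
}

#' The bundled calibrated generator configuration
#'
#' Group-level parameters (documentation prevalence and its note-count
#' coupling, domain marginals conditional on documentation, comorbidity
#' rates, CCI/BMI moments, negative-binomial utilization laws) follow the
#' published study-population summaries; simulation-only choices (dispersion
#' sizes, confounder rates, code pools) are documented in the vignette.
#'
#' @param ... named overrides applied on top of the file values (nested lists
#'   are merged, e.g. `n_patients = 2000` or
#'   `documentation = list(mode = "fixed", prevalence = 1)`).
#' @return A `cog_config` object.
#' @export
calibrated_config <- function(...) {
  cfg <- read_generator_config(system.file("extdata", "config_calibrated.yaml",
                                           package = "cogehr", mustWork = TRUE))
  override_config(cfg, ...)
}

#' The bundled small smoke-test configuration
#'
#' @inheritParams calibrated_config
#' @return A `cog_config` object.
#' @export
smoke_config <- function(...) {
  cfg <- read_generator_config(system.file("extdata", "config_smoke.yaml",
                                           package = "cogehr", mustWork = TRUE))
  override_config(cfg, ...)
}

#' Apply named overrides to a generator configuration
#'
#' @param cfg a `cog_config`.
#' @param ... named overrides; nested lists are merged recursively.
#' @return The modified, re-validated `cog_config`.
#' @export
override_config <- function(cfg, ...) {
  dots <- list(...)
  if (length(dots))
    cfg <- utils::modifyList(unclass(cfg), dots)
  as_generator_config(cfg)
}

as_generator_config <- function(cfg) {
  cfg <- unclass(cfg)
  req <- c("n_patients", "date_window", "documentation", "domain_marginals",
           "confounder_rates", "notes_per_patient", "markup_probability",
           "demographics", "comorbidity_prevalences", "cci", "bmi",
           "utilization", "treatment_rates", "eligibility", "dx_codes")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop_cogehr("generator config missing field(s): %s",
                paste(miss, collapse = ", "))
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    stop_cogehr("n_patients must be a nonnegative integer")
  cfg$n_patients <- as.integer(cfg$n_patients)
  ws <- as.Date(cfg$date_window$start); we <- as.Date(cfg$date_window$end)
  if (is.na(ws) || is.na(we) || !(ws < we))
    stop_cogehr("date_window must satisfy start < end")
  cfg$date_window$start <- ws; cfg$date_window$end <- we

  chk_prob <- function(x, what) {
    x <- as.numeric(x)
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop_cogehr("%s must be probabilities in [0, 1]", what)
    x
  }
  dm <- cfg$domain_marginals
  miss <- setdiff(cog_domains(), names(dm))
  if (length(miss))
    stop_cogehr("domain_marginals missing domain(s): %s",
                paste(miss, collapse = ", "))
  for (d in cog_domains()) dm[[d]] <- chk_prob(dm[[d]], paste("domain_marginals", d))
  cfg$domain_marginals <- dm
  for (nm in names(cfg$confounder_rates))
    cfg$confounder_rates[[nm]] <- chk_prob(cfg$confounder_rates[[nm]],
                                           paste("confounder_rates", nm))
  cfg$documentation$prevalence <- chk_prob(cfg$documentation$prevalence %||% 0.25,
                                           "documentation prevalence")
  cfg$documentation$mode <- match.arg(cfg$documentation$mode %||% "fixed",
                                      c("fixed", "note_coupled"))
  cfg$markup_probability <- chk_prob(cfg$markup_probability, "markup_probability")
  for (nm in names(cfg$eligibility))
    cfg$eligibility[[nm]] <- chk_prob(cfg$eligibility[[nm]],
                                      paste("eligibility", nm))
  for (metric in c("outpatient", "pharmacy", "er", "inpatient", "therapy_days"))
    for (grp in c("impaired", "unimpaired")) {
      par <- cfg$utilization[[metric]][[grp]]
      if (is.null(par$mu) || is.null(par$size) || par$size <= 0 || par$mu < 0)
        stop_cogehr("utilization %s/%s needs mu >= 0 and size > 0", metric, grp)
    }
  if (cfg$notes_per_patient$size %||% 0 <= 0)
    stop_cogehr("notes_per_patient size must be > 0")
  structure(cfg, class = "cog_config")
}

# Solve for the detection fraction c such that raw per-domain embedding
# probabilities p_d = t_d * c yield P(any domain) = c; then
# P(domain d | any) = t_d exactly.  Requires sum(t) >= 1 (expected number of
# domains per documented patient must be at least one); otherwise the
# marginals are used raw and conditioning is approximate.
calibrate_embedding <- function(targets) {
  t <- as.numeric(targets)
  stopifnot(all(t >= 0), all(t <= 1))
  if (sum(t) <= 1 || all(t == 0))
    return(list(raw = t, detect_fraction = 1 - prod(1 - t), exact = FALSE))
  f <- function(cc) cc - (1 - prod(1 - t * cc))
  root <- stats::uniroot(f, lower = 1e-9, upper = 1, tol = 1e-12)$root
  list(raw = t * root, detect_fraction = root, exact = TRUE)
}

# Logistic coupling coefficients (on log note count) through two anchors.
coupling_coefficients <- function(coupling) {
  a <- coupling$anchors
  if (is.null(a) || length(a) != 2)
    stop_cogehr("documentation coupling needs exactly two anchors")
  x <- log(vapply(a, `[[`, 0, "notes"))
  p <- vapply(a, `[[`, 0, "prob")
  lg <- stats::qlogis(p)
  slope <- (lg[2] - lg[1]) / (x[2] - x[1])
  intercept <- lg[1] - slope * x[1]
  c(intercept = intercept, slope = slope)
}

#' @export
print.cog_config <- function(x, ...) {
  cat(sprintf(paste0("<cog_config> %d patients, window %s..%s, ",
                     "documentation mode '%s'\n"),
              x$n_patients, x$date_window$start, x$date_window$end,
              x$documentation$mode))
  invisible(x)
}
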