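# Plain-text serialization of synthetic datasets: CSV tables, JSONL notes,
# and a JSON manifest carrying the seed and config snapshot so a dataset can
# be regenerated byte-identically.

.ds_tables <- c("patients", "diagnoses", "coverage", "claims",
                "measurements", "gold", "gold_mentions")

#' Write a synthetic dataset to a directory
#'
#' Emits one CSV per structured table, the notes as JSONL (one note object
#' per line: `note_id`, `patient_id`, `note_date`, `text`), and
#' `manifest.json` recording the seed, the full config snapshot and the file
#' list.  [read_dataset()] on the output reproduces an equal dataset, and
#' [generate_dataset()] from the manifest's config and seed reproduces
#' byte-identical files.
#'
#' @param ds a `cog_dataset`.
#' @param dir output directory (created if missing).
#' @return The manifest (a list), invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cog_dataset"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop_cogehr("cannot create output directory: %s", dir)
  files <- character(0)
  for (tb in .ds_tables) {
    f <- file.path(dir, paste0(tb, ".csv"))
    df <- ds[[tb]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    tryCatch(utils::write.csv(df, f, row.names = FALSE, na = ""),
             error = function(e)
               stop_cogehr("failed writing %s: %s", f, conditionMessage(e)))
    files <- c(files, basename(f))
  }
  nf <- file.path(dir, "notes.jsonl")
  con <- file(nf, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con), add = TRUE)
  if (nrow(ds$notes)) {
    lines <- vapply(seq_len(nrow(ds$notes)), function(i)
      as.character(jsonlite::toJSON(list(
        note_id = ds$notes$note_id[i], patient_id = ds$notes$patient_id[i],
        note_date = format(ds$notes$note_date[i], "%Y-%m-%d"),
        text = ds$notes$text[i]), auto_unbox = TRUE)), "")
    writeLines(lines, con, sep = "\n")
  }
  files <- c(files, "notes.jsonl")
  manifest <- list(seed = ds$seed, files = files,
                   n_patients = nrow(ds$patients),
                   config = config_for_json(ds$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_for_json <- function(cfg) {
  cfg$date_window$start <- format(cfg$date_window$start, "%Y-%m-%d")
  cfg$date_window$end <- format(cfg$date_window$end, "%Y-%m-%d")
  cfg
}

#' Read a synthetic dataset back from a directory
#'
#' @param dir directory written by [write_dataset()].
#' @return A `cog_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_cogehr("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- list()
  date_cols <- c(service_date = NA, start = NA, end = NA, obs_date = NA,
                 index_date = NA, note_date = NA)
  for (tb in .ds_tables) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop_cogehr("missing table file: %s", f)
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = "character")
    df <- retype_table(tb, df)
    out[[tb]] <- df
  }
  nf <- file.path(dir, "notes.jsonl")
  lines <- if (file.exists(nf)) readLines(nf) else character(0)
  notes <- if (length(lines)) {
    recs <- lapply(lines, jsonlite::fromJSON)
    data.frame(note_id = vapply(recs, `[[`, "", "note_id"),
               patient_id = vapply(recs, `[[`, "", "patient_id"),
               note_date = as.Date(vapply(recs, `[[`, "", "note_date")),
               text = vapply(recs, `[[`, "", "text"),
               stringsAsFactors = FALSE)
  } else data.frame(note_id = character(0), patient_id = character(0),
                    note_date = as.Date(character(0)), text = character(0),
                    stringsAsFactors = FALSE)
  out$notes <- notes
  cfg <- manifest$config
  structure(c(out[c("patients", "diagnoses")], list(notes = notes),
              out[c("coverage", "claims", "measurements", "gold",
                    "gold_mentions")],
              list(config = cfg, seed = as.integer(manifest$seed))),
            class = "cog_dataset")
}

retype_table <- function(tb, df) {
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  lgl <- function(x) x == "TRUE"
  dt <- function(x) as.Date(x)
  conv <- list(
    patients = list(birth_year = int, cci = int),
    diagnoses = list(service_date = dt, primary = lgl),
    coverage = list(start = dt, end = dt),
    claims = list(service_date = dt, length_of_stay_days = int),
    measurements = list(obs_date = dt, bmi = num),
    gold = list(latent_impaired = lgl, impaired = lgl, n_notes = int,
                index_date = dt, eligible_age = lgl,
                eligible_encounters = lgl, eligible_activity = lgl,
                no_exclusion_dx = lgl, eligible_enrollment = lgl,
                eligible_ehr = lgl, eligible_linked = lgl),
    gold_mentions = list())
  for (cl in names(conv[[tb]])) if (cl %in% names(df))
    df[[cl]] <- conv[[tb]][[cl]](df[[cl]])
  # empty strings written for NA character fields
  for (cl in names(df)) if (is.character(df[[cl]]))
    df[[cl]][df[[cl]] == "" & cl %in% c("dx_primary", "dx_other",
                                        "service_class")] <- NA_character_
  df
}
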