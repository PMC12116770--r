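# Lexicon matching over segmented sentences and aggregation to patient-level
# documented-impairment profiles.

# Vectorized matcher: locate all entry matches across a character vector of
# sentence texts.  Returns a data frame (row, entry_id, domain, category,
# match_start, match_end) with 0-based half-open offsets within each
# sentence.  Within one entry matches are non-overlapping and left-to-right;
# overlapping matches from different entries are all reported.
locate_mentions <- function(texts, clex) {
  stopifnot(inherits(clex, "cog_compiled_lexicon"))
  n <- length(texts)
  opts <- stringi::stri_opts_regex(
    case_insensitive = isTRUE(attr(clex, "case_insensitive")))
  qual_rx <- attr(clex, "qualifier_regex")
  qual_ok <- NULL  # computed lazily, only if some entry needs it
  pieces <- vector("list", nrow(clex))
  for (j in seq_len(nrow(clex))) {
    hit <- stringi::stri_detect_regex(texts, clex$regex[j], opts_regex = opts)
    if (isTRUE(clex$requires_qualifier[j])) {
      if (is.null(qual_ok))
        qual_ok <- stringi::stri_detect_regex(texts, qual_rx, opts_regex = opts)
      hit <- hit & qual_ok
    }
    idx <- which(hit)
    if (!length(idx)) next
    loc <- stringi::stri_locate_all_regex(texts[idx], clex$regex[j],
                                          opts_regex = opts)
    cnt <- vapply(loc, nrow, integer(1))
    mat <- do.call(rbind, loc)
    pieces[[j]] <- data.frame(
      row = rep(idx, cnt),
      entry_id = clex$entry_id[j],
      domain = clex$domain[j],
      category = clex$category[j],
      match_start = mat[, 1] - 1L,
      match_end = mat[, 2],
      stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces))
    return(data.frame(row = integer(0), entry_id = character(0),
                      domain = character(0), category = character(0),
                      match_start = integer(0), match_end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  out <- out[order(out$row, out$match_start, out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match one or more sentences against a compiled lexicon
#'
#' Reports one mention per (entry, span).  Overlapping matches from different
#' entries are all kept; within a single entry spans are non-overlapping,
#' scanning left to right.  Exclusion status is not assigned here (see
#' [classify_exclusion()] and [extract_patient_profiles()]).
#'
#' @param sentences a data frame as returned by [segment_sentences()], or a
#'   character vector of sentence texts.
#' @param clex a `cog_compiled_lexicon` from [compile_lexicon()].
#' @return Data frame with columns `sentence_index`, `entry_id`, `domain`,
#'   `category`, `match_start`, `match_end` (0-based half-open offsets within
#'   the sentence).
#' @export
#' @examples
#' clex <- compile_lexicon(default_lexicon())
#' match_sentence("Patient shows poor concentration in session.", clex)
match_sentence <- function(sentences, clex) {
  if (is.character(sentences))
    sentences <- data.frame(sentence_index = seq_along(sentences) - 1L,
                            text = sentences, stringsAsFactors = FALSE)
  m <- locate_mentions(sentences$text, clex)
  m$sentence_index <- sentences$sentence_index[m$row]
  m[, c("sentence_index", "entry_id", "domain", "category",
        "match_start", "match_end")]
}

#' Extract patient-level documented-impairment profiles from clinical notes
#'
#' The full pipeline over a set of notes: strip markup, segment sentences,
#' match the compiled lexicon, classify sentence-level exclusions, and
#' aggregate retained (non-excluded) mentions into per-patient domain and
#' category flags.  Excluded mentions are kept in the mention log with their
#' status for audit; they contribute to no flag.
#'
#' @param notes data frame with columns `note_id`, `patient_id`, `note_date`,
#'   `text` (raw text, possibly containing HTML markup).
#' @param clex a `cog_compiled_lexicon`.
#' @param rules a `cog_rules` object, or `NULL` to disable context exclusion
#'   (all mentions retained; used to measure what the exclusion rules
#'   contribute).
#' @param patient_ids optional character vector of the full patient roster;
#'   patients without notes receive an all-false profile with
#'   `note_count = 0`.
#' @return An object of class `cog_profiles`: a list with
#'   \describe{
#'     \item{profiles}{one row per patient: `patient_id`, `note_count`,
#'       logical flag per domain, `any_impairment`,
#'       `retained_mention_count`.}
#'     \item{categories}{retained (patient, domain, category) combinations.}
#'     \item{mentions}{full mention log: `patient_id`, `note_id`,
#'       `sentence_index`, `entry_id`, `domain`, `category`, `match_start`,
#'       `match_end`, `exclusion`.}
#'   }
#' @export
extract_patient_profiles <- function(notes, clex,
                                     rules = default_exclusion_rules(),
                                     patient_ids = NULL) {
  stopifnot(all(c("note_id", "patient_id", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id))
    stop_cogehr("duplicate note_id values in notes")
  roster <- unique(c(as.character(patient_ids),
                     as.character(notes$patient_id)))

  # segment all notes into one sentence table
  plain <- strip_markup(notes$text)
  seg_list <- lapply(plain, segment_sentences)
  ns <- vapply(seg_list, nrow, integer(1))
  sent <- do.call(rbind, seg_list)
  if (is.null(sent) || nrow(sent) == 0) {
    sent <- data.frame(sentence_index = integer(0), text = character(0),
                       stringsAsFactors = FALSE)
    note_row <- integer(0)
  } else {
    note_row <- rep(seq_len(nrow(notes)), ns)
  }
  sent$note_id <- notes$note_id[note_row]
  sent$patient_id <- as.character(notes$patient_id[note_row])

  m <- locate_mentions(sent$text, clex)
  exclusion <- if (is.null(rules)) rep("none", nrow(sent))
               else classify_sentences(sent$text, rules)
  mentions <- data.frame(
    patient_id = sent$patient_id[m$row],
    note_id = sent$note_id[m$row],
    sentence_index = sent$sentence_index[m$row],
    entry_id = m$entry_id, domain = m$domain, category = m$category,
    match_start = m$match_start, match_end = m$match_end,
    exclusion = exclusion[m$row],
    stringsAsFactors = FALSE)

  kept <- mentions[mentions$exclusion == "none", , drop = FALSE]
  doms <- cog_domains()
  profiles <- data.frame(patient_id = roster, stringsAsFactors = FALSE)
  counts <- table(factor(as.character(notes$patient_id), levels = roster))
  profiles$note_count <- as.integer(counts[profiles$patient_id])
  for (d in doms)
    profiles[[d]] <- profiles$patient_id %in%
      kept$patient_id[kept$domain == d]
  profiles$any_impairment <- Reduce(`|`, profiles[doms])
  rk <- table(factor(kept$patient_id, levels = roster))
  profiles$retained_mention_count <- as.integer(rk[profiles$patient_id])

  categories <- unique(kept[, c("patient_id", "domain", "category")])
  rownames(profiles) <- rownames(categories) <- NULL
  structure(list(profiles = profiles, categories = categories,
                 mentions = mentions),
            class = "cog_profiles")
}

#' @export
print.cog_profiles <- function(x, ...) {
  p <- x$profiles
  cat(sprintf("<cog_profiles> %d patients, %d with documented impairment (%s%%); %d mentions (%d retained)\n",
              nrow(p), sum(p$any_impairment),
              format(prevalence_pct(sum(p$any_impairment), nrow(p))),
              nrow(x$mentions), sum(x$mentions$exclusion == "none")))
  invisible(x)
}

#' Corpus-level domain and category frequency report
#'
#' Counts and percentages per domain and per category among patients with any
#' documented impairment, plus the overall documented prevalence over all
#' patients.  Domain and category rows use the number of patients with
#' `any_impairment` as denominator; the overall row uses all patients.  A
#' zero denominator is flagged (`pct` is `NA`), never divided by.
#'
#' @param profiles a `cog_profiles` object from [extract_patient_profiles()].
#' @return Data frame with columns `level` (`"overall"`, `"domain"`,
#'   `"category"`), `domain`, `category`, `n`, `denominator`, `pct`.
#' @export
corpus_domain_report <- function(profiles) {
  stopifnot(inherits(profiles, "cog_profiles"))
  p <- profiles$profiles
  n_all <- nrow(p)
  n_imp <- sum(p$any_impairment)
  rows <- list(data.frame(level = "overall", domain = NA_character_,
                          category = NA_character_, n = n_imp,
                          denominator = n_all,
                          pct = prevalence_pct(n_imp, n_all),
                          stringsAsFactors = FALSE))
  for (d in cog_domains()) {
    nd <- sum(p[[d]])
    rows[[length(rows) + 1L]] <- data.frame(
      level = "domain", domain = d, category = NA_character_, n = nd,
      denominator = n_imp, pct = prevalence_pct(nd, n_imp),
      stringsAsFactors = FALSE)
    cats <- profiles$categories[profiles$categories$domain == d, , drop = FALSE]
    if (nrow(cats)) {
      tab <- table(cats$category)
      for (cn in names(sort(tab, decreasing = TRUE))) {
        rows[[length(rows) + 1L]] <- data.frame(
          level = "category", domain = d, category = cn,
          n = as.integer(tab[[cn]]), denominator = n_imp,
          pct = prevalence_pct(as.integer(tab[[cn]]), n_imp),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Documented-impairment prevalence by clinical-note count
#'
#' Buckets patients by how many notes they have and reports the documented
#' prevalence in each bucket, quantifying how documentation opportunity
#' scales with note volume.
#'
#' @param profiles a `cog_profiles` object, or its `profiles` data frame.
#' @param breaks upper bucket edges (default `c(5, 50)` giving buckets
#'   `<=5`, `6-50`, `>50`).
#' @return Data frame with `bucket`, `n`, `n_documented`, `prevalence_pct`
#'   (`NA` for empty buckets).
#' @export
bucket_by_note_count <- function(profiles, breaks = c(5, 50)) {
  p <- if (inherits(profiles, "cog_profiles")) profiles$profiles else profiles
  stopifnot(all(c("note_count", "any_impairment") %in% names(p)))
  breaks <- sort(unique(as.integer(breaks)))
  edges <- c(-Inf, breaks, Inf)
  labs <- character(length(edges) - 1L)
  labs[1] <- sprintf("<=%d", breaks[1])
  if (length(breaks) > 1)
    for (k in 2:length(breaks))
      labs[k] <- sprintf("%d-%d", breaks[k - 1L] + 1L, breaks[k])
  labs[length(labs)] <- sprintf(">%d", breaks[length(breaks)])
  bucket <- cut(p$note_count, edges, labels = labs)
  out <- data.frame(bucket = labs, stringsAsFactors = FALSE)
  out$n <- as.integer(table(bucket)[labs])
  agg <- tapply(p$any_impairment, bucket, sum)
  out$n_documented <- as.integer(ifelse(is.na(agg[labs]), 0L, agg[labs]))
  out$prevalence_pct <- prevalence_pct(out$n_documented, out$n)
  out
}
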