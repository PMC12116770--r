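test_that("strip_markup removes tags, keeps text, and never fuses blocks", {
  expect_equal(strip_markup("<p>poor memory</p>"), "poor memory")
  expect_equal(strip_markup("plain text, no tags"), "plain text, no tags")
  squish <- function(x) gsub("[[:space:]]+", " ", x)
  expect_equal(squish(strip_markup("<div>poor</div><div>memory</div>")),
               "poor memory")
  # entity references decode
  expect_equal(strip_markup("slow &amp; unfocused"), "slow & unfocused")
  # malformed markup handled leniently, text preserved
  out <- strip_markup("<p>poor <b>memory</p> noted")
  expect_match(squish(out), "poor memory noted")
})

test_that("strip_markup agrees with a DOM text-extraction oracle", {
  docs <- c(
    "<html><body><p>Patient alert.</p><p>Poor memory noted.</p></body></html>",
    "<div>Reduced attention</div><div>seen today.</div>",
    "<ul><li>thought blocking</li><li>hindered speech</li></ul>",
    "No markup at all. Two sentences here.")
  squish <- function(x) trimws(gsub("[[:space:]]+", " ", x))
  for (d in docs) {
    # oracle: walk text nodes of the parsed DOM, join with spaces
    oracle <- tryCatch({
      doc <- xml2::read_html(d)
      nodes <- xml2::xml_find_all(doc, "//text()")
      squish(paste(vapply(nodes, xml2::xml_text, ""), collapse = " "))
    }, error = function(e) squish(d))
    expect_equal(squish(strip_markup(d)), oracle, label = d)
  }
})

test_that("sentence segmentation handles punctuation, decimals, abbreviations, newlines", {
  s <- segment_sentences("He denies poor memory. She has poor concentration.")
  expect_equal(nrow(s), 2)
  expect_equal(nrow(segment_sentences("")), 0)
  s <- segment_sentences("BMI 30.1 noted. Insight and judgment impaired.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text[1], "BMI 30.1 noted.")
  s <- segment_sentences("Seen by Dr. Smith today. Reports poor memory.")
  expect_equal(nrow(s), 2)
  expect_match(s$text[1], "Dr. Smith today\\.$")
  # newline-delimited list items are boundaries even without punctuation
  s <- segment_sentences("poor memory\nreduced attention\nstable vitals")
  expect_equal(s$text, c("poor memory", "reduced attention", "stable vitals"))
  # question/exclamation terminals
  s <- segment_sentences("Any concerns? None reported!")
  expect_equal(nrow(s), 2)
})

test_that("segmentation offsets are 0-based half-open, ordered, and cover all non-whitespace", {
  texts <- c("One sentence only",
             "A b. C d! E f? G h.",
             "  padded   start. and end.  ",
             "List:\nitem one\nitem two.\nDone.")
  for (tx in texts) {
    s <- segment_sentences(tx)
    if (nrow(s) == 0) next
    expect_true(all(s$start >= 0 & s$end <= nchar(tx)))
    expect_true(all(s$start < s$end))
    expect_true(all(diff(s$start) > 0))
    # half-open offsets recover the sentence text
    for (k in seq_len(nrow(s)))
      expect_equal(substr(tx, s$start[k] + 1, s$end[k]), s$text[k])
    # spans are non-overlapping and jointly cover every non-whitespace char
    covered <- logical(nchar(tx))
    for (k in seq_len(nrow(s))) {
      idx <- (s$start[k] + 1):s$end[k]
      expect_false(any(covered[idx]))
      covered[idx] <- TRUE
    }
    chars <- strsplit(tx, "")[[1]]
    expect_true(all(covered[!grepl("[[:space:]]", chars)]))
  }
})

test_that("matcher agrees with the brute-force substring oracle on random corpora", {
  lit <- make_literal_lexicon()
  clex <- compile_lexicon(lit$lexicon)
  for (seed in c(101, 202)) {
    sentences <- make_oracle_corpus(100, lit$entries, seed)
    m <- match_sentence(sentences, clex)
    got <- table(factor(m$sentence_index, levels = seq_along(sentences) - 1),
                 factor(m$entry_id, levels = clex$entry_id))
    for (i in seq_along(sentences)) {
      want <- oracle_match_counts(sentences[i], lit$entries)
      expect_equal(as.integer(got[i, names(want)]), unname(want),
                   label = sprintf("seed %d sentence %d: %s", seed, i,
                                   sentences[i]))
    }
  }
})

test_that("exclusion classification fires the documented rules with fixed precedence", {
  expect_equal(classify_exclusion("Denies poor memory."), "negation")
  expect_equal(classify_exclusion("Does he have difficulty remembering things?"),
               "question")
  expect_equal(classify_exclusion("Goal: improve poor concentration."), "goal")
  expect_equal(classify_exclusion("Mother has poor memory."), "family_history")
  expect_equal(classify_exclusion("Has poor memory."), "none")
  # precedence: negation > question > goal > family_history
  expect_equal(classify_exclusion("Denies poor memory?"), "negation")
  expect_equal(classify_exclusion("Goal for mother: support memory."), "goal")
  expect_equal(classify_exclusion("Will work on memory with mother?"), "question")
  # multi-word triggers respect flexible whitespace
  expect_equal(classify_exclusion("Negative  for poor memory."), "negation")
})

test_that("exclusion classification agrees with a naive trigger oracle", {
  lit <- make_literal_lexicon()
  sentences <- make_oracle_corpus(80, lit$entries, 303)
  got <- classify_exclusion(sentences)
  want <- vapply(sentences, oracle_exclusion, "", USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("profiles aggregate retained mentions only, with full audit log", {
  clex <- compile_lexicon(default_lexicon())
  notes <- data.frame(
    note_id = c("n1", "n2", "n3"),
    patient_id = c("p1", "p2", "p2"),
    note_date = as.Date("2020-01-01") + 0:2,
    text = c("Poor memory and thought blocking.",
             "Denies poor memory. No reduced attention.",
             "Mother has poor concentration."),
    stringsAsFactors = FALSE)
  prof <- extract_patient_profiles(notes, clex, patient_ids = c("p1", "p2", "p3"))
  p <- prof$profiles
  expect_equal(nrow(p), 3)
  p1 <- p[p$patient_id == "p1", ]
  expect_true(p1$working_memory && p1$speed_of_processing && p1$any_impairment)
  expect_false(p1$attention_vigilance)
  # patient whose only matching sentences are excluded
  p2 <- p[p$patient_id == "p2", ]
  expect_false(p2$any_impairment)
  expect_equal(p2$retained_mention_count, 0L)
  expect_equal(p2$note_count, 2L)
  # excluded mentions retained in the log with their status
  logs <- prof$mentions[prof$mentions$patient_id == "p2", ]
  expect_setequal(logs$exclusion, c("negation", "family_history"))
  # patient with zero notes
  p3 <- p[p$patient_id == "p3", ]
  expect_equal(p3$note_count, 0L)
  expect_false(p3$any_impairment)
  # duplicate note ids rejected
  notes2 <- notes; notes2$note_id <- c("a", "a", "b")
  expect_error(extract_patient_profiles(notes2, clex), "duplicate note_id")
})

test_that("pipeline is deterministic and monotone in added notes, flags have witnesses", {
  clex <- compile_lexicon(default_lexicon())
  lit <- make_literal_lexicon()
  sentences <- make_oracle_corpus(60, lit$entries, 404)
  notes <- data.frame(
    note_id = sprintf("n%02d", seq_along(sentences)),
    patient_id = rep(sprintf("p%d", 1:12), length.out = length(sentences)),
    note_date = as.Date("2020-06-01"),
    text = sentences, stringsAsFactors = FALSE)
  a <- extract_patient_profiles(notes, clex)
  b <- extract_patient_profiles(notes, clex)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$mentions, b$mentions)
  # exclusion soundness: every true domain flag has a retained witness mention
  kept <- a$mentions[a$mentions$exclusion == "none", ]
  for (i in seq_len(nrow(a$profiles)))
    for (d in cog_domains())
      if (a$profiles[[d]][i])
        expect_true(any(kept$patient_id == a$profiles$patient_id[i] &
                          kept$domain == d))
  # monotonicity: an extra note never clears a flag
  extra <- rbind(notes, data.frame(
    note_id = "extra", patient_id = "p1", note_date = as.Date("2020-07-01"),
    text = "Stable visit today.", stringsAsFactors = FALSE))
  a2 <- extract_patient_profiles(extra, clex)
  for (d in cog_domains()) {
    was <- a$profiles[[d]][match("p1", a$profiles$patient_id)]
    now <- a2$profiles[[d]][match("p1", a2$profiles$patient_id)]
    expect_true(!was || now)
  }
})

test_that("retained mentions equal a naive reference pipeline on small corpora", {
  lit <- make_literal_lexicon()
  clex <- compile_lexicon(lit$lexicon)
  sentences <- make_oracle_corpus(90, lit$entries, 505)
  notes <- data.frame(
    note_id = sprintf("n%02d", seq_along(sentences)),
    patient_id = rep(sprintf("p%d", 1:15), length.out = length(sentences)),
    note_date = as.Date("2021-01-01"),
    text = sentences, stringsAsFactors = FALSE)
  prof <- extract_patient_profiles(notes, clex)
  want <- oracle_profiles(notes, lit$entries)
  for (i in seq_len(nrow(prof$profiles))) {
    pid <- prof$profiles$patient_id[i]
    got_doms <- cog_domains()[vapply(cog_domains(), function(d)
      prof$profiles[[d]][i], logical(1))]
    expect_setequal(got_doms, want[[pid]] %||% character(0))
  }
})

test_that("corpus report computes the documented denominators", {
  clex <- compile_lexicon(default_lexicon())
  notes <- data.frame(
    note_id = sprintf("n%d", 1:4),
    patient_id = sprintf("p%d", 1:4),
    note_date = as.Date("2020-01-01"),
    text = c("Poor memory noted.", "Poor memory and reduced attention.",
             "Thought blocking observed.", "Routine visit."),
    stringsAsFactors = FALSE)
  prof <- extract_patient_profiles(notes, clex)
  rep <- corpus_domain_report(prof)
  overall <- rep[rep$level == "overall", ]
  expect_equal(overall$n, 3); expect_equal(overall$denominator, 4)
  expect_equal(overall$pct, 75.0)
  wm <- rep[rep$level == "domain" & rep$domain == "working_memory", ]
  expect_equal(wm$n, 2); expect_equal(wm$denominator, 3)
  expect_equal(wm$pct, 66.7)
  # domain count >= max category count within it
  for (d in unique(rep$domain[rep$level == "domain"])) {
    dn <- rep$n[rep$level == "domain" & rep$domain == d]
    cats <- rep$n[rep$level == "category" & rep$domain == d]
    if (length(cats)) expect_gte(dn, max(cats))
  }
  # all-unimpaired corpus: zero denominators flagged, no division
  none <- extract_patient_profiles(notes[4, , drop = FALSE], clex)
  rep0 <- corpus_domain_report(none)
  expect_equal(rep0$pct[rep0$level == "overall"], 0)
  expect_true(all(is.na(rep0$pct[rep0$level == "domain"])))
})

test_that("note-count buckets report prevalence with empty buckets flagged", {
  p <- data.frame(note_count = c(1, 2, 3, 10, 60),
                  any_impairment = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  b <- bucket_by_note_count(p)
  expect_equal(b$bucket, c("<=5", "6-50", ">50"))
  expect_equal(b$n, c(3L, 1L, 1L))
  expect_equal(b$prevalence_pct, c(33.3, 100, 100))
  b2 <- bucket_by_note_count(p[p$note_count < 6, ])
  expect_true(is.na(b2$prevalence_pct[b2$bucket == ">50"]))
  expect_equal(b2$n[b2$bucket == ">50"], 0L)
})
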