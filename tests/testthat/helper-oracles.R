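`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent, deliberately naive oracles used to cross-check the pipeline.
# They share no code with the implementation: plain loops, fixed substring
# scans, no compiled patterns.

# Write a small lexicon YAML whose entries are literal phrase alternatives
# (no regex syntax), and return both the loaded lexicon and the alternative
# lists for the oracle.
make_literal_lexicon <- function() {
  entries <- list(
    list(domain = "working_memory", category = "poor memory",
         alts = c("poor memory", "bad memory")),
    list(domain = "working_memory", category = "difficulties remembering things",
         alts = c("difficulties remembering things")),
    list(domain = "attention_vigilance", category = "poor concentration",
         alts = c("poor concentration")),
    list(domain = "attention_vigilance", category = "reduced attention",
         alts = c("reduced attention", "decreased attention")),
    list(domain = "speed_of_processing", category = "thought blocking",
         alts = c("thought blocking")),
    list(domain = "reasoning_problem_solving", category = "difficulty learning",
         alts = c("difficulty learning")),
    list(domain = "verbal_learning_memory", category = "hindered speech",
         alts = c("hindered speech")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    version = "test", case_sensitive = FALSE,
    entries = lapply(entries, function(e)
      list(domain = e$domain, category = e$category,
           patterns = as.list(e$alts), example = e$alts[[1]]))), path)
  list(lexicon = load_lexicon(path), entries = entries)
}

is_word_char <- function(ch) grepl("^[a-z0-9_]$", ch)

# Count word-boundary substring occurrences of one phrase in one sentence,
# after lowercasing and collapsing whitespace.
oracle_count_phrase <- function(sentence, phrase) {
  s <- gsub("[[:space:]]+", " ", tolower(sentence))
  p <- gsub("[[:space:]]+", " ", tolower(phrase))
  cnt <- 0L
  start <- 1L
  repeat {
    hit <- regexpr(p, substr(s, start, nchar(s)), fixed = TRUE)
    if (hit == -1L) break
    a <- start + hit - 1L
    b <- a + nchar(p) - 1L
    before <- if (a > 1) substr(s, a - 1L, a - 1L) else ""
    after <- if (b < nchar(s)) substr(s, b + 1L, b + 1L) else ""
    if (!is_word_char(before) && !is_word_char(after)) cnt <- cnt + 1L
    start <- a + 1L
  }
  cnt
}

# Per-sentence (entry -> match count) via the naive oracle.
oracle_match_counts <- function(sentence, entries) {
  out <- integer(length(entries))
  for (j in seq_along(entries))
    out[j] <- sum(vapply(entries[[j]]$alts, oracle_count_phrase,
                         integer(1), sentence = sentence))
  names(out) <- vapply(entries, function(e)
    paste0(gsub("[^a-z0-9]+", "_", e$domain), "/",
           gsub("[^a-z0-9]+", "_", e$category)), "")
  out
}

# Naive sentence-level exclusion: any trigger word/phrase present with word
# boundaries, or terminal question mark.  Mirrors the documented precedence.
oracle_exclusion <- function(sentence,
                             negation = c("no", "not", "denies", "denied",
                                          "without", "negative for",
                                          "absence of", "intact"),
                             goal = c("goal", "goals", "plan to",
                                      "will work on", "objective:"),
                             family = c("mother", "father", "brother",
                                        "sister", "family history", "fh of",
                                        "parent", "parents")) {
  has <- function(words) any(vapply(words, function(w)
    oracle_count_phrase(sentence, w) > 0, logical(1)))
  if (has(negation)) return("negation")
  if (endsWith(trimws(sentence), "?")) return("question")
  if (has(goal)) return("goal")
  if (has(family)) return("family_history")
  "none"
}

# Naive end-to-end reference: markup-free notes in, per-patient retained
# (patient, domain) pairs out.  Sentence split is a simple scan on
# terminal punctuation + newlines (inputs avoid abbreviations/decimals).
oracle_profiles <- function(notes, entries) {
  flags <- list()
  for (i in seq_len(nrow(notes))) {
    sents <- unlist(strsplit(notes$text[i], "(?<=[.!?])\\s+|\\n+", perl = TRUE))
    sents <- sents[nzchar(trimws(sents))]
    for (s in sents) {
      if (oracle_exclusion(s) != "none") next
      cnts <- oracle_match_counts(s, entries)
      for (j in which(cnts > 0)) {
        pid <- as.character(notes$patient_id[i])
        flags[[pid]] <- union(flags[[pid]], entries[[j]]$domain)
      }
    }
  }
  flags
}

# Random benign corpus for oracle-equivalence checks: sentences built from
# clean hits, trigger-excluded hits, near misses, and neutral fillers.
make_oracle_corpus <- function(n_sentences, entries, seed) {
  phrases <- unlist(lapply(entries, `[[`, "alts"))
  near_miss <- c("inattention persists", "memory poor overall",
                 "poormemory noted", "thoughtblocking", "concentrationally",
                 "reduced  attention span", "bad memoryfoam mattress")
  fillers <- c("Vitals stable today", "Patient doing well",
               "Medication continued", "Sleeping six hours nightly")
  withr::with_seed(seed, {
    kind <- sample(c("clean", "excluded", "miss", "filler"), n_sentences,
                   replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.25))
    vapply(kind, function(k) {
      switch(k,
        clean = sprintf("Patient has %s.", sample(phrases, 1)),
        excluded = sprintf(sample(c("Denies %s.", "Any %s?",
                                    "Goal: address %s.", "Mother has %s."), 1),
                           sample(phrases, 1)),
        miss = sprintf("%s.", sample(near_miss, 1)),
        filler = sprintf("%s.", sample(fillers, 1)))
    }, "")
  })
}
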