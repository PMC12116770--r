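# Sentence-level context-exclusion rules (negation / question / goal /
# family history), NegEx-style but sentence-scoped: a trigger anywhere in the
# sentence excludes all of its mentions.

#' Load context-exclusion rules from a YAML file
#'
#' The file lists word-level trigger patterns under `negation`, `goal` and
#' `family_history`, plus `question_terminal` (the character that marks a
#' question when sentence-final).  See the bundled
#' `extdata/exclusion_rules.yaml` for the format.
#'
#' @param path path to a rules YAML file.
#' @return An object of class `cog_rules`.
#' @export
load_exclusion_rules <- function(path) {
  if (!file.exists(path)) stop_cogehr("rules file not found: %s", path)
  raw <- yaml::read_yaml(path)
  new_exclusion_rules(negation = raw$negation,
                      goal = raw$goal,
                      family_history = raw$family_history,
                      question_terminal = raw$question_terminal %||% "?")
}

#' Construct context-exclusion rules
#'
#' @param negation,goal,family_history character vectors of word-level
#'   trigger patterns (single space = any whitespace).
#' @param question_terminal sentence-final character marking a question.
#' @return A `cog_rules` object with pre-compiled trigger regexes.
#' @export
new_exclusion_rules <- function(negation, goal, family_history,
                                question_terminal = "?") {
  compile_triggers <- function(x) {
    if (is.null(x) || !length(x)) return(NA_character_)
    paste0("\\b(?:", paste(expand_pattern(as.character(x)), collapse = "|"),
           ")\\b")
  }
  structure(list(
    negation = as.character(negation),
    goal = as.character(goal),
    family_history = as.character(family_history),
    question_terminal = question_terminal,
    regex = list(negation = compile_triggers(negation),
                 goal = compile_triggers(goal),
                 family_history = compile_triggers(family_history))
  ), class = "cog_rules")
}

#' The bundled default exclusion rules
#'
#' @return A `cog_rules` object.
#' @export
default_exclusion_rules <- function() {
  load_exclusion_rules(system.file("extdata", "exclusion_rules.yaml",
                                   package = "cogehr", mustWork = TRUE))
}

# Vectorized sentence classification.  Returns one of
# none/negation/question/goal/family_history per sentence, applying the fixed
# precedence negation > question > goal > family_history.
classify_sentences <- function(texts, rules) {
  stopifnot(inherits(rules, "cog_rules"))
  n <- length(texts)
  out <- rep("none", n)
  detect <- function(rx) {
    if (is.na(rx)) return(rep(FALSE, n))
    stringi::stri_detect_regex(texts, rx,
                               opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE))
  }
  is_q <- endsWith(trimws(texts), rules$question_terminal)
  fam <- detect(rules$regex$family_history)
  gol <- detect(rules$regex$goal)
  neg <- detect(rules$regex$negation)
  out[fam] <- "family_history"
  out[gol] <- "goal"
  out[is_q] <- "question"
  out[neg] <- "negation"
  out
}

#' Classify the exclusion status of a sentence
#'
#' Applies the four sentence-level context rules in fixed precedence order
#' (negation, then question, then goal, then family history) and returns the
#' first that fires, or `"none"`.  The scope is the whole sentence: one
#' trigger excludes every mention the sentence contains.
#'
#' @param sentence sentence text (character vector; vectorized).
#' @param rules a `cog_rules` object (default bundled rules).
#' @return Character vector over
#'   `c("none", "negation", "question", "goal", "family_history")`.
#' @export
#' @examples
#' classify_exclusion("Denies poor memory.")
#' classify_exclusion("Does he have difficulty remembering things?")
classify_exclusion <- function(sentence, rules = default_exclusion_rules()) {
  classify_sentences(as.character(sentence), rules)
}
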