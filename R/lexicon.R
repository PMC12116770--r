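# Lexicon: the five-domain phrase inventory and its compilation to
# word-boundary regular expressions.
#
# A lexicon entry is a list with fields entry_id, domain, category, patterns
# (character vector of word-level patterns), example (a canonical surface
# phrase matched by the first pattern; used by the synthetic-note generator)
# and requires_qualifier (logical; see compile_lexicon).  In a pattern, a
# single space stands for "any whitespace" and is compiled to \s+; everything
# else is ICU regular-expression syntax.

#' Load a cognitive-impairment lexicon from a YAML file
#'
#' The file holds one record per entry: `domain`, `category`, `patterns`
#' (a list of word-level patterns), optional `example` and
#' `requires_qualifier`.  Entry ids are formed as `domain/category` with
#' spaces slugged to underscores.  Validation enforces the five-domain
#' vocabulary, uniqueness of (domain, category), at least one entry per
#' domain, and that every pattern compiles.
#'
#' @param path path to a lexicon YAML file.
#' @return An object of class `cog_lexicon`.
#' @seealso [default_lexicon()], [compile_lexicon()], [write_lexicon()]
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop_cogehr("lexicon file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_cogehr("failed to parse lexicon file %s: %s", path, conditionMessage(e)))
  if (is.null(raw$entries) || length(raw$entries) == 0)
    stop_cogehr("lexicon file %s has no entries", path)
  entries <- lapply(raw$entries, function(e) {
    list(domain = e$domain %||% NA_character_,
         category = e$category %||% NA_character_,
         patterns = as.character(unlist(e$patterns)),
         example = e$example %||% NA_character_,
         requires_qualifier = isTRUE(e$requires_qualifier))
  })
  new_lexicon(entries,
              version = as.character(raw$version %||% "unversioned"),
              case_sensitive = isTRUE(raw$case_sensitive))
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

new_lexicon <- function(entries, version = "unversioned",
                        case_sensitive = FALSE) {
  entries <- lapply(entries, function(e) {
    e$entry_id <- e$entry_id %||% paste0(slug(e$domain), "/", slug(e$category))
    if (is.na(e$example) && length(e$patterns))
      e$example <- pattern_example(e$patterns[[1]])
    e
  })
  lex <- structure(list(entries = entries, version = version,
                        case_sensitive = case_sensitive),
                   class = "cog_lexicon")
  validate_lexicon(lex)
  lex
}

validate_lexicon <- function(lex) {
  domains <- vapply(lex$entries, `[[`, "", "domain")
  categories <- vapply(lex$entries, `[[`, "", "category")
  ids <- vapply(lex$entries, `[[`, "", "entry_id")
  unknown <- setdiff(unique(domains), cog_domains())
  if (length(unknown))
    stop_cogehr("unknown domain(s) in lexicon: %s", paste(unknown, collapse = ", "))
  missing <- setdiff(cog_domains(), unique(domains))
  if (length(missing))
    stop_cogehr("lexicon has no entries for domain(s): %s",
                paste(missing, collapse = ", "))
  key <- paste(domains, categories, sep = " / ")
  if (anyDuplicated(key))
    stop_cogehr("duplicate (domain, category) in lexicon: %s",
                paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(ids))
    stop_cogehr("duplicate entry_id in lexicon: %s",
                paste(unique(ids[duplicated(ids)]), collapse = "; "))
  for (e in lex$entries) {
    if (length(e$patterns) == 0 || any(!nzchar(e$patterns)))
      stop_cogehr("entry '%s' has an empty pattern list or blank pattern", e$entry_id)
    for (p in e$patterns) {
      ok <- tryCatch({
        stringi::stri_detect_regex("", expand_pattern(p))
        TRUE
      }, error = function(err) FALSE)
      if (!ok) stop_cogehr("pattern does not compile in entry '%s': %s",
                           e$entry_id, p)
    }
  }
  invisible(lex)
}

# A word-level pattern uses single spaces between tokens; compilation maps
# them to \s+ so phrases match across line wraps and double spaces.
expand_pattern <- function(pattern) {
  gsub(" ", "\\\\s+", pattern, fixed = FALSE)
}

# Derive a plain surface phrase from a pattern: take the first alternative in
# every (?:a|b) group and drop residual regex metacharacters.
pattern_example <- function(pattern) {
  x <- pattern
  repeat {
    y <- sub("\\(\\?:([^()|]*)(\\|[^()]*)?\\)", "\\1", x)
    if (identical(y, x)) break
    x <- y
  }
  x <- gsub("\\\\s\\+", " ", x)
  x <- gsub("[\\]\\[\\\\^$*+?(){}|]", "", x, perl = TRUE)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Write a lexicon back to YAML
#'
#' Round-trips with [load_lexicon()]: re-loading the written file yields an
#' equal lexicon (same entries in the same order).
#'
#' @param lex a `cog_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "cog_lexicon"))
  out <- list(
    version = lex$version,
    case_sensitive = lex$case_sensitive,
    entries = lapply(lex$entries, function(e) {
      rec <- list(domain = e$domain, category = e$category,
                  patterns = as.list(e$patterns), example = e$example)
      if (isTRUE(e$requires_qualifier)) rec$requires_qualifier <- TRUE
      rec
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The bundled five-domain cognitive-impairment lexicon
#'
#' Thirty phrase categories across the five domains, each compiled from its
#' category label with flexible whitespace and simple morphological
#' alternates.  The "insight and judgment" entry additionally requires an
#' impairment qualifier in the sentence (see [compile_lexicon()]), because the
#' bare phrase is a routine mental-status-exam heading.
#'
#' @return A `cog_lexicon`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' length(lex$entries)
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon_default.yaml",
                           package = "cogehr", mustWork = TRUE))
}

#' Compile a lexicon into matchable regular expressions
#'
#' Each entry's alternatives are combined into a single ICU regular expression
#' anchored with word boundaries on both ends
#' (`\\b(?:alt1|alt2|...)\\b`), case-insensitive unless the lexicon says
#' otherwise, with single spaces expanded to `\\s+`.  Compilation is
#' deterministic: the same lexicon always yields the same compiled table.
#'
#' Entries flagged `requires_qualifier` only produce mentions when the
#' containing sentence also matches `qualifier_pattern`; set
#' `require_qualifiers = FALSE` to disable this gate globally (the bare
#' phrase then matches on its own).
#'
#' @param lex a `cog_lexicon`.
#' @param require_qualifiers honour entry-level `requires_qualifier` flags?
#' @param qualifier_pattern word-level pattern a qualified sentence must
#'   contain (default: common impairment qualifiers).
#' @return An object of class `cog_compiled_lexicon`: a data frame with one
#'   row per entry (`entry_id`, `domain`, `category`, `regex`,
#'   `requires_qualifier`, `example`) plus matching attributes.
#' @export
compile_lexicon <- function(lex, require_qualifiers = TRUE,
                            qualifier_pattern =
                              "(?:impaired|impairment|poor|limited|fair|decreased|diminished|deficit|deficits)") {
  stopifnot(inherits(lex, "cog_lexicon"))
  validate_lexicon(lex)
  rows <- lapply(lex$entries, function(e) {
    body <- paste0("(?:", paste(expand_pattern(e$patterns), collapse = "|"), ")")
    data.frame(entry_id = e$entry_id, domain = e$domain, category = e$category,
               regex = paste0("\\b", body, "\\b"),
               requires_qualifier = isTRUE(e$requires_qualifier) && require_qualifiers,
               example = e$example, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "case_insensitive") <- !isTRUE(lex$case_sensitive)
  attr(out, "qualifier_regex") <-
    paste0("\\b", expand_pattern(qualifier_pattern), "\\b")
  class(out) <- c("cog_compiled_lexicon", "data.frame")
  out
}

#' @export
print.cog_lexicon <- function(x, ...) {
  domains <- vapply(x$entries, `[[`, "", "domain")
  cat(sprintf("<cog_lexicon> version %s: %d entries across %d domains\n",
              x$version, length(x$entries), length(unique(domains))))
  print(table(domain = domains))
  invisible(x)
}
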