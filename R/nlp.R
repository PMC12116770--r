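# Note preprocessing: markup stripping and sentence segmentation.

#' Strip HTML markup from clinical note text
#'
#' Removes tags, decodes entity references, and replaces block-level tags
#' (`p`, `div`, `br`, `li`, table cells, headings, ...) with newlines so that
#' words from adjacent blocks do not fuse.  Malformed markup is handled
#' leniently via the libxml2 HTML parser; text without any markup passes
#' through unchanged.
#'
#' @param raw_text character vector of raw note texts.
#' @return Character vector of plain texts (may contain newlines at former
#'   block boundaries).
#' @export
#' @examples
#' strip_markup("<p>poor memory</p>")
#' strip_markup("<div>poor</div><div>memory</div>")
strip_markup <- function(raw_text) {
  vapply(as.character(raw_text), strip_markup_one, character(1),
         USE.NAMES = FALSE)
}

.block_tag_rx <- paste0(
  "(?i)</?(?:p|div|br|li|ul|ol|tr|td|th|table|thead|tbody|h[1-6]|section|",
  "article|header|footer|blockquote|hr|dt|dd|dl|pre)\\b[^>]*/?>")

strip_markup_one <- function(txt) {
  if (is.na(txt)) return(NA_character_)
  has_tag <- grepl("<[A-Za-z/!]", txt)
  has_entity <- grepl("&[A-Za-z#][A-Za-z0-9]*;", txt)
  if (!has_tag && !has_entity) return(txt)
  # block-level boundaries become explicit newlines before tag removal
  txt <- gsub(.block_tag_rx, "\n", txt, perl = TRUE)
  doc <- tryCatch(
    xml2::read_html(paste0("<cogehr-root>", txt, "</cogehr-root>")),
    error = function(e) NULL)
  out <- if (!is.null(doc)) xml2::xml_text(doc)
         else gsub("<[^>]*>", " ", txt)        # last-resort lenient fallback
  # collapse runs of spaces/tabs introduced by markup; keep newlines, which
  # the segmenter treats as boundaries
  out <- gsub("[ \t]+", " ", out)
  out <- gsub(" ?\n ?", "\n", out)
  trimws(out)
}

.default_abbreviations <- c("dr", "mr", "mrs", "ms", "prof", "st", "vs",
                            "etc", "approx", "pt", "pts", "e.g", "i.e",
                            "eg", "ie", "no")

#' Segment plain text into sentences with character offsets
#'
#' Terminal punctuation (`.`, `!`, `?`) followed by whitespace or end of text
#' closes a sentence, except after common abbreviations (Dr., pt., e.g., ...).
#' Decimal points never split because the period is not followed by
#' whitespace.  Newlines (e.g. list items, former block boundaries) are
#' always sentence boundaries.  Offsets are 0-based half-open into the input
#' text; together the sentence spans cover every non-whitespace character.
#'
#' @param text a single markup-free string.
#' @param abbreviations lowercase tokens whose trailing period does not end a
#'   sentence.
#' @return Data frame with columns `sentence_index` (0-based), `text`,
#'   `start`, `end` (0-based half-open offsets into `text`).
#' @export
#' @examples
#' segment_sentences("He denies poor memory. She has poor concentration.")
#' segment_sentences("BMI 30.1 noted. Insight and judgment impaired.")
segment_sentences <- function(text, abbreviations = .default_abbreviations) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(sentence_index = integer(0), text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  loc <- stringi::stri_locate_all_regex(text, "[.!?]+(?=\\s|$)|\\r?\\n+")[[1]]
  cuts <- integer(0)
  if (!all(is.na(loc[, 1]))) {
    for (i in seq_len(nrow(loc))) {
      s <- loc[i, 1]; e <- loc[i, 2]
      piece <- substr(text, s, e)
      if (grepl("^[.!?]+$", piece)) {
        if (startsWith(piece, ".") && !grepl("[!?]", piece)) {
          # abbreviation guard: look at the token preceding the period
          before <- substr(text, max(1L, s - 24L), s - 1L)
          tok <- stringi::stri_extract_last_regex(before, "[A-Za-z][A-Za-z.]*$")
          if (!is.na(tok) && tolower(tok) %in% abbreviations) next
        }
        cuts <- c(cuts, e)
      } else {
        cuts <- c(cuts, e)  # newline run: always a boundary
      }
    }
  }
  nch <- nchar(text)
  bounds <- sort(unique(c(cuts[cuts < nch], nch)))
  starts1 <- c(1L, head(bounds, -1L) + 1L)
  piece <- substring(text, starts1, bounds)
  lead <- nchar(piece) - nchar(sub("^[[:space:]]+", "", piece))
  trail <- nchar(piece) - nchar(sub("[[:space:]]+$", "", piece))
  s1t <- starts1 + lead; e1t <- bounds - trail
  keep <- e1t >= s1t  # drop whitespace-only spans
  s1t <- s1t[keep]; e1t <- e1t[keep]
  out <- data.frame(sentence_index = seq_along(s1t) - 1L,
                    text = substring(text, s1t, e1t),
                    start = s1t - 1L, end = e1t, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
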