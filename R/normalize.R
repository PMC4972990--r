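#' Normalize free text for lexicon matching
#'
#' All matching in lexiscreen happens on normalized text: lowercased, with
#' leading/trailing whitespace stripped and internal whitespace runs collapsed
#' to a single space. Curly apostrophes are mapped to the ASCII apostrophe so
#' that contractions ("i'm") compare equal regardless of input keyboard.
#' Emoticon glyph sequences such as ":-(" are preserved verbatim: punctuation
#' carries affective signal in short messages and must survive normalization.
#' The function is idempotent.
#'
#' @param raw Character vector of raw text.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_text("  I'm   Worthless ")
#' normalize_text(":-(")
#' @export
normalize_text <- function(raw) {
  if (!is.character(raw)) abort_input("`raw` must be a character vector.")
  x <- stringr::str_replace_all(raw, "[‘’ʼ]", "'")
  x <- stringr::str_to_lower(x)
  stringr::str_squish(x)
}

# Word characters for boundary semantics: alphanumerics plus apostrophe
# (so "i'm" is one word). Everything else -- spaces, emoticon punctuation --
# is a boundary character.
.word_char_re <- "[[:alnum:]']"

is_word_char <- function(ch) {
  nzchar(ch) & grepl(.word_char_re, ch)
}
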