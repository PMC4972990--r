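# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Naive all-phrases-at-all-positions scan with the word-boundary rule
# (word characters: alphanumerics + apostrophe). Offsets 0-based half-open.
oracle_word_char <- function(ch) nzchar(ch) && grepl("[[:alnum:]']", ch)

oracle_scan <- function(phrase_tbl, norm_text) {
  n <- nchar(norm_text)
  rows <- list()
  for (r in seq_len(nrow(phrase_tbl))) {
    p <- phrase_tbl$phrase[r]
    len <- nchar(p)
    if (len > n) next
    for (s in seq_len(n - len + 1L)) {
      if (substring(norm_text, s, s + len - 1L) != p) next
      left_ok <- s == 1L ||
        !oracle_word_char(substring(norm_text, s - 1L, s - 1L))
      right_ok <- s + len - 1L == n ||
        !oracle_word_char(substring(norm_text, s + len, s + len))
      if (left_ok && right_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s - 1L, end = s - 1L + len, phrase = p,
          entry_id = phrase_tbl$entry_id[r],
          category = phrase_tbl$category[r],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      start = integer(0), end = integer(0), phrase = character(0),
      entry_id = character(0), category = character(0)
    )
  }
  out[order(out$start, out$end, out$entry_id, out$phrase), , drop = FALSE]
}

# Recursive enumeration of the word-by-word combination rule (single-word
# variant maps only), independent of both expand_keyword's expand.grid and
# expansion_count's closed form.
oracle_enumerate <- function(words, vmap_list) {
  if (length(words) == 0) {
    return("")
  }
  rest <- oracle_enumerate(words[-1], vmap_list)
  opts <- c(words[1], vmap_list[[words[1]]])
  out <- character(0)
  for (o in opts) {
    for (r in rest) {
      out <- c(out, if (nzchar(r)) paste(o, r) else o)
    }
  }
  out
}

# Random single-word-key variant instance for expansion property tests.
random_expansion_instance <- function() {
  n_words <- sample(1:4, 1)
  words <- replicate(
    n_words,
    paste(sample(letters[1:6], sample(3:5, 1), replace = TRUE), collapse = "")
  )
  words <- make.unique(words, sep = "x")
  vmap_list <- lapply(words, function(w) {
    k <- sample(0:3, 1)
    if (k == 0) character(0) else paste0(w, "v", seq_len(k))
  })
  names(vmap_list) <- words
  list(
    phrase = paste(words, collapse = " "),
    vmap_list = vmap_list[lengths(vmap_list) > 0]
  )
}

# Hand-built lexicon used across screening tests.
tiny_lexicon <- function() {
  lexicon(tibble::tibble(
    entry_id = c("kw_guilt", "kw_suicide", "kw_mood"),
    category = c("guilt_self_esteem", "suicide", "mood"),
    surface = c("i feel worthless", "take my life", "sad"),
    derivatives = list("feeling worthless", character(0), character(0)),
    variations = list(
      "im wrthless", c("tke my life", "take my lyf"), ":-("
    ),
    sources = list("expert_interview", "expert_interview", "focus_group")
  ))
}

# Flat (phrase, entry_id, category) table of everything a lexicon matches.
all_phrases <- function(lex) {
  e <- lex$entries
  tbl <- tibble::tibble(
    phrase = c(
      e$surface,
      unlist(e$derivatives, use.names = FALSE),
      unlist(e$variations, use.names = FALSE)
    ),
    entry_id = c(
      e$entry_id,
      rep(e$entry_id, lengths(e$derivatives)),
      rep(e$entry_id, lengths(e$variations))
    )
  )
  tbl$category <- e$category[match(tbl$entry_id, e$entry_id)]
  unique(tbl)
}

quiet_config <- function(...) suppressWarnings(validation_config(...))
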