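#' Read a message log
#'
#' Two formats: `"tsv"` expects a tab-separated UTF-8 file with header
#' `message_id`, `timestamp`, `text` (timestamps ISO-8601); `"plain"` treats
#' every non-empty line as one message text, assigning synthetic ids and no
#' timestamps.
#'
#' @param path File path.
#' @param format `"tsv"` or `"plain"`.
#' @return A tibble with columns `message_id`, `timestamp` (character),
#'   `text`.
#' @export
read_messages <- function(path, format = c("tsv", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_input(sprintf("Message file not found: %s.", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "plain") {
    lines <- lines[nzchar(lines)]
    return(tibble::tibble(
      message_id = sprintf("msg%05d", seq_along(lines)),
      timestamp = NA_character_,
      text = lines
    ))
  }
  if (length(lines) < 1) abort_input("Message file is empty.")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("message_id", "timestamp", "text"))) {
    abort_input("Line 1: header must be message_id\ttimestamp\ttext.")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    abort_input(sprintf("Line %d: expected 3 tab-separated fields.", bad[1] + 1L))
  }
  mat <- do.call(rbind, fields)
  out <- tibble::tibble(
    message_id = mat[, 1], timestamp = mat[, 2], text = mat[, 3]
  )
  if (anyDuplicated(out$message_id)) {
    abort_input("Duplicate message_id(s) in message log.")
  }
  out
}

#' Build an exact phrase matcher from a lexicon
#'
#' Indexes every surface, derivative and spelling variation of the lexicon
#' for exact matching on normalized text at word boundaries: a phrase matches
#' only where it is flanked by non-word characters (anything other than
#' alphanumerics and the apostrophe) or the string edges, so "worthless"
#' does not fire inside "worthlessness", while emoticon phrases such as
#' ":-(" are matchable as words in their own right. Candidate positions are
#' generated from a hash index on each phrase's first word (or first glyph,
#' for punctuation-initial phrases) and verified by substring comparison, so
#' lookup behavior is independent of entry insertion order.
#'
#' @param lex A non-empty [lexicon()].
#' @return An object of class `"lexicon_matcher"`.
#' @export
build_matcher <- function(lex) {
  check_lexicon(lex)
  e <- lex$entries
  if (nrow(e) == 0) abort_input("Cannot build a matcher from an empty lexicon.")
  phrase_tbl <- tibble::tibble(
    phrase = c(
      e$surface,
      unlist(e$derivatives, use.names = FALSE),
      unlist(e$variations, use.names = FALSE)
    ),
    entry_id = c(
      e$entry_id,
      rep(e$entry_id, lengths(e$derivatives)),
      rep(e$entry_id, lengths(e$variations))
    ),
    role = c(
      rep("surface", nrow(e)),
      rep("derivative", sum(lengths(e$derivatives))),
      rep("variation", sum(lengths(e$variations)))
    )
  )
  phrase_tbl$category <- e$category[match(phrase_tbl$entry_id, e$entry_id)]
  phrase_tbl <- dplyr::distinct(
    phrase_tbl, phrase, entry_id, .keep_all = TRUE
  )
  # sort for insertion-order independence
  phrase_tbl <- phrase_tbl[order(phrase_tbl$phrase, phrase_tbl$entry_id), ]

  uniq <- unique(phrase_tbl$phrase)
  first_is_word <- is_word_char(substr(uniq, 1, 1))
  first_key <- ifelse(
    first_is_word,
    stringr::str_extract(uniq, paste0("^", .word_char_re, "+")),
    substr(uniq, 1, 1)
  )
  word_index <- split(which(first_is_word), first_key[first_is_word])
  punct_index <- split(which(!first_is_word), first_key[!first_is_word])

  structure(
    list(
      phrases = uniq,
      phrase_nchar = nchar(uniq),
      word_index = word_index,
      punct_index = punct_index,
      phrase_tbl = phrase_tbl
    ),
    class = "lexicon_matcher"
  )
}

#' @export
print.lexicon_matcher <- function(x, ...) {
  cat(sprintf(
    "<lexicon_matcher> %d distinct phrases over %d (phrase, entry) pairs\n",
    length(x$phrases), nrow(x$phrase_tbl)
  ))
  invisible(x)
}

# All boundary-respecting occurrences of indexed phrases in one normalized
# text. Returns a tibble of candidate spans (0-based half-open offsets).
match_candidates <- function(matcher, norm_text) {
  n <- nchar(norm_text)
  empty <- tibble::tibble(
    start = integer(0), end = integer(0), phrase = character(0)
  )
  if (n == 0) return(empty)
  starts <- integer(0)
  idx <- integer(0)

  # word-initial phrases: candidates are starts of maximal word-char runs
  tok <- gregexpr("[[:alnum:]']+", norm_text)[[1]]
  if (tok[1] != -1) {
    tok_start <- as.integer(tok)
    tok_text <- substring(
      norm_text, tok_start, tok_start + attr(tok, "match.length") - 1L
    )
    hit_lists <- matcher$word_index[tok_text]
    for (j in seq_along(tok_start)) {
      cand <- hit_lists[[j]]
      if (!is.null(cand)) {
        starts <- c(starts, rep(tok_start[j], length(cand)))
        idx <- c(idx, cand)
      }
    }
  }
  # punctuation-initial phrases: candidates are occurrences of the first
  # glyph with a non-word (or edge) left neighbour
  if (length(matcher$punct_index) > 0) {
    chars <- strsplit(norm_text, "", fixed = TRUE)[[1]]
    for (key in names(matcher$punct_index)) {
      pos <- which(chars == key)
      ok <- pos == 1L | !is_word_char(chars[pmax(pos - 1L, 1L)])
      pos <- pos[ok]
      cand <- matcher$punct_index[[key]]
      if (length(pos) > 0 && length(cand) > 0) {
        starts <- c(starts, rep(pos, each = length(cand)))
        idx <- c(idx, rep(cand, times = length(pos)))
      }
    }
  }
  if (length(starts) == 0) return(empty)

  len <- matcher$phrase_nchar[idx]
  ends <- starts + len - 1L
  keep <- ends <= n
  starts <- starts[keep]; ends <- ends[keep]; idx <- idx[keep]
  if (length(starts) == 0) return(empty)
  # exact substring verification
  keep <- substring(norm_text, starts, ends) == matcher$phrases[idx]
  starts <- starts[keep]; ends <- ends[keep]; idx <- idx[keep]
  if (length(starts) == 0) return(empty)
  # right boundary: next char must be non-word or string end
  nxt <- substring(norm_text, ends + 1L, ends + 1L)
  keep <- ends == n | !is_word_char(nxt)
  starts <- starts[keep]; ends <- ends[keep]; idx <- idx[keep]
  tibble::tibble(
    start = starts - 1L, # 0-based
    end = starts - 1L + matcher$phrase_nchar[idx], # half-open
    phrase = matcher$phrases[idx]
  )
}

resolve_overlaps <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  len <- cand$end - cand$start
  ord <- order(-len, cand$start, cand$entry_id, cand$phrase)
  cand <- cand[ord, ]
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  out <- cand[keep, ]
  out[order(out$start, out$end), ]
}

#' Screen a message stream against a lexicon matcher
#'
#' Normalizes every message, finds all boundary-respecting occurrences of
#' lexicon phrases, resolves overlaps, and tallies hits per symptom category.
#' With the default `policy = "consume"`, overlapping candidate matches are
#' resolved longest-match-first, then leftmost, and a consumed span yields
#' exactly one hit (ties between entries sharing an identical span are broken
#' deterministically by entry id). `policy = "all"` keeps every candidate
#' occurrence, which is the mode comparable to an exhaustive
#' all-phrases-at-all-positions scan.
#'
#' @param messages Tibble with columns `message_id`, `timestamp`, `text`
#'   (as from [read_messages()]).
#' @param matcher A [build_matcher()] result.
#' @param policy `"consume"` (default) or `"all"`.
#' @return An object of class `"screening_report"` with fields `hits`
#'   (tibble: message_id, start, end, matched_surface, entry_id, category;
#'   offsets 0-based half-open into the normalized text), `messages` (input
#'   plus `normalized_text`, for auditability), `category_counts` (named
#'   vector over the 13 categories), `n_flagged_categories`, and `policy`.
#' @export
screen <- function(messages, matcher, policy = c("consume", "all")) {
  policy <- match.arg(policy)
  if (!inherits(matcher, "lexicon_matcher")) {
    abort_input("Expected a `lexicon_matcher`.")
  }
  if (!is.data.frame(messages) ||
    !all(c("message_id", "text") %in% names(messages))) {
    abort_input("`messages` needs columns message_id and text.")
  }
  messages <- tibble::as_tibble(messages)
  if (!"timestamp" %in% names(messages)) messages$timestamp <- NA_character_
  if (anyDuplicated(messages$message_id)) {
    abort_input("Duplicate message_id(s).")
  }
  messages$normalized_text <- normalize_text(messages$text)

  per_msg <- lapply(seq_len(nrow(messages)), function(i) {
    cand <- match_candidates(matcher, messages$normalized_text[i])
    if (nrow(cand) == 0) return(NULL)
    cand <- dplyr::inner_join(
      cand, matcher$phrase_tbl,
      by = "phrase", relationship = "many-to-many"
    )
    if (policy == "consume") cand <- resolve_overlaps(cand)
    tibble::tibble(
      message_id = messages$message_id[i],
      start = cand$start, end = cand$end,
      matched_surface = cand$phrase,
      entry_id = cand$entry_id, category = cand$category
    )
  })
  hits <- dplyr::bind_rows(per_msg)
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(
      message_id = character(0), start = integer(0), end = integer(0),
      matched_surface = character(0), entry_id = character(0),
      category = character(0)
    )
  }
  counts <- table(factor(hits$category, levels = category_ids()))
  category_counts <- stats::setNames(as.integer(counts), category_ids())
  structure(
    list(
      hits = hits,
      messages = messages,
      category_counts = category_counts,
      n_flagged_categories = sum(category_counts > 0),
      policy = policy
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> %d messages, %d hits across %d of 13 categories (policy: %s)\n",
    nrow(x$messages), nrow(x$hits), x$n_flagged_categories, x$policy
  ))
  nonzero <- x$category_counts[x$category_counts > 0]
  if (length(nonzero) > 0) {
    for (cat_id in names(nonzero)) {
      cat(sprintf("  %-24s %d\n", cat_id, nonzero[[cat_id]]))
    }
  }
  invisible(x)
}

parse_window_length <- function(window_length) {
  if (is.numeric(window_length)) {
    if (window_length <= 0) abort_input("Window length must be positive.")
    return(as.numeric(window_length))
  }
  m <- stringr::str_match(window_length, "^([0-9]+(?:\\.[0-9]+)?)([smhd])$")
  if (is.na(m[1, 1])) {
    abort_input(
      "Window length must be numeric seconds or like \"30m\", \"24h\", \"7d\"."
    )
  }
  unit <- c(s = 1, m = 60, h = 3600, d = 86400)[[m[1, 3]]]
  as.numeric(m[1, 2]) * unit
}

parse_timestamps <- function(ts, message_id) {
  ts_clean <- sub("Z$", "", ts)
  out <- as.POSIXct(ts_clean,
    tz = "UTC",
    tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
    ),
    optional = TRUE
  )
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    abort_input(sprintf(
      "Unparseable timestamp for message(s): %s.",
      paste(message_id[bad], collapse = ", ")
    ))
  }
  out
}

#' Aggregate screening hits into fixed time windows
#'
#' Assigns every hit to exactly one window by the half-open rule: windows are
#' aligned to the epoch with length `window_length`, and a hit whose message
#' timestamp falls exactly on a window boundary belongs to the later window.
#' Window totals therefore always sum to the overall totals.
#'
#' @param report A [screen()] result whose messages carry timestamps.
#' @param window_length Numeric seconds or a string like `"30m"`, `"24h"`,
#'   `"7d"`.
#' @return A tibble with columns `window_start` (POSIXct, UTC), `category`,
#'   `n_hits`.
#' @export
aggregate_window <- function(report, window_length = "24h") {
  if (!inherits(report, "screening_report")) {
    abort_input("Expected a `screening_report`.")
  }
  len <- parse_window_length(window_length)
  hits <- report$hits
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      window_start = as.POSIXct(character(0), tz = "UTC"),
      category = character(0), n_hits = integer(0)
    ))
  }
  msg <- report$messages
  ts <- parse_timestamps(
    msg$timestamp[match(hits$message_id, msg$message_id)],
    hits$message_id
  )
  win <- floor(as.numeric(ts) / len)
  tibble::tibble(
    window_start = as.POSIXct(win * len, origin = "1970-01-01", tz = "UTC"),
    category = hits$category
  ) |>
    dplyr::count(window_start, category, name = "n_hits") |>
    dplyr::arrange(window_start, category)
}
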