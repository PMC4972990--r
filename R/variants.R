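#' Construct a spelling-variant map
#'
#' A variant map associates words with their textspeak spelling variants
#' ("stop" -> "stp"). Keys may be multi-word spans ("can not"), whose variants
#' replace the whole span with a single merged token ("cant"); such keys are
#' matched greedily left-to-right before per-word expansion. Variants are
#' normalized, must be single tokens (no internal spaces), must differ from
#' their source word, and are deduplicated preserving order.
#'
#' @param x Named list: word (or multi-word span) -> character vector of
#'   variants.
#' @return An object of class `"variant_map"` (a validated named list).
#' @examples
#' vm <- variant_map(list(stop = c("stp"), "can not" = "cant"))
#' expand_keyword("can not stop", vm)
#' @export
variant_map <- function(x) {
  if (!is.list(x) ||
    (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x)))))) {
    abort_input("`x` must be a fully named list of character vectors.")
  }
  if (length(x) == 0) {
    return(structure(stats::setNames(list(), character(0)), class = "variant_map"))
  }
  keys <- normalize_text(names(x))
  if (anyDuplicated(keys)) {
    abort_input("Variant-map keys must be unique after normalization.")
  }
  vals <- purrr::map2(x, keys, function(v, key) {
    v <- unique(normalize_text(as.character(v)))
    v <- v[nzchar(v)]
    if (any(grepl(" ", v, fixed = TRUE))) {
      abort_input(sprintf(
        "Variants of %s must be single tokens (no spaces).", dQuote(key)
      ))
    }
    if (any(v == key)) {
      abort_input(sprintf("A variant of %s equals its source.", dQuote(key)))
    }
    v
  })
  names(vals) <- keys
  structure(vals, class = "variant_map")
}

#' Read / write a variant map
#'
#' Tab-separated UTF-8, one line per key: `word TAB variant|variant|...`.
#'
#' @param path File path.
#' @return For `read_variant_map()`, a [variant_map()]; for
#'   `write_variant_map()`, `path` invisibly.
#' @export
read_variant_map <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Variant-map file not found: %s.", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort_input(sprintf(
      "Line %d: expected 2 tab-separated fields.", bad[1]
    ))
  }
  keys <- vapply(fields, `[[`, character(1), 1)
  vals <- split_multi(vapply(fields, `[[`, character(1), 2))
  names(vals) <- keys
  variant_map(vals)
}

#' @rdname read_variant_map
#' @param vmap A [variant_map()].
#' @export
write_variant_map <- function(vmap, path) {
  if (!inherits(vmap, "variant_map")) abort_input("Expected a `variant_map`.")
  writeLines(
    sprintf("%s\t%s", names(vmap), join_multi(vmap)),
    path,
    useBytes = TRUE
  )
  invisible(path)
}

#' Expansion configuration
#'
#' @param include_original Keep the unmodified phrase in the output set?
#'   Defaults to `FALSE`: spelling variations are counted separately from the
#'   main keyword they derive from.
#' @param max_output Cap on the size of the full combination product per
#'   keyword; exceeding it is an explicit overflow error. The default keeps
#'   whole-lexicon expansion desk-scale.
#' @return An object of class `"expansion_config"`.
#' @export
expansion_config <- function(include_original = FALSE, max_output = 1e6) {
  if (!is.numeric(max_output) || length(max_output) != 1 || max_output < 1) {
    abort_input("`max_output` must be a positive number.")
  }
  structure(
    list(
      include_original = isTRUE(include_original),
      max_output = max_output
    ),
    class = "expansion_config"
  )
}

# Segment a phrase against the variant map: greedy left-to-right, longest
# multi-word key first. Each segment carries the original span text and its
# variant options.
segment_phrase <- function(phrase, vmap) {
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  key_lens <- vapply(
    strsplit(names(vmap), " ", fixed = TRUE), length, integer(1)
  )
  max_len <- max(c(1L, key_lens))
  segs <- list()
  i <- 1L
  while (i <= length(words)) {
    matched <- FALSE
    for (k in seq(min(max_len, length(words) - i + 1L), 1L)) {
      span <- paste(words[i:(i + k - 1L)], collapse = " ")
      if (span %in% names(vmap)) {
        segs[[length(segs) + 1L]] <- list(
          original = span, options = c(span, vmap[[span]])
        )
        i <- i + k
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      segs[[length(segs) + 1L]] <- list(
        original = words[i], options = words[i]
      )
      i <- i + 1L
    }
  }
  segs
}

#' Expand a keyword into its spelling-variation combinations
#'
#' Reproduces the variation-extension rule used to grow textspeak lexicons:
#' every word of a multi-word keyword may independently be replaced by any of
#' its spelling variants, and the variation set is the Cartesian product of
#' the per-word options (original word included as an option). With
#' `include_original = FALSE` (the default) the unmodified phrase itself is
#' removed from the result.
#'
#' @param phrase Normalized keyword text (1+ words).
#' @param vmap A [variant_map()].
#' @param cfg An [expansion_config()].
#' @return Character vector of unique normalized variant phrases.
#' @examples
#' vm <- variant_map(list(stop = c("stp"), crying = c("cryin")))
#' expand_keyword("can not stop crying", vm)
#' @export
expand_keyword <- function(phrase, vmap, cfg = expansion_config()) {
  phrase <- normalize_text(phrase)
  if (!nzchar(phrase)) abort_input("`phrase` must be non-empty.")
  if (!inherits(vmap, "variant_map")) abort_input("Expected a `variant_map`.")
  segs <- segment_phrase(phrase, vmap)
  sizes <- vapply(segs, function(s) length(s$options), integer(1))
  n_product <- prod(sizes)
  if (n_product > cfg$max_output) {
    abort_input(sprintf(
      "Expansion of %s would produce %.0f combinations, exceeding max_output = %.0f.",
      dQuote(phrase), n_product, cfg$max_output
    ))
  }
  grid <- expand.grid(
    lapply(segs, `[[`, "options"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- do.call(paste, c(unname(grid), list(sep = " ")))
  out <- unique(normalize_text(out))
  if (!cfg$include_original) out <- setdiff(out, phrase)
  out
}

#' Closed-form size of a keyword expansion
#'
#' Equals `prod(1 + v_i) - 1` over the phrase's segments (where `v_i` is the
#' number of variants of segment i), or `prod(1 + v_i)` when the original
#' phrase is kept. For variant maps whose variants are single tokens this is
#' exactly `length(expand_keyword(...))`.
#'
#' @inheritParams expand_keyword
#' @return A non-negative number.
#' @export
expansion_count <- function(phrase, vmap, cfg = expansion_config()) {
  phrase <- normalize_text(phrase)
  if (!nzchar(phrase)) abort_input("`phrase` must be non-empty.")
  if (!inherits(vmap, "variant_map")) abort_input("Expected a `variant_map`.")
  segs <- segment_phrase(phrase, vmap)
  sizes <- vapply(segs, function(s) length(s$options), numeric(1))
  prod(sizes) - if (cfg$include_original) 0 else 1
}

#' Deterministic textspeak variant candidates for a single word
#'
#' A small rule set mimicking common Filipino/English texting abbreviations:
#' internal-vowel dropping ("stop" -> "stp", "asleep" -> "aslp"), terminal
#' "ing" -> "in" ("crying" -> "cryin"), the word "to" -> "2", and i -> y with
#' a dropped trailing e ("life" -> "lyf"). Words shorter than 3 characters
#' yield no candidates (except the dedicated "to" rule). Intended for
#' building fixture variant maps; real lexica enumerate variants collected
#' from speakers instead.
#'
#' @param word A single token.
#' @param rules Subset of `c("vowel_drop", "ing_to_in", "to_2", "i_to_y")`.
#' @return Character vector of candidates, each differing from `word`;
#'   deterministic.
#' @examples
#' apply_textspeak_rules("stop")
#' apply_textspeak_rules("life")
#' @export
apply_textspeak_rules <- function(word,
                                  rules = c(
                                    "vowel_drop", "ing_to_in",
                                    "to_2", "i_to_y"
                                  )) {
  word <- normalize_text(word)
  if (length(word) != 1 || grepl(" ", word, fixed = TRUE)) {
    abort_input("`word` must be a single token.")
  }
  rules <- match.arg(rules, several.ok = TRUE)
  out <- character(0)
  n <- nchar(word)
  if ("to_2" %in% rules && word == "to") out <- c(out, "2")
  if (n >= 3) {
    if ("vowel_drop" %in% rules) {
      mid <- gsub("[aeiou]", "", substr(word, 2, n - 1))
      out <- c(out, paste0(substr(word, 1, 1), mid, substr(word, n, n)))
    }
    if ("ing_to_in" %in% rules && grepl("ing$", word)) {
      out <- c(out, sub("g$", "", word))
    }
    if ("i_to_y" %in% rules && grepl("i", word, fixed = TRUE) &&
      !grepl("y", word, fixed = TRUE)) {
      out <- c(out, sub("e$", "", gsub("i", "y", word, fixed = TRUE)))
    }
  }
  unique(out[nzchar(out) & out != word])
}

#' Add generated spelling variations to every lexicon entry
#'
#' Expands each entry's surface and derivatives against a variant map and
#' merges the results into the entry's variation set (never duplicating the
#' surface or a derivative). Entries that gain variants are tagged with the
#' `researcher_extension` source.
#'
#' @param lex A [lexicon()].
#' @param vmap A [variant_map()].
#' @param cfg An [expansion_config()].
#' @return The expanded [lexicon()].
#' @export
expand_lexicon <- function(lex, vmap, cfg = expansion_config()) {
  check_lexicon(lex)
  e <- lex$entries
  e$variations <- purrr::pmap(
    list(e$surface, e$derivatives, e$variations),
    function(surface, ders, vars) {
      new <- unlist(lapply(
        c(surface, ders), expand_keyword,
        vmap = vmap, cfg = cfg
      ))
      setdiff(unique(c(vars, new)), c(surface, ders))
    }
  )
  gained <- lengths(e$variations) > 0
  e$sources[gained] <- lapply(
    e$sources[gained], function(s) unique(c(s, "researcher_extension"))
  )
  lexicon(e, metadata = lex$metadata)
}
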