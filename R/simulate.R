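#' Specification for seeded synthetic fixtures
#'
#' Describes the synthetic study material the package can generate: a toy
#' lexicon of pseudo-word keywords, an expert rating panel, and a stream of
#' short messages with keyword occurrences injected at known positions. All
#' randomness flows from `seed` through per-component sub-streams, so each
#' fixture is reproducible piecewise.
#'
#' Defaults emulate the structure of the study material the pipeline is
#' designed for: an 8-expert validation panel, short (5-15 word) messages in
#' an abbreviation-heavy texting style, multi-word keywords of 1-3 words with
#' up to 2 textspeak variants per word, and a high (0.9) per-entry probability
#' of an "essential" rating, consistent with per-category CVRs around 0.9.
#'
#' @param seed Integer master seed.
#' @param entries_per_category Keyword entries generated per category.
#' @param words_per_keyword Integer range of words per keyword phrase.
#' @param variants_per_word Integer range of spelling variants per word.
#' @param panel_size Number of expert raters (default 8).
#' @param essential_probability Per-entry probability that a rater marks the
#'   entry "essential"; scalar or one value per entry.
#' @param injection_rate Expected injected keyword occurrences per message.
#' @param n_messages Number of messages in the simulated stream.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L,
                         entries_per_category = 2L,
                         words_per_keyword = 1:3,
                         variants_per_word = 0:2,
                         panel_size = 8L,
                         essential_probability = 0.9,
                         injection_rate = 0.5,
                         n_messages = 100L) {
  if (length(words_per_keyword) == 0 || any(words_per_keyword < 1)) {
    abort_input("`words_per_keyword` must be a nonempty range of positives.")
  }
  if (length(variants_per_word) == 0 || any(variants_per_word < 0)) {
    abort_input("`variants_per_word` must be a nonempty non-negative range.")
  }
  if (entries_per_category < 1 || panel_size < 1) {
    abort_input("`entries_per_category` and `panel_size` must be positive.")
  }
  if (any(essential_probability < 0) || any(essential_probability > 1)) {
    abort_input("`essential_probability` must lie in [0, 1].")
  }
  if (injection_rate < 0) abort_input("`injection_rate` must be >= 0.")
  structure(
    list(
      seed = as.integer(seed),
      entries_per_category = as.integer(entries_per_category),
      words_per_keyword = as.integer(words_per_keyword),
      variants_per_word = as.integer(variants_per_word),
      panel_size = as.integer(panel_size),
      essential_probability = essential_probability,
      injection_rate = injection_rate,
      n_messages = as.integer(n_messages)
    ),
    class = "fixture_spec"
  )
}

check_spec <- function(spec) {
  if (!inherits(spec, "fixture_spec")) abort_input("Expected a `fixture_spec`.")
  invisible(spec)
}

# Pseudo-word keyword vocabulary: CV-syllable words that cannot collide with
# the plain-English/Filipino filler vocabulary below.
make_pseudo_words <- function(n, n_syllables = 2:3) {
  consonants <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vowels <- c("a", "e", "i", "o", "u")
  words <- character(0)
  while (length(words) < n) {
    k <- sample(n_syllables, 1)
    w <- paste0(
      sample(consonants, k, replace = TRUE),
      sample(vowels, k, replace = TRUE),
      collapse = ""
    )
    words <- unique(c(words, w))
  }
  words[seq_len(n)]
}

# Held-out neutral filler vocabulary for message streams; disjointness from
# all lexicon phrases is asserted at generation time.
filler_vocabulary <- function() {
  c(
    "the", "and", "then", "later", "today", "tonight", "after", "before",
    "class", "school", "campus", "library", "canteen", "jeep", "mall",
    "movie", "game", "music", "coffee", "lunch", "dinner", "merienda",
    "kumusta", "kamusta", "salamat", "sige", "opo", "naman", "talaga",
    "grabe", "ganda", "saya", "kain", "tara", "punta", "uwi", "gabi",
    "umaga", "hapon", "aral", "exam", "quiz", "project", "group", "friend",
    "barkada", "family", "home", "house", "rain", "traffic", "busy",
    "weekend", "monday", "friday", "see", "you", "meet", "watch", "play",
    "study", "review", "finish", "start", "going", "coming", "waiting"
  )
}

#' Generate a seeded toy lexicon with a known count summary
#'
#' Builds `13 * entries_per_category` keyword entries: each entry's surface is
#' a phrase of fresh pseudo-words (never reused across entries, so no lexicon
#' phrase is a sub-phrase of another), derivatives are word-order/tense
#' variants of the surface, and spelling variations are generated with
#' [apply_textspeak_rules()] and [expand_keyword()]. The per-category counts
#' tallied independently during generation are returned alongside, as a
#' cross-check for [count_summary()].
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `lexicon` (a [lexicon()]) and
#'   `expected_summary` (tibble shaped like [count_summary()] output).
#' @export
make_toy_lexicon <- function(spec = fixture_spec()) {
  check_spec(spec)
  withr::with_seed(derive_seed(spec$seed, "lexicon"), {
    ids <- category_ids()
    n_entries <- length(ids) * spec$entries_per_category
    n_words_each <- sample(
      spec$words_per_keyword, n_entries,
      replace = TRUE
    )
    vocab <- make_pseudo_words(sum(n_words_each))
    vocab_split <- split(
      vocab,
      rep(seq_len(n_entries), times = n_words_each)
    )
    rows <- vector("list", n_entries)
    for (i in seq_len(n_entries)) {
      cat_id <- ids[ceiling(i / spec$entries_per_category)]
      words <- vocab_split[[i]]
      surface <- paste(words, collapse = " ")
      ders <- character(0)
      if (length(words) > 1) {
        perm <- sample(length(words))
        if (identical(perm, seq_along(words))) perm <- rev(perm)
        ders <- paste(words[perm], collapse = " ")
      }
      ders <- unique(c(ders, paste(c(words, "na"), collapse = " ")))
      vmap_list <- lapply(words, function(w) {
        cand <- apply_textspeak_rules(w)
        n_var <- sample(spec$variants_per_word, 1)
        cand[seq_len(min(n_var, length(cand)))]
      })
      names(vmap_list) <- words
      vmap_list <- vmap_list[lengths(vmap_list) > 0]
      vars <- expand_keyword(surface, variant_map(vmap_list))
      rows[[i]] <- tibble::tibble(
        entry_id = sprintf("toy_%03d", i),
        category = cat_id,
        surface = surface,
        derivatives = list(ders),
        variations = list(vars),
        sources = list(c("focus_group", "researcher_extension"))
      )
    }
    entries <- dplyr::bind_rows(rows)

    # independent tally, by construction rather than by count_summary()
    expected <- tibble::tibble(
      category = entries$category,
      main = 1L,
      der = lengths(entries$derivatives),
      var = lengths(entries$variations)
    )
    expected <- stats::aggregate(
      cbind(main, der, var) ~ category,
      data = expected, FUN = sum
    )
    expected <- expected[match(ids, expected$category), ]
    expected[is.na(expected$main), c("main", "der", "var")] <- 0L
    expected$category <- ids
    summary_tbl <- tibble::tibble(
      category = c(ids, "total"),
      main_count = c(expected$main, sum(expected$main)),
      derivative_count = c(expected$der, sum(expected$der)),
      variation_count = c(expected$var, sum(expected$var))
    )
    summary_tbl$row_total <- summary_tbl$main_count +
      summary_tbl$derivative_count + summary_tbl$variation_count

    list(
      lexicon = lexicon(
        entries,
        metadata = list(
          name = sprintf("toy lexicon (seed %d)", spec$seed),
          language = "synthetic", seed = spec$seed
        )
      ),
      expected_summary = summary_tbl
    )
  })
}

#' Simulate a complete expert rating panel
#'
#' Each of the `panel_size` raters rates every lexicon entry independently:
#' "essential" with the entry's `essential_probability`, otherwise the
#' remaining mass is split equally between "useful but not essential" and
#' "not necessary".
#'
#' @param lex A [lexicon()].
#' @param spec A [fixture_spec()]; `essential_probability` may be a scalar or
#'   one value per entry.
#' @return A [rating_table()].
#' @export
simulate_ratings <- function(lex, spec = fixture_spec()) {
  check_lexicon(lex)
  check_spec(spec)
  n_entries <- nrow(lex$entries)
  p <- rep_len(spec$essential_probability, n_entries)
  withr::with_seed(derive_seed(spec$seed, "ratings"), {
    grid <- expand.grid(
      rater = sprintf("rater%02d", seq_len(spec$panel_size)),
      entry = lex$entries$entry_id,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    p_full <- rep(p, each = spec$panel_size)
    u <- stats::runif(nrow(grid))
    rating <- ifelse(
      u < p_full, "essential",
      ifelse(u < p_full + (1 - p_full) / 2,
        "useful_not_essential", "not_necessary"
      )
    )
    rating_table(tibble::tibble(
      entry_id = grid$entry, rater_id = grid$rater, rating = rating
    ))
  })
}

#' Simulate a message stream with ground-truth keyword injections
#'
#' Builds `n_messages` short messages of neutral filler words (a held-out
#' vocabulary checked to be disjoint from every token of every lexicon
#' phrase, making the ground truth exact rather than probabilistic) and
#' injects keyword occurrences — a surface, derivative or spelling variation
#' drawn uniformly from a random entry — at Poisson(`injection_rate`) per
#' message, never adjacent to one another. The number and character offsets
#' of all injections in the normalized text are recorded.
#'
#' @param lex A [lexicon()].
#' @param spec A [fixture_spec()].
#' @return A list with `messages` (tibble: message_id, timestamp, text) and
#'   `truth` (tibble: message_id, entry_id, category, phrase, start, end;
#'   offsets 0-based half-open).
#' @export
simulate_messages <- function(lex, spec = fixture_spec()) {
  check_lexicon(lex)
  check_spec(spec)
  if (spec$n_messages < 1) {
    abort_input("Cannot inject into a zero-length message stream.")
  }
  e <- lex$entries
  lex_tokens <- unique(unlist(strsplit(
    c(
      e$surface, unlist(e$derivatives, use.names = FALSE),
      unlist(e$variations, use.names = FALSE)
    ),
    " ",
    fixed = TRUE
  )))
  filler <- setdiff(filler_vocabulary(), lex_tokens)
  if (length(filler) < 5) {
    abort_input("Filler vocabulary is not disjoint from the lexicon.")
  }
  phrase_pool <- tibble::tibble(
    entry_id = rep(
      e$entry_id,
      1L + lengths(e$derivatives) + lengths(e$variations)
    ),
    phrase = unlist(
      purrr::pmap(
        list(e$surface, e$derivatives, e$variations),
        function(s, d, v) c(s, d, v)
      ),
      use.names = FALSE
    )
  )
  phrase_pool$category <- e$category[match(phrase_pool$entry_id, e$entry_id)]

  withr::with_seed(derive_seed(spec$seed, "messages"), {
    t0 <- as.POSIXct("2016-07-20 08:00:00", tz = "UTC")
    gaps <- cumsum(stats::rexp(spec$n_messages, rate = 1 / 1800))
    msgs <- vector("list", spec$n_messages)
    truths <- vector("list", spec$n_messages)
    for (i in seq_len(spec$n_messages)) {
      n_fill <- sample(5:15, 1)
      tokens <- sample(filler, n_fill, replace = TRUE)
      n_inj <- stats::rpois(1, spec$injection_rate)
      n_inj <- min(n_inj, n_fill - 1L) # keep injections non-adjacent
      inj_rows <- NULL
      if (n_inj > 0) {
        picks <- phrase_pool[
          sample.int(nrow(phrase_pool), n_inj, replace = TRUE),
        ]
        # insert after distinct filler positions so injections are
        # separated by at least one filler token
        slots <- sort(sample(seq_len(n_fill - 1L), n_inj))
        out_tokens <- character(0)
        inj_info <- list()
        prev <- 0L
        for (k in seq_len(n_inj)) {
          out_tokens <- c(out_tokens, tokens[(prev + 1L):slots[k]])
          start_char <- nchar(paste(out_tokens, collapse = " ")) + 1L
          out_tokens <- c(out_tokens, picks$phrase[k])
          inj_info[[k]] <- tibble::tibble(
            entry_id = picks$entry_id[k],
            category = picks$category[k],
            phrase = picks$phrase[k],
            start = start_char, # 0-based: length of prefix + 1 space
            end = start_char + nchar(picks$phrase[k])
          )
          prev <- slots[k]
        }
        out_tokens <- c(out_tokens, tokens[(prev + 1L):n_fill])
        tokens <- out_tokens
        inj_rows <- dplyr::bind_rows(inj_info)
      }
      text <- paste(tokens, collapse = " ")
      msg_id <- sprintf("msg%05d", i)
      msgs[[i]] <- tibble::tibble(
        message_id = msg_id,
        timestamp = format(t0 + gaps[i], "%Y-%m-%dT%H:%M:%S"),
        text = text
      )
      if (!is.null(inj_rows)) {
        inj_rows$message_id <- msg_id
        truths[[i]] <- inj_rows
      }
    }
    truth <- dplyr::bind_rows(truths)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(
        message_id = character(0), entry_id = character(0),
        category = character(0), phrase = character(0),
        start = integer(0), end = integer(0)
      )
    } else {
      truth <- truth[, c(
        "message_id", "entry_id", "category", "phrase", "start", "end"
      )]
    }
    list(messages = dplyr::bind_rows(msgs), truth = truth)
  })
}
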