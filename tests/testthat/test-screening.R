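msgs_tbl <- function(texts, ids = sprintf("m%d", seq_along(texts)),
                     ts = rep(NA_character_, length(texts))) {
  tibble::tibble(message_id = ids, timestamp = ts, text = texts)
}

test_that("the matcher recognizes lexicon phrases at word boundaries", {
  m <- build_matcher(tiny_lexicon())
  rep <- screen(msgs_tbl("today i feel worthless again"), m)
  expect_equal(nrow(rep$hits), 1)
  expect_equal(rep$hits$matched_surface, "i feel worthless")
  expect_equal(rep$hits$entry_id, "kw_guilt")
  # offsets are 0-based half-open into the normalized text
  expect_equal(
    substring(
      rep$messages$normalized_text, rep$hits$start + 1, rep$hits$end
    ),
    "i feel worthless"
  )

  # no match inside a longer word
  expect_equal(nrow(screen(msgs_tbl("sadness is not sad here"), m)$hits), 1)
  expect_equal(nrow(screen(msgs_tbl("worthlessness"), m)$hits), 0)
  # punctuation flanks are boundaries
  expect_equal(nrow(screen(msgs_tbl("(sad)"), m)$hits), 1)
  # empty message yields no hits
  expect_equal(nrow(screen(msgs_tbl(""), m)$hits), 0)
})

test_that("emoticons match as words of their own", {
  m <- build_matcher(tiny_lexicon())
  rep <- screen(msgs_tbl("im here :-( talaga"), m)
  expect_equal(rep$hits$matched_surface, ":-(")
  expect_equal(rep$hits$category, "mood")
  # flanking rule is strict: a word character on the left blocks the match
  expect_equal(nrow(screen(msgs_tbl("here:-("), m)$hits), 0)
})

test_that("spelling variations screen like their main keyword", {
  m <- build_matcher(tiny_lexicon())
  rep <- screen(msgs_tbl("lord please tke my life"), m)
  expect_equal(rep$hits$category, "suicide")
  expect_equal(rep$category_counts[["suicide"]], 1L)
})

test_that("empty lexica cannot be compiled into a matcher", {
  empty <- lexicon(tibble::tibble(
    entry_id = character(0), category = character(0), surface = character(0)
  ))
  expect_error(build_matcher(empty), "empty lexicon")
})

test_that("overlaps resolve longest-match-first then leftmost, consuming spans", {
  lex <- lexicon(tibble::tibble(
    entry_id = c("e1", "e2", "e3"),
    category = c("mood", "sleep", "fatigue"),
    surface = c("walang gana", "gana kumain", "gana"),
    derivatives = list(character(0), character(0), character(0)),
    variations = list(character(0), character(0), character(0)),
    sources = list("focus_group", "focus_group", "focus_group")
  ))
  m <- build_matcher(lex)
  rep <- screen(msgs_tbl("ako walang gana kumain ngayon"), m)
  # both two-word phrases tie on length; leftmost wins and consumes its span,
  # which also blocks the one-word "gana"
  expect_equal(rep$hits$matched_surface, "walang gana")
  expect_equal(nrow(rep$hits), 1)

  all_mode <- screen(msgs_tbl("ako walang gana kumain ngayon"), m, policy = "all")
  expect_setequal(
    all_mode$hits$matched_surface, c("walang gana", "gana kumain", "gana")
  )
})

test_that("screening equals the naive all-phrases-all-positions oracle", {
  set.seed(21)
  for (trial in 1:3) {
    spec <- fixture_spec(
      seed = 100 + trial, entries_per_category = 3, injection_rate = 1.2,
      n_messages = 25
    )
    toy <- make_toy_lexicon(spec)
    sim <- simulate_messages(toy$lexicon, spec)
    m <- build_matcher(toy$lexicon)
    rep <- screen(sim$messages, m, policy = "all")
    phrases <- all_phrases(toy$lexicon)
    for (i in seq_len(nrow(sim$messages))) {
      mine <- rep$hits[rep$hits$message_id == sim$messages$message_id[i], ]
      mine <- mine[order(mine$start, mine$end, mine$entry_id, mine$matched_surface), ]
      oracle <- oracle_scan(phrases, normalize_text(sim$messages$text[i]))
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$matched_surface, oracle$phrase)
      expect_equal(mine$entry_id, oracle$entry_id)
    }
  }
})

test_that("reports are deterministic and conserve counts", {
  spec <- fixture_spec(seed = 31, injection_rate = 0.8, n_messages = 40)
  toy <- make_toy_lexicon(spec)
  sim <- simulate_messages(toy$lexicon, spec)
  m <- build_matcher(toy$lexicon)
  r1 <- screen(sim$messages, m)
  r2 <- screen(sim$messages, m)
  expect_identical(r1, r2)
  expect_equal(sum(r1$category_counts), nrow(r1$hits))
  expect_lte(r1$n_flagged_categories, 13)
})

test_that("window aggregation uses half-open epoch-aligned windows", {
  m <- build_matcher(tiny_lexicon())
  # all hits within one hour fall into a single 1-h window
  rep <- screen(msgs_tbl(
    c("sad talaga", "i feel worthless", "take my lyf"),
    ts = c("2016-07-20T10:05:00", "2016-07-20T10:20:00", "2016-07-20T10:59:59")
  ), m)
  w <- aggregate_window(rep, "1h")
  expect_equal(length(unique(w$window_start)), 1)
  expect_equal(sum(w$n_hits), nrow(rep$hits))

  # a hit exactly on the boundary goes to the later window
  rep2 <- screen(msgs_tbl(
    c("sad", "sad ulit"),
    ts = c("2016-07-20T10:59:59", "2016-07-20T11:00:00")
  ), m)
  w2 <- aggregate_window(rep2, "1h")
  expect_equal(nrow(w2), 2)
  expect_equal(
    as.numeric(diff(w2$window_start), units = "secs"), 3600
  )

  # conservation over random timestamps
  set.seed(17)
  n <- 30
  rep3 <- screen(msgs_tbl(
    rep("sad na sad", n),
    ts = format(
      as.POSIXct("2016-07-20", tz = "UTC") + stats::runif(n, 0, 7 * 86400),
      "%Y-%m-%dT%H:%M:%S"
    )
  ), m)
  w3 <- aggregate_window(rep3, "24h")
  expect_equal(sum(w3$n_hits), nrow(rep3$hits))

  bad <- screen(msgs_tbl("sad", ids = "bad1", ts = "yesterday"), m)
  expect_error(aggregate_window(bad, "1h"), "bad1")
  expect_error(aggregate_window(rep, "fortnight"), "Window length")
})

test_that("message logs read from tsv and plain formats", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "message_id\ttimestamp\ttext",
    "m1\t2016-07-20T08:00:00\tkumusta ka",
    "m2\t2016-07-20T08:05:00\tsad ako ngayon"
  ), path)
  msgs <- read_messages(path)
  expect_equal(msgs$message_id, c("m1", "m2"))

  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("kumusta", "", "sad ako"), plain)
  p <- read_messages(plain, format = "plain")
  expect_equal(nrow(p), 2)
  expect_true(all(is.na(p$timestamp)))

  writeLines(c("message_id\ttimestamp\ttext", "m1\tonly two"), path)
  expect_error(read_messages(path), "Line 2")
})
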