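test_that("lexicon construction normalizes, deduplicates and validates", {
  lex <- lexicon(tibble::tibble(
    entry_id = c("a", "b", "c"),
    category = c("mood", "sleep", "suicide"),
    surface = c("  SAD  ", "can not  sleep", "take my life"),
    derivatives = list(character(0), character(0), character(0)),
    variations = list(character(0), character(0), character(0)),
    sources = list("focus_group", "focus_group", "expert_interview")
  ))
  expect_s3_class(lex, "lexicon")
  expect_equal(nrow(lex$entries), 3)
  expect_equal(lex$entries$surface, c("sad", "can not sleep", "take my life"))

  # duplicate variations merge with a logged count; surface never kept
  expect_message(
    lex2 <- lexicon(tibble::tibble(
      entry_id = "a", category = "mood", surface = "sad",
      derivatives = list(character(0)),
      variations = list(c("sd", "sd", "SAD")),
      sources = list("focus_group")
    )),
    "Merged 2"
  )
  expect_equal(lex2$entries$variations[[1]], "sd")

  expect_error(
    lexicon(tibble::tibble(
      entry_id = c("a", "a"), category = c("mood", "mood"),
      surface = c("sad", "down")
    )),
    "Duplicate entry_id"
  )
  expect_error(
    lexicon(tibble::tibble(
      entry_id = "a", category = "sadness", surface = "sad"
    )),
    "mood, interest"
  )
  expect_error(
    lexicon(tibble::tibble(entry_id = "a", category = "mood", surface = "  ")),
    "non-empty"
  )
})

test_that("delimited round trip preserves the count summary bit-exactly", {
  lex <- tiny_lexicon()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_identical(count_summary(back), count_summary(lex))
  expect_identical(back$entries$surface, lex$entries$surface)
  expect_identical(back$entries$variations, lex$entries$variations)
})

test_that("malformed lexicon files are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "entry_id\tcategory\tsurface\tderivatives\tvariations\tsources",
    "a\tmood\tsad\t\t\tfocus_group",
    "b\tmood\tonly three fields"
  ), path)
  expect_error(read_lexicon(path), "Line 3")

  writeLines("wrong\theader", path)
  expect_error(read_lexicon(path), "Line 1")
  expect_error(read_lexicon(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("count_summary matches a brute-force recount and ignores order", {
  spec <- fixture_spec(seed = 11, entries_per_category = 3)
  lex <- make_toy_lexicon(spec)$lexicon
  cs <- count_summary(lex)

  # independent full scan over entries
  for (cat_id in category_ids()) {
    rows <- which(lex$entries$category == cat_id)
    expect_equal(cs$main_count[cs$category == cat_id], length(rows))
    expect_equal(
      cs$derivative_count[cs$category == cat_id],
      sum(vapply(rows, function(i) length(lex$entries$derivatives[[i]]), 1L))
    )
    expect_equal(
      cs$variation_count[cs$category == cat_id],
      sum(vapply(rows, function(i) length(lex$entries$variations[[i]]), 1L))
    )
  }
  expect_equal(cs$row_total, cs$main_count + cs$derivative_count + cs$variation_count)
  tot <- cs[cs$category == "total", ]
  expect_equal(tot$main_count, sum(cs$main_count[cs$category != "total"]))

  # invariant under entry reordering
  shuffled <- lexicon(
    lex$entries[rev(seq_len(nrow(lex$entries))), ],
    metadata = lex$metadata
  )
  expect_identical(count_summary(shuffled), cs)
})

test_that("an empty lexicon summarizes to all zeros", {
  lex <- lexicon(tibble::tibble(
    entry_id = character(0), category = character(0), surface = character(0)
  ))
  cs <- count_summary(lex)
  expect_equal(nrow(cs), 14)
  expect_true(all(cs$row_total == 0))
})

test_that("map_category resolves labels in both systems", {
  expect_equal(map_category("Depressed mood", "dsm5"), "mood")
  expect_equal(map_category("Anxiety", "icd10"), "anxiety")
  expect_equal(map_category("Sleep alterations of any kind", "icd10"), "sleep")

  # the shared psychomotor line needs an explicit qualifier
  expect_error(
    map_category("Psychomotor agitation or retardation", "dsm5"),
    "qualifier"
  )
  expect_equal(
    map_category("Psychomotor agitation or retardation", "dsm5",
      qualifier = "retardation"
    ),
    "psychomotor_retardation"
  )
  expect_equal(
    map_category(
      "Changes of psychomotor activity, with agitation or inhibition",
      "icd10",
      qualifier = "agitation"
    ),
    "psychomotor_agitation"
  )

  expect_error(map_category("", "dsm5"), "non-empty")
  expect_error(map_category("Depresed mood", "dsm5"), "Nearest match")
})

test_that("the taxonomy has exactly 13 stable categories", {
  cats <- symptom_categories()
  expect_equal(nrow(cats), 13)
  expect_false(anyDuplicated(cats$id) > 0)
  expect_equal(sum(duplicated(cats$dsm5_label)), 1) # shared psychomotor line
})

test_that("normalize_text lowercases, squishes, keeps emoticons, idempotent", {
  expect_equal(normalize_text("  I'm   Worthless "), "i'm worthless")
  expect_equal(normalize_text(":-("), ":-(")
  expect_equal(normalize_text("I’m sad"), "i'm sad")

  set.seed(42)
  for (i in 1:50) {
    raw <- paste(
      sample(c(LETTERS, letters, " ", "  ", ":-(", "'", "!", "\t"),
        sample(1:20, 1),
        replace = TRUE
      ),
      collapse = ""
    )
    once <- normalize_text(raw)
    expect_identical(normalize_text(once), once)
  }
})
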