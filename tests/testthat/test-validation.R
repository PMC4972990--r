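test_that("cvr implements both the proportion and classic Lawshe formulas", {
  all_e <- rep("essential", 8)
  expect_equal(cvr(all_e), 1.0)
  six_e <- c(rep("E", 6), "U", "N")
  expect_equal(cvr(six_e), 0.75)
  expect_equal(cvr(six_e, "lawshe_classic"), 0.5)
  none <- rep("not_necessary", 8)
  expect_equal(cvr(none, "lawshe_classic"), -1.0)
  expect_equal(cvr(none), 0.0)
  expect_error(cvr(character(0)), "Empty panel")
  expect_error(cvr(c("E", "maybe")), "Unknown rating")

  # both formulas strictly increasing in n_e at fixed N
  for (n in c(5, 8, 11)) {
    prop <- vapply(0:n, function(k) {
      cvr(rep(c("essential", "not_necessary"), c(k, n - k)))
    }, numeric(1))
    lcl <- vapply(0:n, function(k) {
      cvr(rep(c("essential", "not_necessary"), c(k, n - k)), "lawshe_classic")
    }, numeric(1))
    expect_true(all(diff(prop) > 0) && all(prop >= 0 & prop <= 1))
    expect_true(all(diff(lcl) > 0) && all(lcl >= -1 & lcl <= 1))
  }
})

test_that("mean judgment points average the per-rating point awards", {
  expect_equal(mean_judgment_points(rep("essential", 8)), 2.0)
  expect_equal(mean_judgment_points(rep(c("E", "U"), each = 4)), 1.5)
  expect_equal(mean_judgment_points(rep("not_necessary", 5)), 0.0)
  # identity: mean_points = 2 * n_e/N + n_u/N under default points
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    r <- sample(rating_levels(), n, replace = TRUE)
    expect_equal(
      mean_judgment_points(r),
      2 * mean(r == "essential") + mean(r == "useful_not_essential")
    )
  }
})

test_that("retention decisions honor threshold, rescue interval and strictness", {
  cfg <- quiet_config()
  expect_equal(decide_keyword(0.75, 0.0, cfg), "retained_threshold")
  expect_equal(decide_keyword(1.0, 0.0, cfg), "retained_threshold")
  expect_equal(decide_keyword(0.74, 2.0, cfg), "dropped") # outside rescue interval
  expect_equal(decide_keyword(0.5, 1.5, cfg), "dropped") # strict > on points
  expect_equal(decide_keyword(0.5, 1.51, cfg), "retained_rescue")
  expect_equal(decide_keyword(0.0, 1.6, cfg), "retained_rescue") # closed interval
  expect_equal(decide_keyword(-0.25, 1.6, cfg), "dropped")
  no_rescue <- quiet_config(rescue_enabled = FALSE)
  expect_equal(decide_keyword(0.5, 1.9, no_rescue), "dropped")
})

test_that("exhaustive search maps out when the rescue rule can fire", {
  # classic Lawshe CVR + default points: rescue is satisfiable
  lawshe <- validation_config("lawshe_classic")
  feas <- rescue_compositions(lawshe, n_max = 12)
  expect_gt(nrow(feas), 0)
  # every listed composition actually triggers the rescue branch
  for (r in seq_len(nrow(feas))) {
    expect_equal(
      decide_keyword(feas$cvr[r], feas$mean_points[r], lawshe),
      "retained_rescue"
    )
  }
  # witness: 5 essential + 3 useful of 8 -> cvr 0.25, mean points 1.625
  witness <- rep(c("essential", "useful_not_essential"), c(5, 3))
  expect_equal(cvr(witness, "lawshe_classic"), 0.25)
  expect_equal(mean_judgment_points(witness), 1.625)
  expect_true(any(feas$n == 8 & feas$n_essential == 5 & feas$n_useful == 3))

  # proportion CVR + default points: provably vacuous
  # (cvr <= 0.5 forces mean points <= 1 + cvr <= 1.5), so the config warns
  expect_warning(prop <- validation_config("proportion"), "cannot fire")
  expect_equal(nrow(rescue_compositions(prop, n_max = 12)), 0)

  # essential-only points: vacuous under both formulas, with a warning
  eo <- c(essential = 2, useful_not_essential = 0, not_necessary = 0)
  expect_warning(validation_config("proportion", points = eo), "cannot fire")
  expect_warning(eo_cfg <- validation_config("lawshe_classic", points = eo), "cannot fire")
  expect_equal(nrow(rescue_compositions(eo_cfg, n_max = 12)), 0)

  # disabling rescue silences the satisfiability warning
  expect_no_warning(validation_config("proportion", rescue_enabled = FALSE))
})

test_that("rating tables require a complete panel and round-trip through files", {
  good <- expand.grid(
    entry_id = c("a", "b"), rater_id = c("r1", "r2", "r3"),
    stringsAsFactors = FALSE
  )
  good$rating <- "E"
  rt <- rating_table(good)
  expect_equal(length(rt$panel), 3)

  expect_error(rating_table(good[-1, ]), "Incomplete panel")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratings(rt, path)
  back <- read_ratings(path)
  expect_setequal(back$panel, rt$panel)
  expect_equal(nrow(back$ratings), 6)
  expect_true(all(back$ratings$rating == "essential"))
})

test_that("validate_lexicon drops entries with their derivatives and variations", {
  lex <- tiny_lexicon()
  # kw_guilt unanimous essential, kw_suicide 6/8, kw_mood 2/8 (dropped)
  panel <- sprintf("r%d", 1:8)
  ratings <- rbind(
    data.frame(entry_id = "kw_guilt", rater_id = panel, rating = "E"),
    data.frame(
      entry_id = "kw_suicide", rater_id = panel,
      rating = rep(c("E", "U"), c(6, 2))
    ),
    data.frame(
      entry_id = "kw_mood", rater_id = panel,
      rating = rep(c("E", "N"), c(2, 6))
    )
  )
  res <- validate_lexicon(lex, rating_table(ratings), quiet_config())
  expect_equal(
    res$keyword_results$decision,
    c("retained_threshold", "retained_threshold", "dropped")
  )
  expect_equal(nrow(res$retained$entries), 2)
  expect_false("kw_mood" %in% res$retained$entries$entry_id)
  cs <- count_summary(res$retained)
  expect_equal(cs$variation_count[cs$category == "mood"], 0L) # variations gone too
  expect_equal(res$cvi, mean(c(1, 0.75)))
  summ <- res$category_summary
  expect_equal(summ$mean_cvr[summ$category == "guilt_self_esteem"], 1.0)
  expect_true(is.na(summ$mean_cvr[summ$category == "mood"]))

  expect_error(
    validate_lexicon(
      lex, rating_table(ratings[ratings$entry_id != "kw_mood", ]),
      quiet_config()
    ),
    "kw_mood"
  )
})

test_that("an all-essential panel retains everything with CVI 1, order-invariantly", {
  spec <- fixture_spec(seed = 5, essential_probability = 1)
  toy <- make_toy_lexicon(spec)
  rt <- simulate_ratings(toy$lexicon, spec)
  res <- validate_lexicon(toy$lexicon, rt, quiet_config())
  expect_equal(res$cvi, 1.0)
  expect_true(all(res$keyword_results$decision == "retained_threshold"))
  expect_equal(nrow(res$retained$entries), nrow(toy$lexicon$entries))

  shuffled <- lexicon(
    toy$lexicon$entries[rev(seq_len(nrow(toy$lexicon$entries))), ],
    metadata = toy$lexicon$metadata
  )
  res2 <- validate_lexicon(shuffled, rt, quiet_config())
  expect_equal(res2$cvi, res$cvi)
})
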