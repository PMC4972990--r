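# lexiscreen

Toolkit for building, validating, and applying **symptom lexicons for
depression screening in short text messages**.

Mobile messaging offers a route to ecological momentary assessment of mood:
the words a person types — "i feel worthless", "can't sleep", "tke my lyf",
":-(" — carry signal about depressive symptomatology, and a content-validated
lexicon lets an app tally that signal per symptom, without diagnosing.
`lexiscreen` implements the full pipeline such a lexicon goes through, for
researchers in mental-health text analytics and psychometrics:

1. **Taxonomy** — 13 symptom categories anchored row-for-row in the DSM-5 and
   ICD-10 depressive-episode criteria (mood, interest, appetite/weight, sleep,
   psychomotor agitation, psychomotor retardation, fatigue, guilt/self-esteem,
   concentration, suicide, anxiety, alcohol/substance use, histrionic
   behavior), with `map_category()` to resolve classification-system wording.
2. **Lexicon model** — entries of a main keyword with enumerated derivatives
   (tense/word-order variants) and spelling variations (textspeak), one
   category each; delimited IO; `count_summary()` per-category count tables.
3. **Variant expansion** — the combinatorial rule that grows textspeak
   variation lists: each word of a multi-word keyword may independently be
   replaced by any of its spelling variants, so a phrase with per-word variant
   counts v_1..v_k yields prod(1 + v_i) − 1 variations (`expand_keyword()`,
   closed form `expansion_count()`, heuristic `apply_textspeak_rules()`).
4. **Expert content validation** — Lawshe-style panel validation. For each
   keyword the content validity ratio is CVR = n_e / N (the proportion of the
   N experts rating it "essential"; the classic (n_e − N/2)/(N/2) form is also
   available); keywords with CVR ≥ 0.75 are retained; a keyword with CVR in
   [0, 0.5] may still be rescued when its mean judgment points (2 per
   "essential", 1 per "useful but not essential") strictly exceed 1.5; the
   content validity index CVI is the mean CVR of retained keywords.
   `rescue_compositions()` searches all panel compositions exhaustively to
   document when the rescue rule can actually fire.
5. **Screening engine** — exact multi-phrase matching on normalized text at
   word boundaries (emoticons match as words), longest-then-leftmost overlap
   resolution, per-category tallies and time-window summaries.
6. **Synthetic fixtures** — seeded toy lexica, complete rating panels, and
   message streams with exact ground-truth keyword injections, so the whole
   pipeline is testable end to end without any unpublished lexicon data.

## Worked example

```r
library(lexiscreen)

lex <- lexicon(tibble::tibble(
  entry_id    = c("kw1", "kw2"),
  category    = c("guilt_self_esteem", "suicide"),
  surface     = c("i am worthless", "take my life"),
  derivatives = list("i feel worthless", character(0)),
  variations  = list(c("im wrthless", "i am worthlss"),
                     c("tke my life", "take my lyf")),
  sources     = list("expert_interview", "expert_interview")
))
lex
#> <lexicon> unnamed: 2 entries | 2 main keywords, 1 derivatives, 4 spelling variations (7 keywords in total)

# 8-expert content validation: kw1 gets 7 "essential" + 1 "useful", kw2 is unanimous
panel <- sprintf("r%d", 1:8)
ratings <- rating_table(rbind(
  data.frame(entry_id = "kw1", rater_id = panel, rating = rep(c("E", "U"), c(7, 1))),
  data.frame(entry_id = "kw2", rater_id = panel, rating = "E")
))
res <- validate_lexicon(lex, ratings, validation_config(rescue_enabled = FALSE))
res
#> <validation_result> 2 keywords rated, 2 retained (0 by rescue); CVI = 0.94
```

Both keywords clear the CVR ≥ 0.75 threshold (kw1 at 7/8 = 0.875, kw2 at
1.0), and the CVI is their mean, 0.94. Screening a message stream against the
retained lexicon:

```r
msgs <- tibble::tibble(
  message_id = c("m1", "m2"),
  timestamp  = c("2016-07-20T10:05:00", "2016-07-20T22:40:00"),
  text       = c("Lord please tke my life", "im wrthless talaga :-(")
)
rep <- screen(msgs, build_matcher(res$retained))
rep$hits
#> # A tibble: 2 × 6
#>   message_id start   end matched_surface entry_id category
#>   <chr>      <int> <int> <chr>           <chr>    <chr>
#> 1 m1            12    23 tke my life     kw2      suicide
#> 2 m2             0    11 im wrthless     kw1      guilt_self_esteem
aggregate_window(rep, "24h")
#> # A tibble: 2 × 3
#>   window_start        category          n_hits
#>   <dttm>              <chr>              <int>
#> 1 2016-07-20 00:00:00 guilt_self_esteem      1
#> 2 2016-07-20 00:00:00 suicide                1
```

Each textspeak variation fires for its parent keyword's category, with
0-based half-open offsets into the normalized text; the window summary counts
both hits in the same 24-hour window. The raw tallies are screening support
only — the package deliberately draws no diagnostic threshold.

A shell interface with `stats`, `expand`, `validate`, `screen` and `simulate`
subcommands ships in `inst/scripts/lexiscreen`:

```sh
Rscript inst/scripts/lexiscreen simulate --seed 7 --out-dir fixtures/
Rscript inst/scripts/lexiscreen stats fixtures/lexicon.tsv
```

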