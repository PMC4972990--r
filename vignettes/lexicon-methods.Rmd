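---
title: "Methods: lexicon construction, content validation, and text screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon construction, content validation, and text screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexiscreen)
```

## The screening model

`lexiscreen` implements lexicon-based symptom screening: a curated dictionary
of depressive expressions is matched exactly against message text, and hits
are tallied per symptom category. The underlying assumption is that word
choice leaks mental state — a person preoccupied with worthlessness types
"i am worthless", "im wrthless", "wala akong kwenta" — so the coverage
problem is moved entirely into the lexicon: rather than fuzzy-matching or
stemming at query time, every tense variant, word-order variant and
textspeak spelling is *enumerated* as lexicon data. This matters for the
target population (young, code-switching Filipino texters) whose
abbreviation-heavy style would defeat any matcher built for dictionary
spellings. The engine is therefore deliberately exact; all generalisation
happens when the lexicon is built.

The output is a per-category hit tally, nothing more. No cutoff converts
tallies into a depression flag: the method is screening support for a
clinician or counselor, not a diagnostic instrument, and publishing a
threshold the data cannot support would invite misuse.

## The 13-category taxonomy

Categories mirror the depressive-episode symptom lists of DSM-5 and ICD-10:
nine core symptoms plus three associated features (anxiety, alcohol and
substance use, histrionic behavior). Psychomotor agitation and retardation
are distinct categories even though both classification systems describe
them in one shared line ("Psychomotor agitation or retardation"); the two
symptoms are behaviorally opposite, and merging them would make the tallies
clinically useless. The shared wording is why `map_category()` refuses to
guess for that line and requires an explicit `qualifier` argument.

Each keyword entry belongs to exactly one category. This is a modeling
choice with an arithmetic consequence: per-category count tables are plain
sums, and their grand totals equal the column sums — an invariant
`count_summary()` enforces and the tests check. Allowing multi-category
entries would break that additivity and double-count hits.

## Lexicon counts

An entry is a *main keyword* (its normalized surface), a set of
*derivatives* (enumerated tense/word-order variants, not stemmer output),
and a set of *spelling variations* (textspeak forms). `count_summary()`
reports main/derivative/variation counts per category plus row and grand
totals. For published lexica where only the count tables survive (the raw
keyword lists being unpublished and, for a clinical instrument, deliberately
so), `stub_lexicon()` materialises synthetic placeholder entries realizing a
given count table, so the count arithmetic itself — row totals, column sums,
grand totals — can be verified by actually recounting a lexicon object
rather than by re-adding the printed numbers.

## The variant-expansion rule

Spelling variations of a multi-word keyword are generated combinatorially:
each word contributes an option set (itself plus its collected variants),
and the variation list is the Cartesian product over words, minus the
unmodified phrase. With per-word variant counts $v_1, \dots, v_k$ the count
is

$$\prod_{i=1}^{k}(1 + v_i) - 1,$$

computed in closed form by `expansion_count()` and by construction equal to
`length(expand_keyword(...))`. Two design points:

* **Cross-word contractions.** Filipino/English texting merges spans:
  "can not" becomes "cant" or "cnt". The variant map therefore allows
  multi-word keys whose variants replace the whole span; keys are consumed
  greedily left-to-right, longest first, before per-word expansion. Variants
  themselves must be single tokens — the validity check enforces this, which
  is also what guarantees the closed-form count equals the realized set size
  (multi-token variants could collide after joining).
* **Originals excluded.** The unmodified phrase is not a variation of
  itself; count tables keep main keywords and variations in separate
  columns. A flag (`include_original`) exists for callers who want the full
  closed product.

`apply_textspeak_rules()` provides a small deterministic rule set
(internal-vowel dropping, terminal "ing" → "in", "to" → "2", i → y with
dropped trailing e) for building fixture variant maps. It mimics the *shape*
of collected variants ("stop" → "stp", "life" → "lyf", "crying" → "cryin");
real lexica should use variants elicited from actual texters, which no rule
set reproduces.

The per-keyword product is capped (`max_output`, default $10^6$) with an
explicit overflow error rather than silent truncation: a runaway product is
almost always a variant-map data error, and truncating it would silently
bias the lexicon.

## Expert content validation

Each of $N$ panel experts rates each keyword "essential", "useful but not
essential", or "not necessary". Two CVR definitions are offered:

* `proportion` (default): $\mathrm{CVR} = n_e / N$, the plain ratio of
  "essential" ratings, in $[0, 1]$. Under this reading a 0.75 threshold for
  an 8-expert panel means 6 of 8 — which is the arithmetic that makes a
  0.75 cutoff sensible for $N = 8$.
* `lawshe_classic`: $\mathrm{CVR} = (n_e - N/2)/(N/2)$, in $[-1, 1]$.

A keyword is retained outright when $\mathrm{CVR} \ge 0.75$ (boundary
inclusive). Keywords below threshold may be *rescued*: if
$\mathrm{CVR} \in [0, 0.5]$ (closed interval) and the mean of judgment
points strictly exceeds 1.5, the keyword is kept. Judgment points default to
2 per "essential", 1 per "useful but not essential", 0 per "not necessary".
The 1-point award for the middle level is a deliberate choice: with points
awarded only for "essential" ratings, mean points $> 1.5$ forces
$n_e/N > 0.75$, placing the keyword above the retention threshold and
outside the rescue interval — the rescue rule could never fire.

The rescue rule's satisfiability is subtler than it looks, so the package
settles it by exhaustive enumeration rather than argument.
`rescue_compositions()` enumerates every panel composition
$(n_e, n_u, n_n)$ for all $N$ up to a bound (default 12) and returns the
compositions that trigger rescue. The search shows:

* Under the **proportion** formula with default points, rescue is vacuous:
  $\mathrm{CVR} = n_e/N \le 0.5$ bounds the mean points by
  $2 n_e/N + (N - n_e)/N = 1 + n_e/N \le 1.5$, never strictly above it.
* Under the **classic Lawshe** formula with default points, rescue is
  satisfiable: $\mathrm{CVR} \in [0, 0.5]$ means $n_e/N \in [0.5, 0.75]$,
  e.g. 5 essential + 3 useful of 8 gives $\mathrm{CVR} = 0.25$ and mean
  points 1.625.
* With essential-only points, rescue is vacuous under both formulas.

Because a user can configure a rescue rule that provably cannot fire,
`validation_config()` runs this search at construction time and warns when
the configured formula and point scheme make rescue unsatisfiable — silence
would let a vacuous "safety net" masquerade as a working one. Disabling the
rescue suppresses the check.

Dropped keywords take their derivatives and spelling variations with them:
panels rate main keywords, and nothing in the procedure rates variant
spellings separately, so variants inherit the parent's decision. Per
category the summary reports the mean CVR of *retained* keywords (averaging
over all keywords would mix in the rejected ones the final lexicon no longer
contains), and the CVI is the mean CVR of all retained keywords. Report
display rounds CVR/CVI to 2 decimals; computations are unrounded.

## Frequency summaries

`frequency_summary()` reproduces the two conventions of survey/scale-review
tables: percentages to 1 decimal with cumulative percentages to 2 decimals,
or whole percents for both. Cumulative values are accumulated on *unrounded*
percentages and rounded last, so the column is nondecreasing and terminates
at exactly 100 regardless of how the per-row roundings fall. Rows sort by
descending count with ties keeping input order, which keeps the summary
deterministic for equal counts.

## Matching semantics

All matching happens on normalized text: lowercased, whitespace-squished,
curly apostrophes mapped to ASCII. Emoticon glyphs are preserved — ":-(" is
lexicon-worthy affective signal.

A phrase matches where its exact normalized string occurs flanked by
non-word characters or the string edges; word characters are alphanumerics
plus the apostrophe. So "sad" does not fire inside "sadness", "i'm" is one
word, and ":-(" matches as a word of its own between spaces. One known
consequence of applying the flanking rule uniformly: a word character
immediately before an emoticon blocks the match ("sad:-(" does not contain a
match of ":-(" because its left neighbour is "d"). Messages normally
separate emoticons with whitespace; tightening this for glued emoticons
would complicate the boundary rule for every phrase class and is left as a
documented limitation.

The matcher indexes phrases by first word (or first glyph for
punctuation-initial phrases) and verifies candidates by substring
comparison, so behavior is independent of entry insertion order. Overlapping
candidates are resolved longest-match-first, then leftmost, with accepted
spans consumed — "walang gana" suppresses the inner "gana", and a span
shared by two entries yields exactly one hit (ties broken by entry id for
determinism). An `"all"` policy returns every candidate occurrence; that
mode is what the test suite compares against a naive
every-phrase-at-every-position scan, keeping the production matcher and the
oracle genuinely different algorithms.

Time-window summaries assign each hit to the epoch-aligned window containing
its message timestamp, half-open on the right, so boundary instants go to
the later window and window totals always conserve the overall tally.

## The synthetic-data generator

`fixture_spec()` fixes the simulated study conditions; the defaults are the
conditions the rest of the package is exercised under, not tuning knobs:

* **Panel of 8 experts**, the panel size for which the 0.75 retention
  threshold is calibrated.
* **Essential probability 0.9** per entry: simulated panels then produce
  mean proportion-CVRs near 0.9, the level observed for content-validated
  depressive keyword sets.
* **Messages of 5–15 words** with **Poisson(0.5) injected keyword
  occurrences** per message by default: short EMA-style texts in which
  symptom expressions are present but not dominant.
* **Keywords of 1–3 words, up to 2 textspeak variants per word**, generated
  by the deterministic rule set.

Keyword surfaces are built from pseudo-words unique to each entry, and the
filler vocabulary (neutral English/Filipino words) is checked disjoint from
every lexicon token at generation time. Injections are separated by at least
one filler token. Together these guarantee the recorded ground truth is
*exact*: every injected occurrence is recoverable and nothing else can
match, so the end-to-end recovery test expects equality, not a rate. All
randomness derives from one master seed through labelled sub-streams, so the
lexicon, ratings and messages are reproducible independently.

What the generator does **not** emulate: real Filipino morphology,
code-switch grammar, topic drift, ambiguous polysemous keywords, or
lexicon phrases that overlap each other's vocabulary. Passing tests
establish that the machinery is correct (counting, expansion arithmetic,
panel math, exact matching, conservation), not that the lexicon content
screens real populations well — that is what expert validation and field
trials of an actual lexicon are for.

## Problem sizes and numerical choices

The test suite runs the expansion oracle on 1000 random phrase/variant-map
instances (plus 200 in the unit tests), compares matcher output against the
naive scan on 30-message streams over ~40-entry lexica across multiple
seeds, sweeps 4 essential-probability levels over 104-entry lexica for the
monotonicity property, and enumerates all rescue panel compositions to
N = 12 (455 compositions at N = 12 alone; the sweep over all N ≤ 12 is a few
thousand evaluations). These sizes were chosen to exercise every code path
with comfortable margins while keeping the default suite under a minute.

Rounding uses R's `round()` (banker's rounding); none of the reported
quantities sits on a half-ULP boundary where the convention matters.
Counts are kept as integers throughout; expansion counts use doubles to
represent products beyond integer range before the overflow check.

## Known limitations

* Exact matching cannot catch spellings absent from the lexicon; coverage is
  a data problem by design.
* The flanking rule misses emoticons glued to a preceding word (above).
* Derivatives are enumerated data; no stemmer ships, so morphological
  coverage is only as good as the enumeration.
* `validate_lexicon()` requires complete panels; missing ratings are an
  error, not an imputation problem this package solves.
* Hit tallies are reported raw; any mapping from tallies to clinical action
  is out of scope.
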