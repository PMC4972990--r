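#' Published per-category keyword counts of the Filipino depression lexicon
#'
#' Per-category counts of main keywords, derivatives and spelling variations
#' reported for the Filipino/Taglish depression lexicon, at two stages:
#' `"draft"` (all keywords gathered from focus groups, expert interviews,
#' scale review and researcher-extended spelling variants) and `"validated"`
#' (the test-run version remaining after expert content validation at the
#' CVR >= 0.75 retention threshold). The raw keyword lists themselves were
#' never published; these counts are the reproducible summary of the lexicon
#' and serve as input to count-arithmetic checks via [stub_lexicon()].
#'
#' @param stage `"draft"` or `"validated"`.
#' @return A tibble with columns `category`, `main_count`,
#'   `derivative_count`, `variation_count`.
#' @examples
#' count_summary(stub_lexicon(reference_category_counts("draft")))
#' @export
reference_category_counts <- function(stage = c("draft", "validated")) {
  stage <- match.arg(stage)
  draft <- tibble::tribble(
    ~category, ~main_count, ~derivative_count, ~variation_count,
    "mood", 241L, 1582L, 63340L,
    "interest", 129L, 1035L, 107417L,
    "appetite_weight", 216L, 1357L, 19032L,
    "sleep", 162L, 786L, 187365L,
    "psychomotor_agitation", 174L, 750L, 12957L,
    "psychomotor_retardation", 74L, 431L, 16160L,
    "fatigue", 112L, 424L, 14964L,
    "guilt_self_esteem", 180L, 1000L, 30067L,
    "concentration", 165L, 753L, 239291L,
    "suicide", 90L, 635L, 58732L,
    "alcohol_substance", 63L, 315L, 20875L,
    "anxiety", 112L, 399L, 45251L,
    "histrionic", 44L, 188L, 8418L
  )
  validated <- tibble::tribble(
    ~category, ~main_count, ~derivative_count, ~variation_count,
    "mood", 181L, 1375L, 52130L,
    "interest", 113L, 1011L, 102081L,
    "appetite_weight", 213L, 1353L, 19018L,
    "sleep", 148L, 743L, 183123L,
    "psychomotor_agitation", 129L, 544L, 8993L,
    "psychomotor_retardation", 51L, 366L, 12578L,
    "fatigue", 103L, 420L, 15080L,
    "guilt_self_esteem", 173L, 984L, 29837L,
    "concentration", 135L, 668L, 229375L,
    "suicide", 86L, 612L, 58355L,
    "alcohol_substance", 53L, 315L, 20760L,
    "anxiety", 82L, 359L, 44065L,
    "histrionic", 31L, 165L, 7745L
  )
  if (stage == "draft") draft else validated
}

#' Published per-category content validity ratios
#'
#' Mean content validity ratio (CVR) per symptom category from the 8-expert
#' content-validation panel of the Filipino depression lexicon. The content
#' validity index (CVI) of the lexicon is the mean of the per-keyword CVRs;
#' at category resolution it is recovered as the unweighted mean of these 13
#' values.
#'
#' @return A tibble with columns `category` and `cvr`.
#' @examples
#' round(mean(reference_category_cvr()$cvr), 2)
#' @export
reference_category_cvr <- function() {
  tibble::tribble(
    ~category, ~cvr,
    "mood", 0.86,
    "interest", 0.93,
    "appetite_weight", 0.98,
    "sleep", 0.92,
    "psychomotor_agitation", 0.78,
    "psychomotor_retardation", 0.80,
    "fatigue", 0.89,
    "guilt_self_esteem", 0.94,
    "concentration", 0.93,
    "suicide", 0.97,
    "alcohol_substance", 0.91,
    "anxiety", 0.89,
    "histrionic", 0.92
  )
}

#' Published keyword-frequency counts from the depression-scale review
#'
#' Frequencies of depressive-symptom keywords extracted from 18 established
#' depression and related-construct scales (N = 449 keywords), by symptom.
#' Input for [frequency_summary()] in its 2-decimal mode.
#'
#' @return A named integer vector (symptom label -> count), in the published
#'   descending-frequency order.
#' @export
reference_scale_frequencies <- function() {
  c(
    "Feelings of guilt and low self-esteem" = 148L,
    "Depressed mood" = 103L,
    "Loss of interest or pleasure" = 40L,
    "Anxiety" = 35L,
    "Psychomotor agitation" = 27L,
    "Fatigue" = 23L,
    "Increase or decrease in appetite or weight" = 20L,
    "Diminished concentration" = 17L,
    "Sleep problems" = 15L,
    "Suicidal thoughts and behavior" = 12L,
    "Psychomotor retardation" = 8L,
    "Histrionic behavior" = 1L,
    "Consumption of alcohol" = 0L
  )
}

#' Published focus-group description counts
#'
#' Counts of response themes describing the experience of depression from
#' focus-group discussions with college students (N = 78 responses). Input
#' for [frequency_summary()] in its integer-percent mode.
#'
#' @return A named integer vector (theme -> count).
#' @export
reference_focus_group_descriptions <- function() {
  c(
    "Sad; lonely; unhappy" = 21L,
    "No focus; disturbed" = 11L,
    "Isolation; lack of interest; low interaction" = 7L,
    "Sleep problems" = 7L,
    "Hopelessness; loss of meaning in life" = 6L,
    "Fatigue; stressed" = 5L,
    "Pessimism" = 4L,
    "Uneasiness; instability" = 4L,
    "Moody" = 3L,
    "Emotional" = 2L,
    "Eating problems" = 2L,
    "Low self-esteem" = 2L,
    "Suicidal" = 1L,
    "Anxiety" = 1L,
    "Have no emotional support" = 1L,
    "Pretending to be happy" = 1L
  )
}
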