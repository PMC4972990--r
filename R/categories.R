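#' The 13-category depressive-symptom taxonomy
#'
#' Depressive-episode symptoms listed in the DSM-5 and in the ICD-10 clinical
#' descriptions are organised into 13 lexicon categories: the nine core
#' episode symptoms (with psychomotor agitation and retardation kept as
#' separate categories even though the two classification systems describe
#' them in a single shared line) plus the associated features anxiety,
#' alcohol/substance use and histrionic behavior.
#'
#' @return A tibble with columns `id` (stable category token), `label`
#'   (human-readable category name), `dsm5_label` and `icd10_label` (the
#'   symptom wording in each classification system).
#' @examples
#' symptom_categories()
#' @export
symptom_categories <- function() {
  tibble::tribble(
    ~id, ~label, ~dsm5_label, ~icd10_label,
    "mood", "Mood",
    "Depressed mood",
    "Clearly abnormal depressive mood",
    "interest", "Interest",
    "Markedly diminished interest or pleasure in all or almost all activities",
    "Marked loss of interest or ability to enjoy activities that were previously pleasurable",
    "appetite_weight", "Appetite and weight",
    "Significant weight loss or gain, or increase or decrease in appetite",
    "Changes of appetite (decrease or increase), with the corresponding weight change",
    "sleep", "Sleep",
    "Sleep problems",
    "Sleep alterations of any kind",
    "psychomotor_agitation", "Psychomotor agitation",
    "Psychomotor agitation or retardation",
    "Changes of psychomotor activity, with agitation or inhibition",
    "psychomotor_retardation", "Psychomotor retardation",
    "Psychomotor agitation or retardation",
    "Changes of psychomotor activity, with agitation or inhibition",
    "fatigue", "Fatigue",
    "Fatigue or loss of energy",
    "Lack of vitality or increase of fatigability",
    "guilt_self_esteem", "Guilt and self-esteem",
    "Feelings of guilt, worthlessness, negative self-appraisal",
    "Disproportionate self-reproaches and feelings of excessive guilt or inadequacy; loss of confidence and self-esteem and feelings of inferiority",
    "concentration", "Concentration",
    "Diminished concentration or indecisiveness",
    "Complaints about or decrease of the ability to concentrate and think, accompanied by a lack of decision and vacillation",
    "suicide", "Suicide",
    "Recurrent thoughts of death or suicidal ideation",
    "Recurrent thoughts of death or suicide or any suicidal behavior",
    "anxiety", "Anxiety",
    "Anxiety",
    "Anxiety",
    "alcohol_substance", "Alcohol and substance use",
    "Substance abuse",
    "Excessive consumption of alcohol",
    "histrionic", "Histrionic behavior",
    "Histrionic behavior",
    "Histrionic behavior"
  )
}

#' Category ids in canonical order
#'
#' @return Character vector of the 13 category ids.
#' @export
category_ids <- function() {
  symptom_categories()$id
}

check_category <- function(category) {
  ids <- category_ids()
  bad <- setdiff(unique(category), ids)
  if (length(bad) > 0) {
    abort_input(c(
      sprintf("Unknown category token(s): %s.", paste(bad, collapse = ", ")),
      i = sprintf("Valid ids: %s.", paste(ids, collapse = ", "))
    ))
  }
  invisible(category)
}

#' Map a classification-system symptom label to its category
#'
#' Looks up a DSM-5 or ICD-10 symptom wording (case-insensitive, whitespace
#' tolerant) and returns the owning category id. The psychomotor symptom line
#' is shared verbatim between the agitation and retardation categories in both
#' systems, so for those labels an explicit `qualifier` ("agitation" or
#' "retardation") must be supplied rather than letting the function guess.
#'
#' @param label Symptom wording as printed in the classification system.
#' @param system `"dsm5"` or `"icd10"`.
#' @param qualifier Optional disambiguator for the shared psychomotor line.
#' @return A single category id.
#' @examples
#' map_category("Depressed mood", "dsm5")
#' map_category("Anxiety", "icd10")
#' map_category("Psychomotor agitation or retardation", "dsm5",
#'   qualifier = "agitation"
#' )
#' @export
map_category <- function(label, system = c("dsm5", "icd10"), qualifier = NULL) {
  system <- match.arg(system)
  if (!is.character(label) || length(label) != 1 || !nzchar(normalize_text(label))) {
    abort_input("`label` must be a single non-empty string.")
  }
  cats <- symptom_categories()
  col <- if (system == "dsm5") cats$dsm5_label else cats$icd10_label
  key <- normalize_text(label)
  hits <- which(normalize_text(col) == key)
  if (length(hits) == 0) {
    dists <- utils::adist(key, normalize_text(col))[1, ]
    near <- col[which.min(dists)]
    abort_input(c(
      sprintf("Label %s matches no %s symptom wording.", dQuote(label), toupper(system)),
      i = sprintf("Nearest match: %s.", dQuote(near))
    ))
  }
  if (length(hits) > 1) {
    if (is.null(qualifier)) {
      abort_input(c(
        sprintf(
          "Label %s is shared by categories: %s.",
          dQuote(label), paste(cats$id[hits], collapse = ", ")
        ),
        i = "Supply `qualifier` (\"agitation\" or \"retardation\") to disambiguate."
      ))
    }
    qualifier <- match.arg(qualifier, c("agitation", "retardation"))
    hits <- hits[grepl(qualifier, cats$id[hits], fixed = TRUE)]
    if (length(hits) != 1) {
      abort_input("`qualifier` does not select one of the candidate categories.")
    }
  }
  cats$id[hits]
}
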