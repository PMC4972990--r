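#' Frequency / percentage / cumulative-percentage summary
#'
#' Summarises an ordered mapping of labels to non-negative counts as a
#' frequency table in descending count order (ties keep input order). Two
#' display modes are provided, matching the two conventions used in survey
#' and scale-review reporting: `"decimal"` prints percentages to 1 decimal
#' place and cumulative percentages to 2 decimal places; `"integer"` rounds
#' both to whole percent. In both modes the cumulative column is computed
#' from unrounded percentages and then rounded, so its final value is exactly
#' 100 (printed `100.00` in decimal mode).
#'
#' @param counts Named non-negative numeric vector (label -> count) with at
#'   least one positive count.
#' @param mode `"decimal"` (default) or `"integer"`.
#' @return A tibble with columns `label`, `count`, `percent`,
#'   `cumulative_percent`, in descending count order.
#' @examples
#' frequency_summary(c(a = 21, b = 11), mode = "integer")
#' @export
frequency_summary <- function(counts, mode = c("decimal", "integer")) {
  mode <- match.arg(mode)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort_input("`counts` must be a fully named vector.")
  }
  if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort_input("`counts` must contain non-negative integers.")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort_input("`counts` must contain at least one positive count.")
  }
  ord <- order(-counts)  # stable: ties keep input order
  counts <- counts[ord]
  pct_raw <- 100 * counts / total
  cum_raw <- cumsum(pct_raw)
  if (mode == "decimal") {
    percent <- round(pct_raw, 1)
    cumulative <- round(cum_raw, 2)
  } else {
    percent <- round(pct_raw)
    cumulative <- round(cum_raw)
  }
  tibble::tibble(
    label = names(counts),
    count = as.integer(unname(counts)),
    percent = unname(percent),
    cumulative_percent = unname(cumulative)
  )
}
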