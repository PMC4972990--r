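#' Rating levels used in expert content validation
#'
#' Experts rate each keyword on the three-level Lawshe scale: "essential",
#' "useful but not essential", or "not necessary". File IO also accepts the
#' single-letter tokens E / U / N.
#'
#' @return Character vector of the three canonical level tokens.
#' @export
rating_levels <- function() {
  c("essential", "useful_not_essential", "not_necessary")
}

canonical_rating <- function(x) {
  x <- tolower(trimws(as.character(x)))
  map <- c(
    e = "essential", u = "useful_not_essential", n = "not_necessary",
    essential = "essential",
    useful_not_essential = "useful_not_essential",
    not_necessary = "not_necessary"
  )
  out <- unname(map[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort_input(sprintf(
      "Unknown rating token(s): %s (expected %s or E/U/N).",
      paste(bad, collapse = ", "), paste(rating_levels(), collapse = ", ")
    ))
  }
  out
}

#' Construct an expert rating table
#'
#' Holds one rating per (keyword entry, rater) pair over a complete panel:
#' every entry must be rated exactly once by every rater.
#'
#' @param ratings Data frame with columns `entry_id`, `rater_id`, `rating`
#'   (canonical tokens or E/U/N).
#' @return An object of class `"rating_table"` with fields `ratings`
#'   (tibble) and `panel` (ordered rater ids).
#' @export
rating_table <- function(ratings) {
  if (!is.data.frame(ratings)) abort_input("`ratings` must be a data frame.")
  need <- c("entry_id", "rater_id", "rating")
  if (!all(need %in% names(ratings))) {
    abort_input("`ratings` needs columns entry_id, rater_id, rating.")
  }
  ratings <- tibble::tibble(
    entry_id = as.character(ratings$entry_id),
    rater_id = as.character(ratings$rater_id),
    rating = canonical_rating(ratings$rating)
  )
  panel <- unique(ratings$rater_id)
  entries <- unique(ratings$entry_id)
  tab <- table(ratings$entry_id, ratings$rater_id)
  if (any(tab != 1)) {
    abort_validation(
      "Incomplete panel: every entry needs exactly one rating from every rater."
    )
  }
  structure(
    list(ratings = ratings, panel = panel, entries = entries),
    class = "rating_table"
  )
}

#' Read expert ratings from a delimited file
#'
#' Tab-separated UTF-8 with header `entry_id`, `rater_id`, `rating`; rating
#' tokens may be canonical or E/U/N.
#'
#' @param path File path.
#' @return A [rating_table()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Ratings file not found: %s.", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2) abort_input("Ratings file has no data rows.")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("entry_id", "rater_id", "rating"))) {
    abort_input("Line 1: header must be entry_id\trater_id\trating.")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    abort_input(sprintf("Line %d: expected 3 tab-separated fields.", bad[1] + 1L))
  }
  mat <- do.call(rbind, fields)
  rating_table(tibble::tibble(
    entry_id = mat[, 1], rater_id = mat[, 2], rating = mat[, 3]
  ))
}

#' Write a rating table to the delimited format
#' @param table A [rating_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path) {
  if (!inherits(table, "rating_table")) abort_input("Expected a `rating_table`.")
  r <- table$ratings
  writeLines(
    c(
      "entry_id\trater_id\trating",
      sprintf("%s\t%s\t%s", r$entry_id, r$rater_id, r$rating)
    ),
    path,
    useBytes = TRUE
  )
  invisible(path)
}

#' Content-validation configuration
#'
#' Controls the retention decision. `cvr_formula = "proportion"` computes the
#' CVR as the plain ratio of "essential" ratings to panel size (the reading
#' under which a 0.75 threshold for an 8-expert panel means 6 of 8);
#' `"lawshe_classic"` computes Lawshe's `(n_e - N/2) / (N/2)`. Keywords with
#' CVR below the threshold may still be rescued: if the CVR lies in the
#' closed interval `[rescue_cvr_low, rescue_cvr_high]` and the mean of
#' judgment points (default 2 per "essential", 1 per "useful but not
#' essential", 0 per "not necessary") strictly exceeds `rescue_mean_points`,
#' the keyword is retained.
#'
#' On construction the rescue rule is checked for satisfiability by
#' exhaustive search over all panel compositions up to `feasibility_n_max`
#' raters; if no composition can trigger it under the chosen formula and
#' point scheme (for instance with points awarded only for "essential"
#' ratings, where mean points > 1.5 forces the CVR above the rescue
#' interval), a configuration warning is emitted.
#'
#' @param cvr_formula `"proportion"` or `"lawshe_classic"`.
#' @param cvr_threshold Retention threshold on the CVR (default 0.75).
#' @param rescue_enabled Apply the judgment-point rescue rule? Default `TRUE`.
#' @param points Named numeric vector of judgment points per rating level.
#' @param rescue_cvr_low,rescue_cvr_high Closed CVR interval for the rescue.
#' @param rescue_mean_points Strict lower bound on mean judgment points.
#' @param feasibility_n_max Largest panel size for the satisfiability search.
#' @return An object of class `"validation_config"`.
#' @export
validation_config <- function(cvr_formula = c("proportion", "lawshe_classic"),
                              cvr_threshold = 0.75,
                              rescue_enabled = TRUE,
                              points = c(
                                essential = 2, useful_not_essential = 1,
                                not_necessary = 0
                              ),
                              rescue_cvr_low = 0.0,
                              rescue_cvr_high = 0.5,
                              rescue_mean_points = 1.5,
                              feasibility_n_max = 12L) {
  cvr_formula <- match.arg(cvr_formula)
  if (cvr_threshold < 0 || cvr_threshold > 1) {
    abort_input("`cvr_threshold` must lie in [0, 1].")
  }
  if (rescue_cvr_low > rescue_cvr_high) {
    abort_input("`rescue_cvr_low` must not exceed `rescue_cvr_high`.")
  }
  if (!all(rating_levels() %in% names(points)) || any(points < 0)) {
    abort_input(
      "`points` must assign a non-negative value to each rating level."
    )
  }
  cfg <- structure(
    list(
      cvr_formula = cvr_formula, cvr_threshold = cvr_threshold,
      rescue_enabled = isTRUE(rescue_enabled),
      points = points[rating_levels()],
      rescue_cvr_low = rescue_cvr_low, rescue_cvr_high = rescue_cvr_high,
      rescue_mean_points = rescue_mean_points
    ),
    class = "validation_config"
  )
  if (cfg$rescue_enabled) {
    feas <- rescue_compositions(cfg, n_max = feasibility_n_max)
    if (nrow(feas) == 0) {
      warning(sprintf(
        paste0(
          "Rescue rule cannot fire: no panel composition with N <= %d ",
          "satisfies CVR in [%g, %g] and mean judgment points > %g under ",
          "formula \"%s\" with the given point scheme."
        ),
        feasibility_n_max, cfg$rescue_cvr_low, cfg$rescue_cvr_high,
        cfg$rescue_mean_points, cfg$cvr_formula
      ), call. = FALSE)
    }
  }
  cfg
}

#' Content validity ratio of one keyword
#'
#' With `formula = "proportion"` the CVR is the ratio of the number of
#' experts rating the keyword "essential" to the total number of experts,
#' giving values in `[0, 1]`. With `formula = "lawshe_classic"` it is
#' `(n_e - N/2) / (N/2)`, in `[-1, 1]`.
#'
#' @param ratings Character vector of one complete panel's ratings for a
#'   single keyword (canonical tokens or E/U/N).
#' @param formula `"proportion"` or `"lawshe_classic"`.
#' @return A single number.
#' @examples
#' cvr(c("E", "E", "E", "E", "E", "E", "U", "N")) # 6 of 8 essential
#' @export
cvr <- function(ratings, formula = c("proportion", "lawshe_classic")) {
  formula <- match.arg(formula)
  if (length(ratings) == 0) abort_input("Empty panel: no ratings supplied.")
  ratings <- canonical_rating(ratings)
  n <- length(ratings)
  n_e <- sum(ratings == "essential")
  if (formula == "proportion") n_e / n else (n_e - n / 2) / (n / 2)
}

#' Mean judgment points of one keyword
#'
#' @inheritParams cvr
#' @param points Named numeric vector of points per rating level.
#' @return Mean points per rater.
#' @examples
#' mean_judgment_points(c("E", "E", "E", "E", "U", "U", "U", "U")) # 1.5
#' @export
mean_judgment_points <- function(ratings,
                                 points = c(
                                   essential = 2, useful_not_essential = 1,
                                   not_necessary = 0
                                 )) {
  if (length(ratings) == 0) abort_input("Empty panel: no ratings supplied.")
  ratings <- canonical_rating(ratings)
  mean(unname(points[ratings]))
}

#' Retention decision for one keyword
#'
#' A keyword is retained outright when its CVR reaches the threshold
#' (`cvr >= cvr_threshold`); otherwise, when the rescue rule is enabled, it
#' is retained if the CVR lies in the closed rescue interval and the mean
#' judgment points strictly exceed the rescue bound; otherwise it is dropped.
#'
#' @param cvr_value CVR of the keyword (under `cfg$cvr_formula`).
#' @param mean_points Mean judgment points of the keyword.
#' @param cfg A [validation_config()].
#' @return One of `"retained_threshold"`, `"retained_rescue"`, `"dropped"`.
#' @export
decide_keyword <- function(cvr_value, mean_points, cfg = validation_config()) {
  if (cvr_value >= cfg$cvr_threshold) {
    "retained_threshold"
  } else if (cfg$rescue_enabled &&
    cvr_value >= cfg$rescue_cvr_low && cvr_value <= cfg$rescue_cvr_high &&
    mean_points > cfg$rescue_mean_points) {
    "retained_rescue"
  } else {
    "dropped"
  }
}

#' Exhaustive search for rescue-triggering panel compositions
#'
#' Enumerates every panel composition (`n_e` essential, `n_u` useful but not
#' essential, `n_n` not necessary; `n_e + n_u + n_n = N`) for all panel sizes
#' `N <= n_max` and returns those whose CVR and mean judgment points satisfy
#' the rescue rule of `cfg` while falling below the retention threshold.
#' This documents exactly when the rescue rule can fire for a given formula
#' and point scheme.
#'
#' @param cfg A [validation_config()] (its satisfiability warning is not
#'   re-triggered here).
#' @param n_max Largest panel size to enumerate.
#' @return A tibble with columns `n`, `n_essential`, `n_useful`,
#'   `n_not_necessary`, `cvr`, `mean_points`.
#' @export
rescue_compositions <- function(cfg, n_max = 12L) {
  if (!inherits(cfg, "validation_config")) {
    abort_input("Expected a `validation_config`.")
  }
  rows <- list()
  for (n in seq_len(n_max)) {
    for (n_e in 0:n) {
      for (n_u in 0:(n - n_e)) {
        n_n <- n - n_e - n_u
        ratings <- rep(rating_levels(), times = c(n_e, n_u, n_n))
        v <- cvr(ratings, cfg$cvr_formula)
        mp <- mean_judgment_points(ratings, cfg$points)
        if (v < cfg$cvr_threshold &&
          v >= cfg$rescue_cvr_low && v <= cfg$rescue_cvr_high &&
          mp > cfg$rescue_mean_points) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            n = n, n_essential = n_e, n_useful = n_u, n_not_necessary = n_n,
            cvr = v, mean_points = mp
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(
      n = integer(0), n_essential = integer(0), n_useful = integer(0),
      n_not_necessary = integer(0), cvr = numeric(0), mean_points = numeric(0)
    )
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Validate a lexicon against an expert rating table
#'
#' Computes per-keyword CVR and mean judgment points, applies the retention
#' decision, removes dropped entries together with their derivatives and
#' variations (derivatives and variations inherit the main keyword's
#' decision), and summarises: per-category mean CVR over retained keywords
#' and the content validity index (CVI), the mean CVR of all retained
#' keywords.
#'
#' @param lex A [lexicon()]; every entry must be rated.
#' @param table A [rating_table()].
#' @param cfg A [validation_config()].
#' @return A list of class `"validation_result"` with fields:
#'   `keyword_results` (tibble: entry_id, category, cvr, mean_points,
#'   decision), `category_summary` (tibble: category, n_retained, mean_cvr),
#'   `cvi` (number), `retained` (the filtered [lexicon()]), and `config`.
#' @export
validate_lexicon <- function(lex, table, cfg = validation_config()) {
  check_lexicon(lex)
  if (!inherits(table, "rating_table")) abort_input("Expected a `rating_table`.")
  unrated <- setdiff(lex$entries$entry_id, table$entries)
  if (length(unrated) > 0) {
    abort_validation(sprintf(
      "Unrated entry id(s): %s.", paste(unrated, collapse = ", ")
    ))
  }
  by_entry <- split(table$ratings$rating, table$ratings$entry_id)
  e <- lex$entries
  res <- tibble::tibble(
    entry_id = e$entry_id,
    category = e$category,
    cvr = vapply(
      by_entry[e$entry_id], cvr, numeric(1),
      formula = cfg$cvr_formula
    ),
    mean_points = vapply(
      by_entry[e$entry_id], mean_judgment_points, numeric(1),
      points = cfg$points
    )
  )
  res$decision <- mapply(decide_keyword, res$cvr, res$mean_points,
    MoreArgs = list(cfg = cfg), USE.NAMES = FALSE
  )
  res$cvr <- unname(res$cvr)
  res$mean_points <- unname(res$mean_points)
  keep <- res$decision != "dropped"
  retained <- lexicon(e[keep, , drop = FALSE], metadata = lex$metadata)
  cat_summary <- res[keep, ] |>
    dplyr::group_by(category = factor(category, levels = category_ids())) |>
    dplyr::summarise(
      n_retained = dplyr::n(), mean_cvr = mean(cvr), .groups = "drop"
    ) |>
    tidyr::complete(category, fill = list(n_retained = 0L)) |>
    dplyr::mutate(category = as.character(category))
  cvi <- if (any(keep)) mean(res$cvr[keep]) else NA_real_
  structure(
    list(
      keyword_results = res,
      category_summary = cat_summary,
      cvi = cvi,
      retained = retained,
      config = cfg
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  n <- nrow(x$keyword_results)
  kept <- sum(x$keyword_results$decision != "dropped")
  cat(sprintf(
    "<validation_result> %d keywords rated, %d retained (%d by rescue); CVI = %s\n",
    n, kept, sum(x$keyword_results$decision == "retained_rescue"),
    format(round(x$cvi, 2), nsmall = 2)
  ))
  invisible(x)
}
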