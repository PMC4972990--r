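#' Construct a symptom lexicon
#'
#' A lexicon is a collection of keyword entries. Each entry has a main keyword
#' (`surface`), a set of `derivatives` (enumerated tense/word-order variants),
#' a set of `variations` (abbreviation/textspeak spelling variants), exactly
#' one symptom category, and provenance tags. All texts are normalized with
#' [normalize_text()] on construction; duplicate derivatives/variations within
#' an entry are merged (with a message reporting how many were dropped), and
#' the surface itself is never kept among its own derivatives or variations.
#'
#' @param entries A data frame with columns `entry_id`, `category`, `surface`,
#'   and list (or `|`-joined character) columns `derivatives`, `variations`,
#'   `sources`.
#' @param metadata Named list of free-form lexicon metadata (name, language
#'   tag, version, ...).
#' @return An object of class `"lexicon"`.
#' @examples
#' lex <- lexicon(tibble::tibble(
#'   entry_id = "kw1", category = "mood", surface = "can not stop crying",
#'   derivatives = list("could not stop crying"),
#'   variations = list(c("cant stp crying", "cnt stop cryin")),
#'   sources = list("focus_group")
#' ))
#' count_summary(lex)
#' @export
lexicon <- function(entries, metadata = list()) {
  if (!is.data.frame(entries)) abort_input("`entries` must be a data frame.")
  required <- c("entry_id", "category", "surface")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort_input(sprintf(
      "`entries` lacks column(s): %s.", paste(missing_cols, collapse = ", ")
    ))
  }
  entries <- tibble::as_tibble(entries)
  for (col in c("derivatives", "variations", "sources")) {
    if (!col %in% names(entries)) {
      entries[[col]] <- rep(list(character(0)), nrow(entries))
    } else if (is.character(entries[[col]])) {
      entries[[col]] <- split_multi(entries[[col]])
    }
  }

  entries$entry_id <- as.character(entries$entry_id)
  entries$category <- as.character(entries$category)
  entries$surface <- normalize_text(as.character(entries$surface))

  if (anyDuplicated(entries$entry_id)) {
    dup <- unique(entries$entry_id[duplicated(entries$entry_id)])
    abort_input(sprintf(
      "Duplicate entry_id(s): %s.", paste(dup, collapse = ", ")
    ))
  }
  check_category(entries$category)
  if (any(!nzchar(entries$surface))) {
    abort_input("Every `surface` must be non-empty after normalization.")
  }

  n_dropped <- 0L
  clean_set <- function(x, surface) {
    x <- normalize_text(x)
    x <- x[nzchar(x)]
    keep <- unique(x)
    keep <- setdiff(keep, surface)
    n_dropped <<- n_dropped + (length(x) - length(keep))
    keep
  }
  entries$derivatives <- purrr::map2(
    entries$derivatives, entries$surface, clean_set
  )
  entries$variations <- purrr::map2(
    entries$variations, entries$surface, clean_set
  )
  entries$sources <- purrr::map(entries$sources, function(s) {
    s <- unique(as.character(s))
    bad <- setdiff(s, c(
      "focus_group", "expert_interview", "scale_review", "researcher_extension"
    ))
    if (length(bad) > 0) {
      abort_input(sprintf(
        "Unknown source tag(s): %s.", paste(bad, collapse = ", ")
      ))
    }
    s
  })
  if (n_dropped > 0) {
    message(sprintf(
      "Merged %d duplicate/self-referential derivative or variation text(s).",
      n_dropped
    ))
  }

  structure(
    list(entries = entries, metadata = metadata),
    class = "lexicon"
  )
}

#' Test for lexicon objects
#' @param x An object.
#' @return `TRUE` for objects created by [lexicon()].
#' @export
is_lexicon <- function(x) inherits(x, "lexicon")

check_lexicon <- function(lex) {
  if (!is_lexicon(lex)) abort_input("Expected a `lexicon` object.")
  invisible(lex)
}

#' @export
print.lexicon <- function(x, ...) {
  cs <- count_summary(x)
  total <- cs[cs$category == "total", ]
  name <- x$metadata$name %||% "unnamed"
  cat(sprintf(
    "<lexicon> %s: %d entries | %d main keywords, %d derivatives, %d spelling variations (%d keywords in total)\n",
    name, nrow(x$entries), total$main_count, total$derivative_count,
    total$variation_count, total$row_total
  ))
  invisible(x)
}

#' Per-category keyword count summary
#'
#' Tallies, for each of the 13 symptom categories, the number of main
#' keywords, derivatives and spelling variations held by the lexicon, plus a
#' row total (`main + derivatives + variations`) and a grand-total row whose
#' cells are the column sums. Categories with no entries appear with zeros, so
#' the summary always has 14 rows.
#'
#' @param lex A [lexicon()] object.
#' @return A tibble with columns `category`, `main_count`, `derivative_count`,
#'   `variation_count`, `row_total`; the last row has `category == "total"`.
#' @export
count_summary <- function(lex) {
  check_lexicon(lex)
  ids <- category_ids()
  e <- lex$entries
  per <- tibble::tibble(
    category = e$category,
    main = 1L,
    der = lengths(e$derivatives),
    var = lengths(e$variations)
  )
  agg <- per |>
    dplyr::group_by(category = factor(category, levels = ids)) |>
    dplyr::summarise(
      main_count = sum(main), derivative_count = sum(der),
      variation_count = sum(var), .groups = "drop"
    ) |>
    tidyr::complete(
      category,
      fill = list(main_count = 0L, derivative_count = 0L, variation_count = 0L)
    ) |>
    dplyr::mutate(category = as.character(category))
  agg <- agg[match(ids, agg$category), ]
  total <- tibble::tibble(
    category = "total",
    main_count = sum(agg$main_count),
    derivative_count = sum(agg$derivative_count),
    variation_count = sum(agg$variation_count)
  )
  out <- dplyr::bind_rows(agg, total)
  out$row_total <- out$main_count + out$derivative_count + out$variation_count
  out
}

#' Read a lexicon from a delimited file
#'
#' The delimited lexicon format is tab-separated UTF-8 with a header row and
#' one entry per line: `entry_id`, `category`, `surface`, `derivatives`
#' (`|`-joined), `variations` (`|`-joined), `sources` (`|`-joined).
#'
#' @param path Path to the file.
#' @param metadata Optional metadata list attached to the lexicon.
#' @return A [lexicon()] object.
#' @export
read_lexicon <- function(path, metadata = list()) {
  if (!file.exists(path)) {
    abort_input(sprintf("Lexicon file not found: %s.", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1) abort_input("Lexicon file is empty.")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c(
    "entry_id", "category", "surface", "derivatives", "variations", "sources"
  )
  if (!identical(header, expected)) {
    abort_input(sprintf(
      "Line 1: header must be %s.", paste(expected, collapse = "\t")
    ))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != 6)
  if (length(bad) > 0) {
    abort_input(sprintf(
      "Line %d: expected 6 tab-separated fields, found %d.",
      bad[1] + 1L, n_fields[bad[1]]
    ))
  }
  mat <- do.call(rbind, fields)
  entries <- tibble::tibble(
    entry_id = mat[, 1], category = mat[, 2], surface = mat[, 3],
    derivatives = split_multi(mat[, 4]),
    variations = split_multi(mat[, 5]),
    sources = split_multi(mat[, 6])
  )
  lexicon(entries, metadata = metadata)
}

#' Write a lexicon to the delimited format
#'
#' @param lex A [lexicon()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  check_lexicon(lex)
  e <- lex$entries
  lines <- c(
    "entry_id\tcategory\tsurface\tderivatives\tvariations\tsources",
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s",
      e$entry_id, e$category, e$surface,
      join_multi(e$derivatives), join_multi(e$variations),
      join_multi(e$sources)
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a stub lexicon realizing given per-category counts
#'
#' Constructs a lexicon of synthetic placeholder entries whose per-category
#' main/derivative/variation counts equal a supplied count table. Useful for
#' checking count arithmetic against published lexicon size tables when the
#' underlying keyword lists themselves are not available: within each category
#' one entry carries all of the category's derivative and variation
#' placeholders and the remaining entries are bare main keywords.
#'
#' @param counts A data frame with columns `category`, `main_count`,
#'   `derivative_count`, `variation_count` (one row per category; a `total`
#'   row, if present, is ignored). Categories with `main_count == 0` must have
#'   zero derivatives and variations.
#' @return A [lexicon()] object whose [count_summary()] reproduces `counts`.
#' @export
stub_lexicon <- function(counts) {
  if (!is.data.frame(counts)) abort_input("`counts` must be a data frame.")
  counts <- counts[counts$category != "total", , drop = FALSE]
  check_category(counts$category)
  rows <- purrr::pmap(
    list(
      counts$category, counts$main_count,
      counts$derivative_count, counts$variation_count
    ),
    function(cat, n_main, n_der, n_var) {
      if (n_main == 0) {
        if (n_der > 0 || n_var > 0) {
          abort_input(sprintf(
            "Category %s has derivatives/variations but no main keywords.", cat
          ))
        }
        return(NULL)
      }
      surfaces <- sprintf("%s stub %d", gsub("_", " ", cat), seq_len(n_main))
      ders <- c(
        list(sprintf("%s der %d", gsub("_", " ", cat), seq_len(n_der))),
        rep(list(character(0)), n_main - 1L)
      )
      vars <- c(
        list(sprintf("%s var %d", gsub("_", " ", cat), seq_len(n_var))),
        rep(list(character(0)), n_main - 1L)
      )
      tibble::tibble(
        entry_id = sprintf("%s_%d", cat, seq_len(n_main)),
        category = cat, surface = surfaces,
        derivatives = ders, variations = vars,
        sources = rep(list("researcher_extension"), n_main)
      )
    }
  )
  lexicon(
    dplyr::bind_rows(rows),
    metadata = list(name = "stub lexicon (synthetic placeholder entries)")
  )
}
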