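#' Article corpora
#'
#' A corpus is a tibble with one row per newspaper article and a fixed core
#' schema, carrying `source_label` and `period` attributes. Core columns:
#'
#' * `article_id` (character, unique), `newspaper` (character),
#'   `publication_date` (`Date`) — required;
#' * `headline`, `body` (character; possibly empty, never `NA`) — required;
#' * `edition` (character), `page_number` (integer `>= 1`), `url`
#'   (character) — optional, `NA` when absent;
#' * `continues_from_front_page`, `has_photo` (logical, default `FALSE`);
#' * `photo_kinds` (list of character vectors; subsets of
#'   `deceased, bereaved, location, method, dramatic`; non-empty only when
#'   `has_photo` is `TRUE`).
#'
#' Any extra columns (screener category tags, scraper metadata, ...) are
#' preserved on round-trip but ignored by scoring computations.
#'
#' @param articles A data frame with at least the required columns.
#' @param source_label Free-text provenance label.
#' @param period Optional length-2 `Date` vector (start, end); when set,
#'   every `publication_date` must fall inside it.
#' @return A validated `mrs_corpus` tibble.
#' @examples
#' corpus(tibble::tibble(
#'   article_id = "a1", newspaper = "The Daily", publication_date = as.Date("2020-04-02"),
#'   headline = "Headline", body = "Body text.", has_photo = FALSE))
#' @export
corpus <- function(articles, source_label = "", period = NULL) {
  stopifnot(is.data.frame(articles))
  df <- tibble::as_tibble(articles)
  required <- c("article_id", "newspaper", "publication_date", "headline", "body")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_mrscore(paste0("missing required article field(s): ",
                        paste(missing, collapse = ", ")), "mrscore_validation_error")
  if (!"edition" %in% names(df)) df$edition <- NA_character_
  if (!"page_number" %in% names(df)) df$page_number <- NA_integer_
  if (!"continues_from_front_page" %in% names(df)) df$continues_from_front_page <- FALSE
  if (!"has_photo" %in% names(df)) df$has_photo <- FALSE
  if (!"photo_kinds" %in% names(df)) df$photo_kinds <- rep(list(character()), nrow(df))
  if (!"url" %in% names(df)) df$url <- NA_character_
  df$article_id <- as.character(df$article_id)
  df$newspaper <- as.character(df$newspaper)
  df$publication_date <- as.Date(df$publication_date)
  df$page_number <- as.integer(df$page_number)
  df$continues_from_front_page <- as.logical(df$continues_from_front_page) %in% TRUE
  df$has_photo <- as.logical(df$has_photo) %in% TRUE
  if (!is.list(df$photo_kinds)) df$photo_kinds <- as.list(df$photo_kinds)
  df$photo_kinds <- lapply(df$photo_kinds, function(x) {
    x <- as.character(x); x[!is.na(x) & nzchar(x)]
  })
  core <- c("article_id", "newspaper", "publication_date", "edition", "page_number",
            "continues_from_front_page", "headline", "body", "has_photo",
            "photo_kinds", "url")
  df <- df[, c(core, setdiff(names(df), core)), drop = FALSE]
  out <- structure(df, source_label = source_label, period = period,
                   class = c("mrs_corpus", class(df)))
  validate_corpus(out)
}

photo_kind_levels <- function() c("deceased", "bereaved", "location", "method", "dramatic")

#' Validate a corpus against its invariants
#'
#' Checks id uniqueness, non-`NA` headline/body, `page_number >= 1`,
#' `photo_kinds` implying `has_photo`, photo-kind vocabulary, and (when a
#' period is set) that all publication dates fall within it.
#'
#' @param x An `mrs_corpus`.
#' @return `x` invisibly-validated (returned unchanged) or an error.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "mrs_corpus"))
  dup <- unique(x$article_id[duplicated(x$article_id)])
  if (length(dup) > 0L)
    stop_mrscore(paste0("duplicate article_id(s): ", paste(dup, collapse = ", ")),
                 "mrscore_validation_error")
  if (anyNA(x$article_id) || any(!nzchar(x$article_id)))
    stop_mrscore("article_id must be non-empty for every article", "mrscore_validation_error")
  for (f in c("headline", "body")) {
    bad <- x$article_id[is.na(x[[f]])]
    if (length(bad) > 0L)
      stop_mrscore(paste0("field '", f, "' absent (NA) for article(s): ",
                          paste(bad, collapse = ", ")), "mrscore_validation_error")
  }
  if (anyNA(x$publication_date))
    stop_mrscore("publication_date missing or unparseable for some articles",
                 "mrscore_validation_error")
  bad <- x$article_id[!is.na(x$page_number) & x$page_number < 1L]
  if (length(bad) > 0L)
    stop_mrscore(paste0("page_number < 1 for article(s): ", paste(bad, collapse = ", ")),
                 "mrscore_validation_error")
  kinds <- unique(unlist(x$photo_kinds))
  if (length(setdiff(kinds, photo_kind_levels())) > 0L)
    stop_mrscore(paste0("unknown photo_kinds: ",
                        paste(setdiff(kinds, photo_kind_levels()), collapse = ", ")),
                 "mrscore_validation_error")
  bad <- x$article_id[lengths(x$photo_kinds) > 0L & !x$has_photo]
  if (length(bad) > 0L)
    stop_mrscore(paste0("photo_kinds set but has_photo FALSE for article(s): ",
                        paste(bad, collapse = ", ")), "mrscore_validation_error")
  period <- attr(x, "period")
  if (!is.null(period)) {
    outside <- x$article_id[x$publication_date < period[1] | x$publication_date > period[2]]
    if (length(outside) > 0L)
      stop_mrscore(paste0("publication_date outside corpus period for article(s): ",
                          paste(outside, collapse = ", ")), "mrscore_validation_error")
  }
  x
}

#' @export
print.mrs_corpus <- function(x, ...) {
  period <- attr(x, "period")
  cat("<mrs_corpus> ", nrow(x), " article(s), ",
      length(unique(x$newspaper)), " newspaper(s)",
      if (!is.null(period)) paste0(", ", period[1], " .. ", period[2]), "\n", sep = "")
  NextMethod()
}

core_columns <- function() c("article_id", "newspaper", "publication_date", "edition",
                             "page_number", "continues_from_front_page", "headline",
                             "body", "has_photo", "photo_kinds", "url")

#' Read a corpus file
#'
#' Two on-disk formats are supported. `records` is JSON-lines: one UTF-8
#' JSON object per line with the fields of the article schema; absent
#' optional fields are simply omitted. `delimited` is RFC-4180 CSV with a
#' header row; `photo_kinds` is serialized as semicolon-joined tokens and
#' newlines inside text fields are escaped as `\\n` (the record-per-line
#' format stores them natively). Unknown extra fields are preserved.
#'
#' @param path File to read.
#' @param format `"records"` (JSONL) or `"delimited"` (CSV).
#' @param source_label,period Corpus-level metadata (see [corpus()]);
#'   defaults to the file name and no period.
#' @return A validated `mrs_corpus`.
#' @export
read_corpus <- function(path, format = c("records", "delimited"),
                        source_label = basename(path), period = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mrscore(paste0("no such file: ", path), "mrscore_io_error")
  df <- if (format == "records") read_corpus_jsonl(path) else read_corpus_csv(path)
  corpus(df, source_label = source_label, period = period)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_article_table())
  required <- c("article_id", "newspaper", "publication_date", "headline", "body")
  recs <- vector("list", length(lines))
  problems <- character()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      problems <- c(problems, paste0("line ", i, ": not a JSON object"))
      next
    }
    miss <- setdiff(required, names(rec))
    if (length(miss) > 0L) {
      problems <- c(problems, paste0("line ", i, ": missing field(s) ",
                                     paste(miss, collapse = ", ")))
      next
    }
    recs[[i]] <- rec
  }
  if (length(problems) > 0L)
    stop_mrscore(paste0("malformed records in ", path, ":\n  ",
                        paste(problems, collapse = "\n  ")), "mrscore_validation_error")
  all_names <- unique(unlist(lapply(recs, names)))
  cols <- lapply(all_names, function(nm) {
    vals <- lapply(recs, function(r) r[[nm]])
    if (nm == "photo_kinds") return(lapply(vals, function(v) as.character(v %||% character())))
    if (nm %in% c("continues_from_front_page", "has_photo"))
      return(vapply(vals, function(v) isTRUE(as.logical(v %||% FALSE)), logical(1)))
    if (nm == "page_number")
      return(vapply(vals, function(v) if (is.null(v)) NA_integer_ else as.integer(v), integer(1)))
    vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), character(1))
  })
  names(cols) <- all_names
  df <- tibble::as_tibble(cols)
  df$publication_date <- as.Date(df$publication_date)
  df
}

csv_escape <- function(x) {
  x <- stringr::str_replace_all(x, stringr::fixed("\\"), "\\\\")
  stringr::str_replace_all(x, stringr::fixed("\n"), "\\n")
}

csv_unescape <- function(x) {
  stringr::str_replace_all(x, "\\\\n|\\\\\\\\",
                           function(m) ifelse(m == "\\n", "\n", "\\"))
}

read_corpus_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        trim_ws = FALSE, progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) return(empty_article_table())
  for (f in intersect(c("headline", "body"), names(df))) {
    df[[f]][is.na(df[[f]])] <- ""
    df[[f]] <- csv_unescape(df[[f]])
  }
  if ("photo_kinds" %in% names(df)) {
    df$photo_kinds <- lapply(df$photo_kinds, function(v) {
      if (is.na(v) || !nzchar(v)) character() else strsplit(v, ";", fixed = TRUE)[[1]]
    })
  }
  if ("publication_date" %in% names(df)) df$publication_date <- as.Date(df$publication_date)
  if ("page_number" %in% names(df)) df$page_number <- as.integer(df$page_number)
  for (f in intersect(c("continues_from_front_page", "has_photo"), names(df)))
    df[[f]] <- toupper(df[[f]]) %in% "TRUE"
  df
}

empty_article_table <- function() {
  tibble::tibble(article_id = character(), newspaper = character(),
                 publication_date = as.Date(character()), edition = character(),
                 page_number = integer(), continues_from_front_page = logical(),
                 headline = character(), body = character(), has_photo = logical(),
                 photo_kinds = list(), url = character())
}

#' Write a corpus file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p), format)`
#' reproduces `x` field-for-field, including the absence (not
#' empty-string coercion) of optional fields.
#'
#' @param x An `mrs_corpus`.
#' @param path Output file.
#' @param format `"records"` (JSONL) or `"delimited"` (CSV).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("records", "delimited")) {
  format <- match.arg(format)
  validate_corpus(x)
  if (format == "records") write_corpus_jsonl(x, path) else write_corpus_csv(x, path)
  invisible(path)
}

write_corpus_jsonl <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    rec <- list()
    for (nm in names(x)) {
      v <- x[[nm]][[i]]
      if (nm == "publication_date") v <- format(x$publication_date[i], "%Y-%m-%d")
      if (nm == "photo_kinds") { if (length(v) == 0L) next } else if (is.na(v) &&
          !nm %in% c("headline", "body")) next
      rec[[nm]] <- v
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

write_corpus_csv <- function(x, path) {
  df <- x
  class(df) <- setdiff(class(df), "mrs_corpus")
  df$photo_kinds <- vapply(x$photo_kinds, paste, character(1), collapse = ";")
  df$publication_date <- format(df$publication_date, "%Y-%m-%d")
  for (f in c("headline", "body")) df[[f]] <- csv_escape(df[[f]])
  readr::write_csv(df, path, na = "", progress = FALSE)
}
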