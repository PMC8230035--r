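#' Corpus screening
#'
#' Implements the inclusion/exclusion rules for building the analysis set:
#' articles must match a suicide keyword prefilter, be specific case
#' reports (not commentary, ideation-only pieces, suicide bombings, or
#' deaths of undetermined cause), and devote at least half their content to
#' the case. Screening emits one decision per article and a PRISMA-style
#' report of counts by exclusion reason.
#'
#' @name screening
NULL

screening_reasons <- function() c(
  "included", "general_commentary", "ideation_only", "bombing_intent",
  "undetermined_cause", "below_half_content", "not_matching_prefilter",
  "out_of_period", "wrong_language")

category_tags <- function() c("case_report", "general_commentary", "ideation_only",
                              "bombing_intent", "undetermined_cause")

default_keywords <- function() c("suicide", "kills self", "ends life")

#' Build a screening configuration
#'
#' @param period Optional length-2 `Date` vector; articles dated outside it
#'   are excluded `out_of_period`.
#' @param language Optional language code; when set, articles carrying a
#'   `language` field with a different value are excluded `wrong_language`
#'   (articles without the field are assumed to match).
#' @param keywords Prefilter phrases (default: `suicide`, `kills self`,
#'   `ends life`), matched case-insensitively at token boundaries against
#'   headline and body.
#' @param category_field Name of the optional per-article column carrying a
#'   human screener's category tag (one of `case_report`,
#'   `general_commentary`, `ideation_only`, `bombing_intent`,
#'   `undetermined_cause`).
#' @param lexicon Lexicon used for the relevance fraction and — only for
#'   articles without a category tag — the heuristic category-cue fallback.
#' @param use_cue_fallback Disable to skip the heuristic fallback entirely.
#' @return An `mrs_screening_config` list.
#' @export
screening_config <- function(period = NULL, language = NULL,
                             keywords = default_keywords(),
                             category_field = "category",
                             lexicon = read_lexicon(),
                             use_cue_fallback = TRUE) {
  stopifnot(length(keywords) > 0L)
  structure(list(period = period, language = language, keywords = keywords,
                 category_field = category_field, lexicon = lexicon,
                 use_cue_fallback = use_cue_fallback),
            class = "mrs_screening_config")
}

#' Read a screening configuration from YAML
#'
#' Recognized keys: `period` (list of two ISO dates), `language`,
#' `keywords`, `category_field`, `lexicon` (path), `use_cue_fallback`.
#'
#' @param path YAML file.
#' @return An `mrs_screening_config`.
#' @export
read_screening_config <- function(path) {
  y <- yaml::read_yaml(path)
  screening_config(
    period = if (!is.null(y$period)) as.Date(unlist(y$period)),
    language = y$language,
    keywords = unlist(y$keywords) %||% default_keywords(),
    category_field = y$category_field %||% "category",
    lexicon = read_lexicon(y$lexicon),
    use_cue_fallback = y$use_cue_fallback %||% TRUE)
}

#' Keyword prefilter
#'
#' @param article One article (one-row corpus tibble or named list with
#'   `headline` and `body`).
#' @param keywords Non-empty character vector of phrases.
#' @return `TRUE` iff any phrase matches headline or body,
#'   case-insensitively, as a whole token sequence ("suicidal" does not
#'   match the keyword "suicide").
#' @examples
#' keyword_prefilter(list(headline = "", body = "He ends life in despair"),
#'                   c("suicide", "kills self", "ends life"))
#' @export
keyword_prefilter <- function(article, keywords = default_keywords()) {
  stopifnot(length(keywords) > 0L)
  a <- as.list(article)
  any_phrase(a$headline %||% "", keywords) || any_phrase(a$body %||% "", keywords)
}

#' Fraction of body sentences about the suicide case
#'
#' The operational proxy for the "less than 50% of the content" exclusion:
#' the body is split into sentences ([split_sentences()]) and the fraction
#' of sentences containing at least one suicide-case term (lexicon list
#' `case_terms`) is returned. Deterministic for a fixed splitter and
#' lexicon; an empty body yields 0.
#'
#' @param article One article (or a bare body string).
#' @param lexicon An [read_lexicon()] lexicon.
#' @return Number in `[0, 1]`.
#' @export
relevance_fraction <- function(article, lexicon = read_lexicon()) {
  body <- if (is.character(article)) article else as.list(article)$body %||% ""
  sents <- split_sentences(body)
  if (nrow(sents) == 0L) return(0)
  hits <- vapply(sents$sentence, any_phrase, logical(1),
                 phrases = unlist(lexicon$case_terms))
  sum(hits) / nrow(sents)
}

categorize_article <- function(a, config) {
  tag <- a[[config$category_field]]
  if (!is.null(tag) && length(tag) == 1L && !is.na(tag) && nzchar(tag)) {
    if (!tag %in% category_tags())
      stop_mrscore(paste0("unknown screening category tag '", tag, "' for article '",
                          a$article_id %||% "?", "'"), "mrscore_validation_error")
    return(list(category = tag, source = "tag"))
  }
  if (!config$use_cue_fallback) return(list(category = "case_report", source = "none"))
  lex <- config$lexicon
  text <- paste(a$headline %||% "", a$body %||% "")
  if (any_phrase(text, unlist(lex$commentary_cues)))
    return(list(category = "general_commentary", source = "cue"))
  death_terms <- c("died", "death", "dead", "body")
  if (any_phrase(text, unlist(lex$ideation_cues)) && !any_phrase(text, death_terms))
    return(list(category = "ideation_only", source = "cue"))
  if (any_phrase(text, unlist(lex$bombing_cues)))
    return(list(category = "bombing_intent", source = "cue"))
  if (any_phrase(text, unlist(lex$undetermined_cues)))
    return(list(category = "undetermined_cause", source = "cue"))
  list(category = "case_report", source = "none")
}

#' Screen one article
#'
#' Rules are applied in a fixed order — period/language, keyword prefilter,
#' category exclusions (human tag when present, else heuristic lexicon
#' cues), then the relevance-fraction rule (`< 0.5` excludes; exactly 50%
#' is included) — and the first failing rule determines the exclusion
#' reason.
#'
#' @param article One article.
#' @param config An [screening_config()].
#' @return One-row tibble: `article_id, included, reason,
#'   relevance_fraction` (NA unless the prefilter passed), and
#'   `category_source` (`"tag"`, `"cue"` or `"none"` — `"cue"` marks the
#'   heuristic fallback).
#' @export
screen_article <- function(article, config = screening_config()) {
  a <- as.list(article)
  decision <- function(reason, frac = NA_real_, src = NA_character_) {
    tibble::new_tibble(list(article_id = as.character(a$article_id %||% NA_character_),
                            included = reason == "included", reason = reason,
                            relevance_fraction = frac, category_source = src),
                       nrow = 1L)
  }
  if (!is.null(config$language)) {
    lang <- a$language
    if (!is.null(lang) && length(lang) == 1L && !is.na(lang) &&
        tolower(lang) != tolower(config$language))
      return(decision("wrong_language"))
  }
  if (!is.null(config$period)) {
    d <- as.Date(a$publication_date)
    if (!is.na(d) && (d < config$period[1] || d > config$period[2]))
      return(decision("out_of_period"))
  }
  if (!keyword_prefilter(a, config$keywords))
    return(decision("not_matching_prefilter"))
  frac <- relevance_fraction(a, config$lexicon)
  cat_res <- categorize_article(a, config)
  if (cat_res$category != "case_report")
    return(decision(cat_res$category, frac, cat_res$source))
  if (frac < 0.5) return(decision("below_half_content", frac, cat_res$source))
  decision("included", frac, cat_res$source)
}

#' Screen a corpus
#'
#' @param x An `mrs_corpus`.
#' @param config An [screening_config()].
#' @return List with `decisions` (one row per article, see
#'   [screen_article()]) and `report` (an `mrs_screening_report`).
#' @export
screen_corpus <- function(x, config = screening_config()) {
  stopifnot(inherits(x, "mrs_corpus"))
  decisions <- if (nrow(x) == 0L)
    screen_article(list(article_id = "x"), config)[0, , drop = FALSE]
  else dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i)
    screen_article(x[i, , drop = FALSE], config)))
  list(decisions = decisions, report = screening_report(decisions))
}

#' Tally screening decisions into a PRISMA-style report
#'
#' @param decisions Decision tibble from [screen_corpus()].
#' @return An `mrs_screening_report`: `n_scanned` (all decisions),
#'   `n_identified` (passed the prefilter and period/language checks),
#'   `n_included`, and a named `exclusions` vector of per-reason counts.
#'   Conservation holds by construction: `n_identified = n_included +`
#'   post-prefilter exclusion counts.
#' @export
screening_report <- function(decisions) {
  counts <- table(factor(decisions$reason, levels = screening_reasons()))
  pre <- c("not_matching_prefilter", "out_of_period", "wrong_language")
  excl <- counts[setdiff(screening_reasons(), "included")]
  structure(list(
    n_scanned = nrow(decisions),
    n_identified = nrow(decisions) - sum(counts[pre]),
    n_included = unname(counts[["included"]]),
    exclusions = setNames(as.integer(excl), names(excl))),
    class = "mrs_screening_report")
}

#' @export
print.mrs_screening_report <- function(x, ...) {
  cat(format_prisma(x), sep = "\n")
  invisible(x)
}

#' Format a screening report as a PRISMA-style text summary
#'
#' @param report An `mrs_screening_report`.
#' @return Character vector of lines.
#' @export
format_prisma <- function(report) {
  ex <- report$exclusions
  pre <- c("not_matching_prefilter", "out_of_period", "wrong_language")
  post <- setdiff(names(ex), pre)
  c(paste0("Records scanned:            ", report$n_scanned),
    paste0("  excluded before screening: ", sum(ex[pre])),
    paste0("    ", pre, ": ", ex[pre]),
    paste0("Records identified:         ", report$n_identified),
    paste0("  excluded during screening: ", sum(ex[post])),
    paste0("    ", post, ": ", ex[post]),
    paste0("Records included:           ", report$n_included),
    "Note: the 50%-content rule is a sentence-level proxy; category",
    "exclusions marked category_source = 'cue' are heuristic.")
}

#' Write a screening report as CSV
#'
#' @param report An `mrs_screening_report`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_screening_report <- function(report, path) {
  df <- tibble::tibble(
    item = c("n_scanned", "n_identified", "n_included",
             paste0("excluded_", names(report$exclusions))),
    count = c(report$n_scanned, report$n_identified, report$n_included,
              as.integer(report$exclusions)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
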