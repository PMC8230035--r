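#' Rule-based criterion detection
#'
#' Each auto-capable rubric criterion has a deterministic detector: a rule
#' over lexicon term lists applied to the article fields in the criterion's
#' scope. Matching is case-insensitive and token-boundary anchored, and
#' every positive code carries evidence spans (field, character offsets,
#' matched text). Detectors that depend on article metadata (photos, front
#' page) read the metadata flags only.
#'
#' @name detection
NULL

quote_char_regex <- function() "[\"“”]"

# evidence constructors -------------------------------------------------

new_spans <- function(start, end, text) {
  tibble::new_tibble(list(start = start, end = end, text = text),
                     nrow = length(start))
}

ev <- function(field, spans, text) {
  if (nrow(spans) == 0L)
    return(tibble::new_tibble(list(field = character(), start = integer(),
                                   end = integer(), text = character()), nrow = 0L))
  spans <- merge_spans(spans[, c("start", "end", "text")], text)
  tibble::new_tibble(list(field = rep(field, nrow(spans)), start = spans$start,
                          end = spans$end, text = spans$text), nrow = nrow(spans))
}

ev_metadata <- function(text) {
  tibble::new_tibble(list(field = "metadata", start = NA_integer_,
                          end = NA_integer_, text = text), nrow = 1L)
}

no_ev <- function() ev("body", empty_match(), "")

# per-sentence co-occurrence: spans of `terms` restricted to sentences that
# also match `with` (a list of extra phrase lists that must all match)
sentence_cooccur <- function(body, sentences, terms, with = list()) {
  if (nrow(sentences) == 0L || !any_phrase(body, terms))
    return(new_spans(integer(), integer(), character()))
  keep <- list()
  for (i in seq_len(nrow(sentences))) {
    s <- sentences$sentence[i]
    if (!any_phrase(s, terms)) next
    ok <- all(vapply(with, function(w) {
      if (length(w) == 1L && startsWith(w[1], "rx:"))
        stringr::str_detect(s, substring(w[1], 4L))
      else any_phrase(s, w)
    }, logical(1)))
    if (!ok) next
    m <- match_phrases(s, terms)
    keep[[length(keep) + 1L]] <- new_spans(m$start + sentences$start[i] - 1L,
                                           m$end + sentences$start[i] - 1L, m$text)
  }
  if (length(keep) == 0L) return(new_spans(integer(), integer(), character()))
  dplyr::bind_rows(keep)
}

# detection context shared by all criteria of one article
detect_context <- function(article) {
  a <- as.list(article)
  a$headline <- a$headline %||% ""
  a$body <- a$body %||% ""
  if (is.list(a$photo_kinds)) a$photo_kinds <- unlist(a$photo_kinds)
  a$sentences <- split_sentences(a$body)
  a
}

#' Detect a single criterion in an article
#'
#' @param article One article: a one-row corpus tibble or a named list with
#'   at least `headline` and `body` (plus `page_number`,
#'   `continues_from_front_page`, `has_photo`, `photo_kinds` for the
#'   metadata criteria).
#' @param code Criterion code, e.g. `"N1"`.
#' @param lexicon An [read_lexicon()] lexicon.
#' @param registry Helpline registry tibble (needed by P2's auto mode;
#'   `NULL` defers P2 to manual coding).
#' @return A list with elements `code` (0 or 1) and `evidence` (tibble
#'   `field, start, end, text`; rows only when `code == 1`).
#' @examples
#' lex <- read_lexicon()
#' detect_criterion(list(headline = "", body = "He committed suicide on Monday."),
#'                  "N1", lex)$code
#' @export
detect_criterion <- function(article, code, lexicon, registry = NULL) {
  stopifnot(code %in% criterion_codes())
  criteria <- load_criteria()
  mode <- criteria$detection_mode[criteria$code == code]
  if (mode == "manual_only")
    stop_mrscore(paste0("criterion ", code, " is manual-only and has no detector"),
                 "mrscore_mode_error")
  ctx <- detect_context(article)
  res <- detect_one(ctx, code, lexicon, registry)
  if (res$code == 0L) res$evidence <- res$evidence[0, , drop = FALSE]
  res
}

detect_one <- function(ctx, code, lex, registry) {
  body <- ctx$body; headline <- ctx$headline; sents <- ctx$sentences
  fire <- function(spans_body) list(code = as.integer(nrow(spans_body) > 0L),
                                    evidence = spans_body)
  switch(code,
    P1 = {
      pats <- c(unlist(lex$helpline_names), unlist(lex$helpline_phone_patterns))
      fire(ev("body", match_phrases(body, pats), body))
    },
    P2 = {
      if (is.null(registry)) return(list(code = 0L, evidence = no_ev(), needs_manual = TRUE))
      p1 <- detect_one(ctx, "P1", lex, registry)
      if (p1$code == 0L) return(list(code = 0L, evidence = no_ev()))
      ok <- vapply(seq_len(nrow(p1$evidence)), function(i) {
        txt <- p1$evidence$text[i]
        digs <- stringr::str_remove_all(txt, "[^0-9]")
        hit <- tolower(trimws(txt)) %in% tolower(registry$name) |
          (nchar(digs) >= 8L & digs %in% registry$phone_digits)
        if (!any(hit)) return(FALSE)
        nm <- tolower(trimws(txt)) == tolower(registry$name)
        ph <- nchar(digs) >= 8L & digs == registry$phone_digits
        any(registry$operational[nm | ph])
      }, logical(1))
      list(code = as.integer(any(ok)), evidence = p1$evidence[ok, , drop = FALSE])
    },
    P3 = {
      acc <- match_phrases(body, unlist(lex$mental_health_accept_terms))
      rej <- match_phrases(body, unlist(lex$mental_health_reject_terms))
      if (nrow(acc) > 0L && nrow(rej) > 0L) {
        # a reject match strictly covering an accept match vetoes that span;
        # a reject match inside an accept phrase (e.g. "mental" within
        # "mental illness") does not
        veto <- vapply(seq_len(nrow(acc)), function(i) {
          any(rej$start <= acc$start[i] & rej$end >= acc$end[i] &
                (rej$end - rej$start) > (acc$end[i] - acc$start[i]))
        }, logical(1))
        acc <- acc[!veto, , drop = FALSE]
      }
      fire(ev("body", acc, body))
    },
    P4 = fire(ev("body", match_phrases(body, unlist(lex$substance_struggle_terms)), body)),
    P5 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$expert_role_terms),
      list(c(unlist(lex$attribution_cues), paste0("re:", quote_char_regex())))), body)),
    P6 = fire(ev("body", match_phrases(body, unlist(lex$prevention_markers)), body)),
    P7 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$stat_markers),
      list("rx:[0-9]")), body)),
    P8 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$myth_markers),
      list(unlist(lex$refutation_markers))), body)),
    P9 = fire(ev("body", match_phrases(body, unlist(lex$hope_markers)), body)),
    P10 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$official_source_terms),
      list(unlist(lex$attribution_cues))), body)),
    N1 = {
      e <- dplyr::bind_rows(
        ev("headline", match_phrases(headline, unlist(lex$criminalizing_phrases)), headline),
        ev("body", match_phrases(body, unlist(lex$criminalizing_phrases)), body))
      list(code = as.integer(nrow(e) > 0L), evidence = e)
    },
    N2 = {
      word <- match_phrases(headline, "suicide")
      meth <- match_phrases(headline, unlist(lex$method_terms))
      reason <- if (any_phrase(headline, unlist(lex$reason_cues)) &&
                    any_phrase(headline, unlist(lex$stressor_nouns)))
        match_phrases(headline, unlist(lex$stressor_nouns))
      else empty_match()
      e <- ev("headline", dplyr::bind_rows(word, meth, reason)[, c("start", "end", "text")],
              headline)
      list(code = as.integer(nrow(e) > 0L), evidence = e)
    },
    N3 = {
      e <- dplyr::bind_rows(
        ev("headline", match_phrases(headline, unlist(lex$method_terms)), headline),
        ev("body", match_phrases(body, unlist(lex$method_terms)), body))
      list(code = as.integer(nrow(e) > 0L), evidence = e)
    },
    N4 = {
      m <- match_phrases(body, unlist(lex$method_detail_terms))
      if (length(unique(m$phrase)) >= 2L) fire(ev("body", m, body))
      else list(code = 0L, evidence = no_ev())
    },
    N5 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$site_terms),
      list(unlist(lex$location_prepositions))), body)),
    N6 = {
      if (!any_phrase(body, unlist(lex$single_factor_markers)))
        return(list(code = 0L, evidence = no_ev()))
      marker_sents <- integer()
      spans <- list()
      for (i in seq_len(nrow(sents))) {
        m <- match_phrases(sents$sentence[i], unlist(lex$single_factor_markers))
        if (nrow(m) == 0L) next
        marker_sents <- c(marker_sents, i)
        spans[[length(spans) + 1L]] <- new_spans(m$start + sents$start[i] - 1L,
                                                 m$end + sents$start[i] - 1L, m$text)
      }
      spans <- dplyr::bind_rows(spans)
      if (length(marker_sents) == 0L) return(list(code = 0L, evidence = no_ev()))
      if (any_phrase(body, unlist(lex$speculation_markers)))
        return(list(code = 0L, evidence = no_ev()))
      stressors <- unique(unlist(lapply(marker_sents, function(i)
        match_phrases(sents$sentence[i], unlist(lex$stressor_nouns))$phrase)))
      if (length(stressors) >= 2L) return(list(code = 0L, evidence = no_ev()))
      list(code = 1L, evidence = ev("body", spans, body))
    },
    N7 = {
      hp <- isTRUE(ctx$has_photo)
      kinds <- ctx$photo_kinds %||% character()
      if (hp) list(code = 1L, evidence = ev_metadata(
        paste0("has_photo=TRUE", if (length(kinds) > 0L)
          paste0("; kinds=", paste(kinds, collapse = ",")))))
      else list(code = 0L, evidence = no_ev())
    },
    N8 = fire(ev("body", match_phrases(body, unlist(lex$grief_terms)), body)),
    N9 = fire(ev("body", sentence_cooccur(body, sents, unlist(lex$note_terms),
      list(paste0("re:", quote_char_regex()))), body)),
    N10 = {
      front <- (!is.null(ctx$page_number) && !is.na(ctx$page_number) &&
                  ctx$page_number == 1L) || isTRUE(ctx$continues_from_front_page)
      if (front) list(code = 1L, evidence = ev_metadata(
        paste0("page_number=", ctx$page_number %||% NA,
               "; continues_from_front_page=", isTRUE(ctx$continues_from_front_page))))
      else list(code = 0L, evidence = no_ev())
    }
  )
}

#' Auto-code one article against all 20 criteria
#'
#' Runs every auto-capable detector; manual-only criteria (none in the
#' default registry) and hybrid criteria lacking their registry input are
#' coded 0 and flagged in `notes` as needing manual coding. The coupling
#' P2 <= P1 (help-seeking information cannot be verified operational if
#' none is present) is enforced structurally.
#'
#' @inheritParams detect_criterion
#' @param coded_at Timestamp recorded on the record (fixed default keeps
#'   outputs digest-comparable; pass `Sys.time()` for wall-clock stamps).
#' @return An `mrs_coding` record: list with `article_id`, `coder_id =
#'   "auto"`, `codes` (named 0/1 integer vector over all 20 criteria),
#'   `evidence` (tibble `criterion, field, start, end, text`), `notes`,
#'   `coded_at`, `lexicon_version`.
#' @export
code_article_auto <- function(article, lexicon, registry = NULL,
                              coded_at = as.POSIXct("1970-01-01", tz = "UTC")) {
  ctx <- detect_context(article)
  criteria <- load_criteria()
  codes <- setNames(integer(20), criterion_codes())
  evs <- list()
  needs_manual <- character()
  for (code in criterion_codes()) {
    mode <- criteria$detection_mode[criteria$code == code]
    if (mode == "manual_only") { needs_manual <- c(needs_manual, code); next }
    res <- detect_one(ctx, code, lexicon, registry)
    if (isTRUE(res$needs_manual)) needs_manual <- c(needs_manual, code)
    codes[[code]] <- res$code
    if (res$code == 1L && nrow(res$evidence) > 0L)
      evs[[code]] <- dplyr::mutate(res$evidence, criterion = code, .before = 1L)
  }
  if (codes[["P1"]] == 0L && codes[["P2"]] == 1L) {  # structural guard
    codes[["P2"]] <- 0L
    evs[["P2"]] <- NULL
  }
  evidence <- if (length(evs) > 0L) dplyr::bind_rows(evs) else
    tibble::tibble(criterion = character(), field = character(),
                   start = integer(), end = integer(), text = character())
  coding_record(article_id = as.character(ctx$article_id %||% NA_character_),
                coder_id = "auto", codes = codes, evidence = evidence,
                coded_at = coded_at,
                notes = if (length(needs_manual) > 0L)
                  paste0("needs_manual:", paste(needs_manual, collapse = ",")) else "",
                lexicon_version = lexicon$version)
}

#' Auto-code every article of a corpus
#'
#' @param x An `mrs_corpus`.
#' @inheritParams code_article_auto
#' @return A list of `mrs_coding` records, one per article, in corpus order.
#' @seealso [coding_table()] to flatten records into the wide coding-sheet
#'   shape used by scoring.
#' @export
code_corpus_auto <- function(x, lexicon, registry = NULL,
                             coded_at = as.POSIXct("1970-01-01", tz = "UTC")) {
  stopifnot(inherits(x, "mrs_corpus"))
  lapply(seq_len(nrow(x)), function(i)
    code_article_auto(x[i, , drop = FALSE], lexicon, registry, coded_at = coded_at))
}
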