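#' Text matching primitives
#'
#' All rubric detection is span-based matching of lowercase lexicon phrases
#' against article text. Matching is case-insensitive and token-boundary
#' anchored: a phrase matches only where it is not embedded in a longer
#' alphanumeric token, so "suicide" never matches inside "suicidal".
#' Internal whitespace in a phrase matches any whitespace run.
#'
#' @name textmatch
#' @keywords internal
NULL

# regex for one phrase, token-boundary anchored. Phrases may themselves be
# regular expressions when wrapped in re:<pattern> (used for phone numbers).
phrase_regex <- function(phrase) {
  if (startsWith(phrase, "re:")) {
    return(substring(phrase, 4L))
  }
  esc <- stringr::str_replace_all(phrase, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
  esc <- stringr::str_replace_all(esc, "\\s+", "\\\\s+")
  paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
}

# one alternation regex for a whole phrase list, cached per list; plain
# phrases are ordered longest-first so the leftmost-first alternation
# prefers the longest entry at a position ("police officers" over "police")
.rx_cache <- new.env(parent = emptyenv())

phrases_regex <- function(phrases) {
  key <- paste(phrases, collapse = "\x1f")
  hit <- .rx_cache[[key]]
  if (!is.null(hit)) return(hit)
  plain <- phrases[!startsWith(phrases, "re:")]
  raw <- substring(phrases[startsWith(phrases, "re:")], 4L)
  alts <- character()
  if (length(plain) > 0L) {
    plain <- plain[order(-nchar(plain))]
    esc <- stringr::str_replace_all(plain, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
    esc <- stringr::str_replace_all(esc, "\\s+", "\\\\s+")
    alts <- paste0("(?<![A-Za-z0-9])(?:", paste(esc, collapse = "|"), ")(?![A-Za-z0-9])")
  }
  rx <- paste0("(?:", c(alts, raw), ")", collapse = "|")
  .rx_cache[[key]] <- rx
  rx
}

#' Locate lexicon phrase matches in a text field
#'
#' @param text character scalar (may be empty).
#' @param phrases character vector of lowercase phrases or `re:` patterns.
#' @return tibble with columns `phrase` (matched text, lowercased and
#'   whitespace-squished — for plain entries this is the lexicon entry
#'   itself), `start`, `end`, `text` (matched substring), ordered by start
#'   position; zero rows when nothing matches. Matches do not overlap: the
#'   longest entry wins at each position.
#' @keywords internal
match_phrases <- function(text, phrases) {
  if (!is_scalar_chr(text) || !nzchar(text) || length(phrases) == 0L)
    return(empty_match())
  loc <- stringr::str_locate_all(
    text, stringr::regex(phrases_regex(phrases), ignore_case = TRUE))[[1]]
  if (nrow(loc) == 0L) return(empty_match())
  matched <- stringr::str_sub(text, loc[, 1], loc[, 2])
  tibble::new_tibble(list(phrase = stringr::str_squish(tolower(matched)),
                          start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
                          text = matched), nrow = nrow(loc))
}

empty_match <- function() {
  tibble::new_tibble(list(phrase = character(), start = integer(),
                          end = integer(), text = character()), nrow = 0L)
}

# TRUE iff any phrase matches
any_phrase <- function(text, phrases) {
  if (!is_scalar_chr(text) || !nzchar(text) || length(phrases) == 0L) return(FALSE)
  stringr::str_detect(text, stringr::regex(phrases_regex(phrases), ignore_case = TRUE))
}

# merge overlapping [start,end] spans for evidence reporting; matched text is
# re-extracted from the source field so merged spans stay faithful to it
merge_spans <- function(spans, text) {
  if (nrow(spans) <= 1L) return(spans)
  spans <- dplyr::arrange(spans, .data$start, .data$end)
  keep <- rep(TRUE, nrow(spans))
  cur <- 1L
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans$start[i] <= spans$end[cur]) {
      spans$end[cur] <- max(spans$end[cur], spans$end[i])
      keep[i] <- FALSE
    } else cur <- i
  }
  spans <- spans[keep, , drop = FALSE]
  spans$text <- stringr::str_sub(text, spans$start, spans$end)
  spans
}

#' Split text into sentences
#'
#' Deterministic rule-based splitter: sentences end at runs of `.`, `!` or
#' `?` followed by whitespace or end of text. Common abbreviations are not
#' special-cased; the rule is intentionally simple so results are
#' reproducible across runs and platforms.
#'
#' @param text character scalar.
#' @return tibble with columns `sentence`, `start`, `end` (character offsets
#'   into `text`, 1-based inclusive).
#' @export
split_sentences <- function(text) {
  empty <- tibble::new_tibble(list(sentence = character(), start = integer(),
                                   end = integer()), nrow = 0L)
  if (!is_scalar_chr(text) || !nzchar(trimws(text))) return(empty)
  # positions just after sentence-final punctuation
  ends <- stringr::str_locate_all(text, "[.!?]+(?=\\s|$)")[[1]][, 2]
  bounds <- unique(c(ends, nchar(text)))
  starts <- c(1L, head(bounds, -1L) + 1L)
  out <- tibble::tibble(start = as.integer(starts), end = as.integer(bounds))
  out$sentence <- stringr::str_sub(text, out$start, out$end)
  # drop whitespace-only fragments, trim leading space from offsets
  keep <- nzchar(trimws(out$sentence))
  out <- out[keep, , drop = FALSE]
  lead <- nchar(out$sentence) - nchar(stringr::str_trim(out$sentence, "left"))
  out$start <- out$start + as.integer(lead)
  out$sentence <- stringr::str_sub(text, out$start, out$end)
  out[, c("sentence", "start", "end")]
}
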