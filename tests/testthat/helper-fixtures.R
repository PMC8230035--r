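# Shared fixtures: lexicon/registry loaded once; article builders; a cached
# medium synthetic run reused by the acceptance-scale tests.

.fixtures <- new.env(parent = emptyenv())

test_lexicon <- function() {
  if (is.null(.fixtures$lex)) .fixtures$lex <- read_lexicon()
  .fixtures$lex
}

test_registry <- function() {
  if (is.null(.fixtures$reg)) .fixtures$reg <- read_helpline_registry()
  .fixtures$reg
}

make_article <- function(body = "", headline = "", id = "a1",
                         newspaper = "The Daily", date = "2020-04-15", ...) {
  tibble::tibble(article_id = id, newspaper = newspaper,
                 publication_date = as.Date(date), headline = headline,
                 body = body, ...)
}

make_corpus <- function(bodies, newspaper = "The Daily", ...) {
  corpus(tibble::tibble(article_id = paste0("a", seq_along(bodies)),
                        newspaper = newspaper,
                        publication_date = as.Date("2020-04-15"),
                        headline = "", body = bodies, ...))
}

# random valid corpus for round-trip properties
random_corpus <- function(n, seed) {
  set.seed(seed)
  words <- c("city", "report", "family", "street", "house", "night", "morning")
  rand_text <- function() paste(sample(words, sample(3:8, 1), replace = TRUE),
                                collapse = " ")
  has_photo <- stats::runif(n) < 0.3
  kinds <- lapply(has_photo, function(h)
    if (h && stats::runif(1) < 0.7) sample(c("deceased", "location", "method"),
                                           sample(1:2, 1)) else character())
  corpus(tibble::tibble(
    article_id = sprintf("r%03d", seq_len(n)),
    newspaper = sample(c("Paper A", "Paper B"), n, replace = TRUE),
    publication_date = as.Date("2020-04-01") + sample(0:89, n, replace = TRUE),
    edition = ifelse(stats::runif(n) < 0.5, "City", NA_character_),
    page_number = ifelse(stats::runif(n) < 0.8, sample(1:20, n, replace = TRUE),
                         NA_integer_),
    continues_from_front_page = stats::runif(n) < 0.1,
    headline = vapply(seq_len(n), function(i) rand_text(), character(1)),
    body = vapply(seq_len(n), function(i)
      paste(rand_text(), if (stats::runif(1) < 0.3) "\nsecond line" else ""),
      character(1)),
    has_photo = has_photo,
    photo_kinds = kinds,
    url = ifelse(stats::runif(n) < 0.4, "https://example.org/x", NA_character_)))
}

# one synthetic run (generate + screen + auto-code the case articles),
# computed once and shared across the heavier tests
synthetic_run <- function(n = 1000, seed = 20260923) {
  key <- paste0("run_", n, "_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  lex <- test_lexicon()
  res <- generate_corpus(generator_config(n_articles = n, seed = seed), lex)
  scr <- screen_corpus(res$corpus, screening_config(lexicon = lex))
  case_ids <- res$truth$article_id[
    res$truth$screening_category %in% c("included", "below_half_content")]
  xs <- res$corpus[res$corpus$article_id %in% case_ids, , drop = FALSE]
  recs <- code_corpus_auto(xs, lex, test_registry())
  out <- list(corpus = res$corpus, truth = res$truth, screening = scr,
              case_corpus = xs, records = recs, codes = coding_table(recs))
  .fixtures[[key]] <- out
  out
}

# quick coding record from a named subset of criteria set to 1
codes_with <- function(on = character()) {
  v <- stats::setNames(integer(20), criterion_codes())
  v[on] <- 1L
  v
}
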