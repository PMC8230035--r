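#' Scoring and aggregation
#'
#' Turns final codings into article scores (per-polarity sums on 0-10
#' scales), per-newspaper mean (SD) summaries, criterion frequency tables,
#' and period-over-period comparisons.
#'
#' @name scoring
NULL

# extract the named 20-code vector from any coding-ish object
final_codes_of <- function(x) {
  if (inherits(x, "mrs_coding")) return(x$codes)
  if (inherits(x, "mrs_reconciled")) return(x$final_codes)
  if (is.data.frame(x) && nrow(x) == 1L)
    return(setNames(as.integer(unlist(x[, criterion_codes()])), criterion_codes()))
  if (is.numeric(x) && all(criterion_codes() %in% names(x)))
    return(x[criterion_codes()])
  stop_mrscore("cannot extract criterion codes from object", "mrscore_scoring_error")
}

article_id_of <- function(x) {
  if (inherits(x, c("mrs_coding", "mrs_reconciled"))) return(x$article_id)
  if (is.data.frame(x) && "article_id" %in% names(x)) return(as.character(x$article_id[1]))
  NA_character_
}

#' Score one coding
#'
#' The positive score is the sum of the ten positive codes, the negative
#' score the sum of the ten negative codes; both live on 0-10 scales (10 is
#' best on the positive scale, 0 is best on the negative scale). A
#' reconciliation with unresolved discrepancies cannot be scored unless
#' `permissive = TRUE`, in which case unresolved criteria contribute 0 to
#' their polarity's sum and the affected criteria are listed in the result.
#'
#' @param coding An `mrs_coding`, an `mrs_reconciled`, a one-row wide
#'   coding tibble, or a named 0/1 vector over [criterion_codes()].
#' @param permissive Allow scoring in the presence of unresolved codes.
#' @return One-row tibble `article_id, positive_score, negative_score`
#'   (plus `unresolved` listing skipped criteria when permissive scoring
#'   engaged them).
#' @examples
#' rec <- coding_record("a1", "auto",
#'   setNames(c(1, 0, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
#'            criterion_codes()))
#' score_article(rec)
#' @export
score_article <- function(coding, permissive = FALSE) {
  codes <- final_codes_of(coding)
  unresolved <- names(codes)[is.na(codes)]
  if (length(unresolved) > 0L && !permissive)
    stop_mrscore(paste0("article '", article_id_of(coding),
                        "' has unresolved discrepancies on: ",
                        paste(unresolved, collapse = ", "),
                        " (resolve them or score permissively)"),
                 "mrscore_scoring_error")
  tibble::tibble(
    article_id = article_id_of(coding),
    positive_score = as.integer(sum(codes[positive_codes()], na.rm = TRUE)),
    negative_score = as.integer(sum(codes[negative_codes()], na.rm = TRUE)),
    unresolved = paste(unresolved, collapse = ","))
}

#' Score a set of codings
#'
#' @param codings List of coding objects accepted by [score_article()], or
#'   a wide coding tibble (one row per article).
#' @inheritParams score_article
#' @return Tibble `article_id, positive_score, negative_score, unresolved`.
#' @export
score_articles <- function(codings, permissive = FALSE) {
  if (is.data.frame(codings))
    codings <- lapply(seq_len(nrow(codings)), function(i) codings[i, , drop = FALSE])
  if (inherits(codings, c("mrs_coding", "mrs_reconciled"))) codings <- list(codings)
  bad <- character()
  rows <- lapply(codings, function(x) {
    tryCatch(score_article(x, permissive = permissive),
             mrscore_scoring_error = function(e) {
               bad <<- c(bad, article_id_of(x)); NULL
             })
  })
  if (length(bad) > 0L)
    stop_mrscore(paste0("unresolved discrepancies block scoring for article(s): ",
                        paste(bad, collapse = ", ")), "mrscore_scoring_error")
  dplyr::bind_rows(rows)
}

#' Per-newspaper score summaries
#'
#' Groups article scores by newspaper and reports arithmetic mean and
#' sample (n-1) standard deviation of the positive and negative scores,
#' plus a pooled `Total` row computed over all articles (article-weighted,
#' not an unweighted mean of newspaper means). SD is `NA` for newspapers
#' with a single article.
#'
#' @param scores Tibble from [score_articles()].
#' @param x The `mrs_corpus` the scores refer to (source of the
#'   article-to-newspaper mapping).
#' @return Tibble `newspaper, n_articles, positive_mean, positive_sd,
#'   negative_mean, negative_sd`; `Total` is the last row.
#' @export
summarize_by_newspaper <- function(scores, x) {
  stopifnot(inherits(x, "mrs_corpus"))
  unknown <- setdiff(scores$article_id, x$article_id)
  if (length(unknown) > 0L)
    stop_mrscore(paste0("score(s) reference articles absent from the corpus: ",
                        paste(unknown, collapse = ", ")), "mrscore_scoring_error")
  joined <- dplyr::inner_join(scores,
                              tibble::tibble(article_id = x$article_id,
                                             newspaper = x$newspaper),
                              by = "article_id")
  one <- function(df, label) {
    tibble::tibble(newspaper = label, n_articles = nrow(df),
                   positive_mean = mean(df$positive_score),
                   positive_sd = if (nrow(df) >= 2L) stats::sd(df$positive_score) else NA_real_,
                   negative_mean = mean(df$negative_score),
                   negative_sd = if (nrow(df) >= 2L) stats::sd(df$negative_score) else NA_real_)
  }
  per <- joined |>
    dplyr::group_by(.data$newspaper) |>
    dplyr::group_map(~ one(.x, .y$newspaper)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per, one(joined, "Total"))
}

#' Criterion frequency table
#'
#' For each of the 20 criteria: the number of articles coded 1 and the
#' percentage of the total, rounded half-up to two decimals. Rows are
#' ordered by descending count within polarity (positive block first).
#'
#' @param codings As for [score_articles()].
#' @param total Denominator; defaults to the number of codings and must
#'   equal it when supplied.
#' @return Tibble `polarity, code, name, count, percent` with attribute
#'   `total_articles`.
#' @export
frequency_table <- function(codings, total = NULL) {
  if (is.data.frame(codings))
    codings <- lapply(seq_len(nrow(codings)), function(i) codings[i, , drop = FALSE])
  if (inherits(codings, c("mrs_coding", "mrs_reconciled"))) codings <- list(codings)
  if (length(codings) == 0L)
    stop_mrscore("frequency_table requires at least one coding", "mrscore_scoring_error")
  total <- total %||% length(codings)
  if (total != length(codings))
    stop_mrscore("total must equal the number of codings", "mrscore_scoring_error")
  mat <- do.call(rbind, lapply(codings, final_codes_of))
  counts <- colSums(mat, na.rm = TRUE)
  reg <- load_criteria()
  out <- tibble::tibble(polarity = reg$polarity, code = reg$code, name = reg$name,
                        count = as.integer(counts[reg$code]),
                        percent = unname(round_half_up(100 * counts[reg$code] / total, 2)))
  out <- dplyr::bind_rows(
    dplyr::arrange(out[out$polarity == "positive", ], dplyr::desc(.data$count)),
    dplyr::arrange(out[out$polarity == "negative", ], dplyr::desc(.data$count)))
  attr(out, "total_articles") <- as.integer(total)
  out
}

#' Compare two scoring periods
#'
#' Signed period-over-period differences (B minus A) in newspaper mean
#' scores and criterion prevalences, for quarter-on-quarter tracking of
#' reporting practice.
#'
#' @param a,b Each a list with elements `summaries` (from
#'   [summarize_by_newspaper()]) and `frequency` (from
#'   [frequency_table()]); optionally `registry_version`.
#' @return List with `newspapers` (tibble `newspaper, n_a, n_b,
#'   positive_mean_delta, negative_mean_delta, status`; status flags
#'   newspapers present in only one period) and `criteria` (tibble
#'   `code, name, percent_a, percent_b, percent_delta`).
#' @export
compare_periods <- function(a, b) {
  va <- a$registry_version %||% "1"
  vb <- b$registry_version %||% "1"
  if (!identical(va, vb))
    stop_mrscore(paste0("criterion registry versions differ: ", va, " vs ", vb),
                 "mrscore_scoring_error")
  sa <- a$summaries; sb <- b$summaries
  news <- dplyr::full_join(
    sa[, c("newspaper", "n_articles", "positive_mean", "negative_mean")],
    sb[, c("newspaper", "n_articles", "positive_mean", "negative_mean")],
    by = "newspaper", suffix = c("_a", "_b"))
  news <- dplyr::transmute(news, newspaper = .data$newspaper,
    n_a = .data$n_articles_a, n_b = .data$n_articles_b,
    positive_mean_delta = .data$positive_mean_b - .data$positive_mean_a,
    negative_mean_delta = .data$negative_mean_b - .data$negative_mean_a,
    status = dplyr::case_when(is.na(.data$n_articles_a) ~ "only_in_b",
                              is.na(.data$n_articles_b) ~ "only_in_a",
                              TRUE ~ "both"))
  fa <- a$frequency; fb <- b$frequency
  crit <- dplyr::inner_join(fa[, c("code", "name", "percent")],
                            fb[, c("code", "percent")],
                            by = "code", suffix = c("_a", "_b"))
  crit$percent_delta <- crit$percent_b - crit$percent_a
  list(newspapers = news, criteria = crit)
}

#' Write a summary or frequency tibble as aligned text
#'
#' @param df A tibble.
#' @param path Output file; `NULL` returns the lines.
#' @return Lines invisibly (or visibly when `path` is `NULL`).
#' @export
write_aligned <- function(df, path = NULL) {
  mat <- rbind(names(df), apply(as.data.frame(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.2f", col) else as.character(col)
  })), 2, as.character))
  widths <- apply(nchar(mat), 2, max)
  lines <- apply(mat, 1, function(r)
    paste(mapply(function(s, w) formatC(s, width = w, flag = "-"), r, widths),
          collapse = "  "))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
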