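#' Coding records
#'
#' One coder's 20 binary codes for one article. Records come from the
#' automatic detectors ([code_article_auto()], `coder_id = "auto"`) or from
#' manual coding sheets ([ingest_manual_codes()]). Every record satisfies
#' P2 <= P1: help-seeking information cannot be verified operational unless
#' it is present.
#'
#' @param article_id Article identifier.
#' @param coder_id `"auto"` or a human coder identifier.
#' @param codes Named integer vector over all of [criterion_codes()], values
#'   0/1.
#' @param evidence Tibble `criterion, field, start, end, text` (rows only
#'   for criteria coded 1; empty for manual records).
#' @param coded_at Timestamp.
#' @param notes Free text.
#' @param lexicon_version Lexicon version for auto records, `NA` otherwise.
#' @return An `mrs_coding` list.
#' @export
coding_record <- function(article_id, coder_id, codes,
                          evidence = NULL,
                          coded_at = as.POSIXct("1970-01-01", tz = "UTC"),
                          notes = "", lexicon_version = NA_character_) {
  codes <- codes[criterion_codes()]
  names(codes) <- criterion_codes()
  codes <- as.integer(codes)
  names(codes) <- criterion_codes()
  if (anyNA(codes) || !all(codes %in% c(0L, 1L)))
    stop_mrscore(paste0("codes for article '", article_id,
                        "' must be 0/1 for all 20 criteria"), "mrscore_coding_error")
  if (codes[["P2"]] == 1L && codes[["P1"]] == 0L)
    stop_mrscore(paste0("inconsistent codes for article '", article_id,
                        "': P2 = 1 requires P1 = 1"), "mrscore_coding_error")
  evidence <- evidence %||% tibble::tibble(criterion = character(), field = character(),
                                           start = integer(), end = integer(),
                                           text = character())
  if (nrow(evidence) > 0L) {
    zero <- intersect(unique(evidence$criterion), names(codes)[codes == 0L])
    if (length(zero) > 0L)
      stop_mrscore(paste0("evidence recorded for criteria coded 0: ",
                          paste(zero, collapse = ", ")), "mrscore_coding_error")
  }
  structure(list(article_id = article_id, coder_id = coder_id, codes = codes,
                 evidence = evidence, coded_at = coded_at, notes = notes,
                 lexicon_version = lexicon_version),
            class = "mrs_coding")
}

#' @export
print.mrs_coding <- function(x, ...) {
  on <- names(x$codes)[x$codes == 1L]
  cat("<mrs_coding> article ", x$article_id, ", coder ", x$coder_id,
      ": score (", sum(x$codes[positive_codes()]), "+, ",
      sum(x$codes[negative_codes()]), "-)",
      if (length(on) > 0L) paste0(" [", paste(on, collapse = " "), "]"), "\n", sep = "")
  invisible(x)
}

#' Flatten coding records to the wide coding-sheet shape
#'
#' @param records A list of `mrs_coding` records (or a single record).
#' @return Tibble with columns `article_id, coder_id, P1..P10, N1..N10,
#'   notes` — the same shape as a manual coding sheet.
#' @export
coding_table <- function(records) {
  if (inherits(records, "mrs_coding")) records <- list(records)
  dplyr::bind_rows(lapply(records, function(r) {
    tibble::as_tibble(c(list(article_id = r$article_id, coder_id = r$coder_id),
                        as.list(r$codes), list(notes = r$notes)))
  }))
}

#' Ingest a manual coding sheet
#'
#' Sheets are CSV with one row per (article, coder): columns `article_id`,
#' `coder_id`, `P1..P10`, `N1..N10` and optional `notes`. Cells must be 0
#' or 1; a row with P2 = 1 but P1 = 0 is rejected as inconsistent.
#'
#' @param path CSV file path.
#' @return A list of `mrs_coding` records.
#' @export
ingest_manual_codes <- function(path) {
  if (!file.exists(path)) stop_mrscore(paste0("no such file: ", path), "mrscore_io_error")
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("article_id", "coder_id", criterion_codes())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_mrscore(paste0("coding sheet missing column(s): ", paste(miss, collapse = ", ")),
                 "mrscore_coding_error")
  unknown <- setdiff(names(df), c(need, "notes"))
  if (length(unknown) > 0L)
    stop_mrscore(paste0("unknown criterion column(s): ", paste(unknown, collapse = ", ")),
                 "mrscore_coding_error")
  if (anyNA(df$article_id) || any(!nzchar(df$article_id)))
    stop_mrscore("coding sheet has rows with missing article_id", "mrscore_coding_error")
  lapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(df[i, criterion_codes()])
    bad <- criterion_codes()[!vals %in% c("0", "1")]
    if (length(bad) > 0L)
      stop_mrscore(paste0("row ", i, " (article '", df$article_id[i],
                          "'): non-binary cell(s) in ", paste(bad, collapse = ", ")),
                   "mrscore_coding_error")
    coding_record(article_id = df$article_id[i], coder_id = df$coder_id[i],
                  codes = setNames(as.integer(vals), criterion_codes()),
                  notes = if ("notes" %in% names(df)) df$notes[i] %||% "" else "")
  })
}

#' Write coding records as JSONL
#'
#' One JSON object per record; evidence spans are embedded as arrays.
#'
#' @param records List of `mrs_coding`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_codings <- function(records, path) {
  if (inherits(records, "mrs_coding")) records <- list(records)
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(list(
      article_id = r$article_id, coder_id = r$coder_id, codes = as.list(r$codes),
      evidence = r$evidence, coded_at = format(r$coded_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      notes = r$notes, lexicon_version = r$lexicon_version),
      auto_unbox = TRUE, dataframe = "rows", na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read coding records from JSONL
#'
#' @param path File written by [write_codings()].
#' @return List of `mrs_coding`.
#' @export
read_codings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    evidence <- if (length(r$evidence) > 0L) tibble::as_tibble(r$evidence) else NULL
    coding_record(article_id = r$article_id, coder_id = r$coder_id,
                  codes = setNames(as.integer(unlist(r$codes[criterion_codes()])),
                                   criterion_codes()),
                  evidence = evidence,
                  coded_at = as.POSIXct(r$coded_at, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  notes = r$notes %||% "",
                  lexicon_version = r$lexicon_version %||% NA_character_)
  })
}

#' Reconcile two coders' records for one article
#'
#' Dual independent coding is reconciled criterion by criterion: agreeing
#' codes are copied to the final coding; disagreements are resolved by the
#' chosen strategy. `"flag"` leaves them unresolved for a human decision
#' (such records block scoring unless scoring is run permissively);
#' `"conservative"` takes the stricter reading — 0 for a positive
#' criterion, 1 for a negative one — so a disputed protective practice is
#' not credited and a disputed harmful practice is not excused.
#'
#' @param rec_a,rec_b `mrs_coding` records for the same article from
#'   different coders.
#' @param strategy `"flag"`, `"prefer_A"`, `"prefer_B"` or
#'   `"conservative"`.
#' @param resolved_by Identifier recorded on the reconciliation.
#' @return An `mrs_reconciled` list: `article_id`, `final_codes` (named
#'   integer vector, `NA` where unresolved), `discrepancies` (tibble
#'   `criterion, code_a, code_b, resolution`), `resolved_by`.
#' @export
reconcile_codings <- function(rec_a, rec_b,
                              strategy = c("flag", "prefer_A", "prefer_B", "conservative"),
                              resolved_by = "") {
  strategy <- match.arg(strategy)
  stopifnot(inherits(rec_a, "mrs_coding"), inherits(rec_b, "mrs_coding"))
  if (!identical(rec_a$article_id, rec_b$article_id))
    stop_mrscore(paste0("article_id mismatch: '", rec_a$article_id, "' vs '",
                        rec_b$article_id, "'"), "mrscore_coding_error")
  if (identical(rec_a$coder_id, rec_b$coder_id))
    stop_mrscore("reconciliation requires two distinct coders", "mrscore_coding_error")
  a <- rec_a$codes; b <- rec_b$codes
  final <- a
  disagree <- criterion_codes()[a != b]
  resolution <- character(length(disagree))
  for (k in seq_along(disagree)) {
    cr <- disagree[k]
    final[[cr]] <- switch(strategy,
      flag = NA_integer_,
      prefer_A = a[[cr]],
      prefer_B = b[[cr]],
      conservative = if (startsWith(cr, "P")) 0L else 1L)
    resolution[k] <- switch(strategy, flag = "unresolved", prefer_A = "A",
                            prefer_B = "B", conservative = "consensus_value")
  }
  # strategies may break the P2<=P1 coupling (e.g. prefer_B on P2 only);
  # restore it in the strict direction
  if (!is.na(final[["P1"]]) && !is.na(final[["P2"]]) &&
      final[["P1"]] == 0L && final[["P2"]] == 1L) final[["P2"]] <- 0L
  structure(list(article_id = rec_a$article_id, final_codes = final,
                 discrepancies = tibble::tibble(criterion = disagree,
                                                code_a = a[disagree], code_b = b[disagree],
                                                resolution = resolution),
                 resolved_by = resolved_by),
            class = "mrs_reconciled")
}

#' @export
print.mrs_reconciled <- function(x, ...) {
  cat("<mrs_reconciled> article ", x$article_id, ": ",
      nrow(x$discrepancies), " discrepancy(ies)",
      if (anyNA(x$final_codes)) " (unresolved)", "\n", sep = "")
  invisible(x)
}

#' Record a human resolution for a flagged discrepancy
#'
#' @param rec An `mrs_reconciled` with unresolved criteria.
#' @param values Named 0/1 vector, names are criterion codes to resolve.
#' @param resolved_by Identifier of the resolver.
#' @return The updated `mrs_reconciled`.
#' @export
resolve_discrepancies <- function(rec, values, resolved_by = "consensus") {
  stopifnot(inherits(rec, "mrs_reconciled"))
  for (cr in names(values)) {
    if (!cr %in% rec$discrepancies$criterion)
      stop_mrscore(paste0("criterion ", cr, " is not in dispute"), "mrscore_coding_error")
    rec$final_codes[[cr]] <- as.integer(values[[cr]])
    rec$discrepancies$resolution[rec$discrepancies$criterion == cr] <- "consensus_value"
  }
  if (!anyNA(rec$final_codes[c("P1", "P2")]) &&
      rec$final_codes[["P1"]] == 0L && rec$final_codes[["P2"]] == 1L)
    rec$final_codes[["P2"]] <- 0L
  rec$resolved_by <- resolved_by
  rec
}

#' Per-criterion inter-rater agreement
#'
#' Percent agreement and Cohen's kappa per criterion over paired records.
#' For criterion \eqn{c} with 2x2 confusion counts \eqn{a,b,c,d} (both 1 /
#' A-only / B-only / both 0, \eqn{n} pairs), observed agreement is
#' \eqn{p_o = (a+d)/n}, chance agreement \eqn{p_e} is the product of the
#' coder marginals, and \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. When
#' \eqn{p_e = 1} (degenerate marginals: a coder used a single code
#' throughout and so did the other), kappa is undefined and reported `NA`.
#'
#' @param pairs List of 2-element lists of `mrs_coding` records, or a pair
#'   of equal-length record lists given as `pairs` and `pairs_b`.
#' @param pairs_b Optional second record list aligned with `pairs`.
#' @return Tibble `criterion, n, percent_agreement, kappa`.
#' @export
interrater_agreement <- function(pairs, pairs_b = NULL) {
  if (!is.null(pairs_b)) {
    stopifnot(length(pairs) == length(pairs_b))
    pairs <- Map(list, pairs, pairs_b)
  }
  if (length(pairs) == 0L)
    stop_mrscore("agreement requires at least one pair of records", "mrscore_coding_error")
  a_mat <- do.call(rbind, lapply(pairs, function(p) p[[1]]$codes))
  b_mat <- do.call(rbind, lapply(pairs, function(p) p[[2]]$codes))
  n <- nrow(a_mat)
  out <- lapply(criterion_codes(), function(cr) {
    x <- a_mat[, cr]; y <- b_mat[, cr]
    po <- mean(x == y)
    p1a <- mean(x); p1b <- mean(y)
    pe <- p1a * p1b + (1 - p1a) * (1 - p1b)
    kappa <- if (isTRUE(all.equal(pe, 1))) NA_real_ else (po - pe) / (1 - pe)
    tibble::tibble(criterion = cr, n = n, percent_agreement = po, kappa = kappa)
  })
  dplyr::bind_rows(out)
}
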