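#' Load a rubric lexicon
#'
#' A lexicon is a named set of lowercase term lists, one per detector
#' purpose (criminalizing phrases, method terms, helpline name/phone
#' patterns, accept/reject mood terms, ...), with a version string. The
#' packaged default (`system.file("extdata", "lexicon_default.yaml",
#' package = "mrscore")`) seeds each list from the worked phrases of the
#' rubric item descriptions; it is this package's own resource and can be
#' replaced wholesale by pointing `path` at another YAML file of the same
#' shape.
#'
#' @param path Path to a lexicon YAML file, or `NULL` for the packaged
#'   default.
#' @return A list of character vectors with class `mrs_lexicon` and a
#'   `version` element.
#' @examples
#' lex <- read_lexicon()
#' lex$criminalizing_phrases
#' @export
read_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lexicon_default.yaml", package = "mrscore")
  lex <- yaml::read_yaml(path)
  validate_lexicon(lex)
  structure(lex, class = "mrs_lexicon")
}

required_lexicon_lists <- function() c(
  "case_terms", "criminalizing_phrases", "method_terms", "method_detail_terms",
  "site_terms", "location_prepositions", "single_factor_markers",
  "speculation_markers", "stressor_nouns", "reason_cues", "helpline_names",
  "helpline_phone_patterns", "mental_health_accept_terms",
  "mental_health_reject_terms", "substance_struggle_terms",
  "intoxication_only_terms", "expert_role_terms", "attribution_cues",
  "official_source_terms", "bare_source_phrases", "stat_markers",
  "myth_markers", "refutation_markers", "prevention_markers", "hope_markers",
  "grief_terms", "note_terms")

validate_lexicon <- function(lex) {
  if (!is_scalar_chr(lex$version %||% NA_character_))
    stop_mrscore("lexicon must carry a scalar 'version' string", "mrscore_lexicon_error")
  missing <- setdiff(required_lexicon_lists(), names(lex))
  if (length(missing) > 0L)
    stop_mrscore(paste0("lexicon is missing term lists: ",
                        paste(missing, collapse = ", ")), "mrscore_lexicon_error")
  for (nm in setdiff(names(lex), "version")) {
    entries <- unlist(lex[[nm]])
    plain <- entries[!startsWith(entries, "re:")]
    if (any(plain != tolower(plain)))
      stop_mrscore(paste0("lexicon list '", nm, "' contains non-lowercase entries"),
                   "mrscore_lexicon_error")
  }
  # accept/reject pairs must be disjoint as entries
  pairs <- list(c("mental_health_accept_terms", "mental_health_reject_terms"),
                c("substance_struggle_terms", "intoxication_only_terms"),
                c("official_source_terms", "bare_source_phrases"))
  for (p in pairs) {
    both <- intersect(unlist(lex[[p[1]]]), unlist(lex[[p[2]]]))
    if (length(both) > 0L)
      stop_mrscore(paste0("lexicon lists '", p[1], "' and '", p[2],
                          "' share entries: ", paste(both, collapse = ", ")),
                   "mrscore_lexicon_error")
  }
  invisible(lex)
}

#' @export
print.mrs_lexicon <- function(x, ...) {
  cat("<mrs_lexicon> version", x$version, "-",
      length(setdiff(names(x), "version")), "term lists\n")
  invisible(x)
}

#' Load a helpline registry
#'
#' The registry is a curated local list of crisis-support services
#' (name, phone, region, operational flag) used to verify that printed
#' help-seeking information is up to date (criterion P2). Verification is
#' always against this local file — never a live lookup — so coding is
#' deterministic.
#'
#' @param path Path to a registry CSV (`name,phone,region,operational`), or
#'   `NULL` for the packaged example registry.
#' @return A tibble with an added `phone_digits` column (digits only).
#' @export
read_helpline_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "helplines.csv", package = "mrscore")
  reg <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), phone = readr::col_character(),
    region = readr::col_character(), operational = readr::col_logical()))
  reg$phone_digits <- stringr::str_remove_all(reg$phone, "[^0-9]")
  reg
}
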