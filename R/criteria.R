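#' The 20-criterion reporting rubric
#'
#' The scorecard holds 10 positive criteria (P1..P10, protective practices
#' such as printing helpline information) and 10 negative criteria
#' (N1..N10, harmful practices such as naming the suicide method). Each is
#' coded 1 when present in an article and 0 when absent; the two scores are
#' the per-polarity sums, so each lives on a 0-10 scale. On the positive
#' scale 10 is best; on the negative scale 0 is best.
#'
#' @return A tibble with one row per criterion and columns
#'   \describe{
#'     \item{code}{`"P1"`..`"P10"`, `"N1"`..`"N10"`.}
#'     \item{polarity}{`"positive"` or `"negative"`.}
#'     \item{name}{Short rubric-item name.}
#'     \item{scope}{List column; each element a character vector drawn from
#'       `"headline"`, `"body"`, `"metadata"` — the article fields the
#'       criterion reads.}
#'     \item{detection_mode}{`"auto"`, `"hybrid"` or `"manual_only"`.
#'       `hybrid` criteria (P2: helpline verified operational) are
#'       auto-detectable only against a local helpline registry and are
#'       otherwise deferred to a human coder.}
#'   }
#' @examples
#' load_criteria()
#' @export
load_criteria <- function() {
  def <- function(code, name, scope, mode = "auto") {
    tibble::tibble(code = code,
                   polarity = if (startsWith(code, "P")) "positive" else "negative",
                   name = name, scope = list(scope), detection_mode = mode)
  }
  dplyr::bind_rows(
    def("P1",  "Presence of help-seeking information", "body"),
    def("P2",  "Help-seeking information is up to date and operational", "body", "hybrid"),
    def("P3",  "Links to poor mental health", "body"),
    def("P4",  "Links to drug/alcohol abuse", "body"),
    def("P5",  "Comments from mental health and suicide prevention experts", "body"),
    def("P6",  "Reduces stigma, highlights suicides are preventable", "body"),
    def("P7",  "Credible population-level suicide statistics", "body"),
    def("P8",  "Challenges popular myths", "body"),
    def("P9",  "Links to hopeful stories", "body"),
    def("P10", "Verified information and facts from official source", "body"),
    def("N1",  "Use of criminalizing language", c("headline", "body")),
    def("N2",  "Attention-grabbing headline", "headline"),
    def("N3",  "Method of suicide mentioned", c("headline", "body")),
    def("N4",  "Describes method in detail", "body"),
    def("N5",  "Discloses details of the suicide site", "body"),
    def("N6",  "Reduces reason to a single factor", "body"),
    def("N7",  "Accompanying photos", c("metadata")),
    def("N8",  "Contains information on grieving persons", "body"),
    def("N9",  "Publishes note or text", "body"),
    def("N10", "Article on the front page", c("metadata"))
  )
}

#' Criterion codes in canonical order
#'
#' @return Character vector `P1..P10, N1..N10`.
#' @export
criterion_codes <- function() c(paste0("P", 1:10), paste0("N", 1:10))

positive_codes <- function() paste0("P", 1:10)
negative_codes <- function() paste0("N", 1:10)
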