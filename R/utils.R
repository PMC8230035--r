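#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd setNames
NULL

# round half up (Table-style percentages); base round() is half-even
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# md5 of a file, empty string if absent
file_digest <- function(path) {
  if (!file.exists(path)) return("")
  unname(tools::md5sum(path))
}

stop_mrscore <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mrscore_error"))
}
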