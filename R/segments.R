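#' Couinaud segment codes
#'
#' The nine Couinaud segments are encoded as integers in label maps:
#' 1, 2, 3, 5, 6, 7, 8 for the like-named segments, and 41/42 for
#' segments 4a/4b (so a label map stays a single integer volume while
#' reports keep the nine-segment granularity). 0 is background.
#'
#' @return `segment_codes()` returns the nine codes in report order;
#'   `segment_names()` the matching display names ("1", ..., "4a", "4b", ...).
#' @export
segment_codes <- function() c(1L, 2L, 3L, 41L, 42L, 5L, 6L, 7L, 8L)

#' @rdname segment_codes
#' @export
segment_names <- function() c("1", "2", "3", "4a", "4b", "5", "6", "7", "8")

#' @param code integer vector of segment codes.
#' @rdname segment_codes
#' @export
segment_name <- function(code) {
  nm <- segment_names()[match(as.integer(code), segment_codes())]
  if (anyNA(nm)) cn_stop(sprintf("unknown segment code: %s",
                                 paste(code[is.na(nm)], collapse = ", ")),
                         "couinaud_unknown_code")
  nm
}

# Normalize user-facing segment identifiers ("4a", "4", 41, "7", ...) to
# integer codes; "4" expands to both 4a and 4b.
normalize_codes <- function(x) {
  if (length(x) == 0) return(integer(0))
  x <- as.character(unlist(x, use.names = FALSE))
  x <- trimws(x)
  out <- integer(0)
  for (xi in x) {
    code <- switch(tolower(xi),
                   "4a" = 41L, "4b" = 42L, "4" = c(41L, 42L),
                   suppressWarnings(as.integer(xi)))
    if (length(code) == 1 && (is.na(code) || !(code %in% segment_codes())))
      cn_stop(sprintf("unknown segment code: '%s'", xi), "couinaud_unknown_code")
    out <- c(out, code)
  }
  unique(out)
}

cn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "couinaud_error")))
}

cn_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "couinaud_warning")))
}
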