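#' Sentinel for the factual (observed) exposure level
#'
#' When standardizing, the exposure is normally set to a fixed level `x` for
#' every subject before averaging predictions.  Passing `FACTUAL` instead keeps
#' each subject's own observed exposure, so the standardized estimate is the
#' factual outcome probability p(Y = 1) (or, within a subset, the factual
#' probability in that subset).  This is a distinct sentinel object rather
#' than `NA`, so genuinely missing exposure values can never be confused with
#' a request for factual predictions.
#'
#' @format An object of class `factual_level`.
#' @examples
#' is_factual(FACTUAL)
#' is_factual(0)
#' @export
FACTUAL <- structure("<FACTUAL>", class = "factual_level")

#' @rdname FACTUAL
#' @param x object to test.
#' @return `is_factual()` returns `TRUE` if `x` is the `FACTUAL` sentinel.
#' @export
is_factual <- function(x) inherits(x, "factual_level")

#' @export
print.factual_level <- function(x, ...) {
  cat("<factual exposure level>\n")
  invisible(x)
}

#' @export
format.factual_level <- function(x, ...) "FACTUAL"

# Normalize a user-supplied set of exposure levels to a list, accepting the
# FACTUAL sentinel, the string "FACTUAL" (config surface), or atomic values.
normalize_levels <- function(x) {
  if (is_factual(x)) return(list(FACTUAL))
  if (!is.list(x)) x <- as.list(x)
  x <- lapply(x, function(v) {
    if (is_factual(v)) return(FACTUAL)
    if (is.character(v) && length(v) == 1L && v == "FACTUAL") return(FACTUAL)
    v
  })
  if (length(x) == 0L) stop("at least one exposure level must be requested")
  x
}

level_label <- function(v) {
  if (is_factual(v)) "factual" else as.character(v)
}
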