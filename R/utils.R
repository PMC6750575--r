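#' Report percentage formatter
#'
#' Formats a count ratio as a percentage at a fixed number of decimal
#' places, the way summary sentences in a report quote them (e.g. 45 of
#' 72 tests -> "62.5%").
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal places (default 1).
#' @return character scalar like `"62.5%"`.
#' @export
format_percent <- function(num, den, digits = 1) {
  if (den <= 0) stop("denominator must be positive")
  paste0(formatC(round(100 * num / den, digits), format = "f",
                 digits = digits), "%")
}

#' @rdname format_percent
#' @return `percent_value()` returns the rounded numeric percentage.
#' @export
percent_value <- function(num, den, digits = 1) {
  if (den <= 0) stop("denominator must be positive")
  round(100 * num / den, digits)
}
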