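#' Round half away from zero
#'
#' Published financing tables conventionally round 0.5 up, whereas base
#' [round()] rounds to even. All reporting-time rounding in this package goes
#' through this helper so printed cells can be reproduced digit for digit.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(94.105, 2)  # 94.11
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format an amount the way financing tables print it
#'
#' Thousands separators, fixed decimals, `"-"` for `NA` (an absent cell, which
#' is distinct from a true zero).
#'
#' @param x Numeric vector (may contain `NA` for absent cells).
#' @param digits Decimal places.
#' @return Character vector.
#' @keywords internal
format_amount <- function(x, digits = 0) {
  out <- ifelse(
    is.na(x),
    "-",
    formatC(round_half_up(x, digits), format = "f", digits = digits, big.mark = ",")
  )
  as.character(out)
}

# stop() with a classed condition so callers/tests can distinguish error kinds
fp_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "fpfundflow_error"))
}
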