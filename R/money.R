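#' Round an amount to euro cents
#'
#' Commercial (half-up) rounding to two decimals, used at every reporting
#' boundary. Internal arithmetic is carried at full double precision; only
#' displayed or exported money is cent-rounded, so category sums stay exact.
#'
#' @param x Numeric vector of euro amounts (non-negative in this package).
#' @param digits Number of decimal places (default 2, i.e. cents).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_cents(c(2060.005, 691.0049))
#' @export
round_cents <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against binary representation of exact half-cents
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format euro amounts for display
#'
#' @param x Numeric vector.
#' @return Character vector with two decimals, dot separator, no symbol.
#' @keywords internal
format_eur <- function(x) {
  formatC(round_cents(x), format = "f", digits = 2)
}

# shared assertion helper: scalar finite non-negative number
check_money <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and >= 0", what), call. = FALSE)
  }
  invisible(x)
}
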