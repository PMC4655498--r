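#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Deterministic commercial rounding used for all reported integers and
#' whole-dollar amounts: 0.5 rounds to 1, -0.5 rounds to -1. Base R's
#' `round()` uses banker's rounding, which is not the convention of the
#' reported tables (computation stays unrounded throughout the engines;
#' integers appear only in reports).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(-3.648)  # -4
#' round_half_away(0.5)     # 1
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

match_bound <- function(bound) {
  match.arg(bound, c("point", "low", "high"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @importFrom stats qnorm rbinom rnorm sd setNames
#' @importFrom utils read.csv write.csv modifyList
NULL
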