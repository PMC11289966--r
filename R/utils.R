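# shared numeric helpers

#' Round half-up at a fixed number of decimals
#'
#' Presentation-layer rounding used when rendering percentages the way the
#' source tables print them (half-up, 1 decimal place by default). All
#' internal computation keeps full precision; this is applied only when
#' formatting or when comparing against printed values.
#'
#' @param x numeric vector.
#' @param dp decimal places.
#' @return `x` rounded half-up at `dp` decimals.
#' @export
round_half_up <- function(x, dp = 1) {
  s <- 10^dp
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# format "mean (lower, upper)" in percent at dp decimals
format_pct_ci <- function(mean, lower, upper, dp = 1) {
  f <- function(v) formatC(round_half_up(100 * v, dp), format = "f", digits = dp)
  sprintf("%s (%s, %s)", f(mean), f(lower), f(upper))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
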