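#' Round half away from zero
#'
#' Decimal rounding with ties going half-up (4.675 -> 4.68), the convention
#' used for all displayed weights, scores and value estimates. Base `round()`
#' rounds half to even, which does not match tabulated committee output.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample SD with the n-1 denominator; 0 for fewer than two observations
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x)
}
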