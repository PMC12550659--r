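#' Round half away from zero
#'
#' Commercial ("half up") rounding, as used for treated-patient counts and
#' reported percentages throughout the cascade. Differs from [base::round()],
#' which rounds half to even (so `round(0.5)` is 0 but `round_half_up(0.5)`
#' is 1).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))   # 1 2 3
#' round_half_up(0.5676, 2)          # 0.57
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("treatcascade_invalid_input", "error")))
}
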