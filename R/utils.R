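deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Fixed-tie-break rounding used everywhere real-valued pixels or table
#' entries are committed to a grid: ties go away from zero (`-0.5 -> -1`,
#' `100.5 -> 101`), independent of the platform's default banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(c(0.4, -0.5, 100.5))
#' round_half_away(91.449, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}
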