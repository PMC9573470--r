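## Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Printed tables in the radar/physiology literature round `x.x5` upward;
#' base [round()] rounds to even. This helper reproduces the printed style.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(6.25, 1) # 6.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

next_power_of_two <- function(n) {
  2^ceiling(log2(max(n, 1)))
}

## Round to the nearest multiple of 2^-bits, ties away from zero.
round_to_grid <- function(x, bits) {
  round_half_up(x * 2^bits) / 2^bits
}

## Validate a scalar numeric argument.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
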