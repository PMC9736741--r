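`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## normalized key for case/whitespace-insensitive species & region matching
norm_key <- function(x) gsub("\\s+", " ", trimws(tolower(as.character(x))))

#' Round half away from zero
#'
#' Commercial rounding used for the presentation layer of valuation reports
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.345, 2)  # 2.35
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon counters binary representation error in abs(x) * p
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## exact molar mass ratio CO2 : C, used everywhere a pool is converted
co2_per_c <- function() 44 / 12

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}
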