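#' Round half away from zero
#'
#' Rounding convention used for all reported percentages and p-values:
#' ties go up in magnitude (5.85 -> 5.9), unlike [base::round()]'s
#' round-half-even. This matches how figure legends print values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar checks used by the config validators
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (length(x) != 1L) stopf("'%s' must be a single number", name)
  if (allow_na && is.na(x)) return(x)
  if (!is.finite(x)) stopf("'%s' must be finite", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s]", name, lower, upper)
  as.numeric(x)
}
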