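#' Round half away from zero
#'
#' Presentation rounding for reported percentages, standard errors and
#' confidence bounds. Base \code{round()} rounds half to even (banker's
#' rounding); published survey tables round halves away from zero, so a
#' lower CI bound of 0.15949... prints as 0.2 and 46.45 prints as 46.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded to \code{digits} decimals, halves away from zero.
#' @examples
#' round_half_up(0.5)   # 1, where round(0.5) is 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by one ulp so values that are .5 up to representation error round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# internal: stop with a classed condition so callers can test error types
qhws_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "qhws_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# internal: scalar checks used by validators
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
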