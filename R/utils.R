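#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all displayed percentages so that
#' values such as 1/9 print as 11.1 and 2/9 as 22.2. Base [round()] uses
#' banker's rounding, which is kept out of the display path on purpose.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Format a proportion as a display percent
#'
#' @param x proportion(s) in \[0, 1\] (NA allowed).
#' @param digits decimal places (default 1, matching the reporting convention).
#' @return numeric percent, rounded half-up.
#' @export
percent <- function(x, digits = 1) round_half_up(100 * x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg) stop(errorCondition(msg, class = c("proctailor_validation_error", "error")))
abort_format <- function(msg) stop(errorCondition(msg, class = c("proctailor_format_error", "error")))
abort_lookup <- function(msg) stop(errorCondition(msg, class = c("proctailor_lookup_error", "error")))
abort_config <- function(msg) stop(errorCondition(msg, class = c("proctailor_config_error", "error")))
abort_integrity <- function(msg) stop(errorCondition(msg, class = c("proctailor_integrity_error", "error")))
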