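#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' all Mb and percentage figures reported by this package. Base [round()]
#' rounds half to even, which disagrees with printed genome-report tables at
#' exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just under .5 (e.g. from
  # a division) still round up as their printed form would
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
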