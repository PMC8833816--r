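#' Round half away from zero
#'
#' Displayed percentages are rounded half-up (so 85.25 renders as 85.3),
#' unlike [round()] which rounds half to even.  Used for display only; all
#' comparisons and tests run on unrounded values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# percentage on the scale tables print: 100 * num / den evaluated in that
# order so dyadic ratios (e.g. 341/400) stay exact before rounding
pct <- function(num, den) 100 * num / den

fmt_pct <- function(p, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(p, digits))
}

fmt_est_ci <- function(num, den, lower, upper, digits = 1) {
  sprintf(paste0("%.", digits, "f%% (%.", digits, "f\u2013%.", digits, "f%%)"),
          round_half_up(pct(num, den), digits),
          round_half_up(100 * lower, digits),
          round_half_up(100 * upper, digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
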