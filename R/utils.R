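#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed pharmacovigilance tables
#' conventionally round half up. Used for all emitted percentages.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count against a total, printed-table style
#'
#' @param n count(s).
#' @param total denominator.
#' @param digits decimal places (default 2, the usual printed precision).
#' @return numeric percentage rounded half up.
#' @export
percent_of <- function(n, total, digits = 2) {
  if (any(total <= 0)) stop("percent_of(): total must be positive")
  round_half_up(100 * n / total, digits)
}

# first matching alias present in `available`, or NA
.resolve_alias <- function(aliases, available) {
  hit <- aliases[aliases %in% available]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

.norm_term <- function(x) tolower(trimws(x))

.assert_quarter <- function(quarter) {
  if (!is.character(quarter) || length(quarter) != 1L ||
      !grepl("^[0-9]{4}Q[1-4]$", quarter)) {
    stop("quarter label must match YYYYQ[1-4], got: ", quarter)
  }
  invisible(quarter)
}
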