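#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used for
#' displayed support/confidence/lift values. Differs from [base::round()],
#' which rounds half to even (so `round(1.625, 2)` gives 1.62, not 1.63).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(1.625, 2)  # 1.63
#' round_half_up(1.125, 2)  # 1.13
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards against representation dust just below .5 boundaries
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# canonical, locale-independent item ordering used everywhere itemsets are
# sorted or compared
sort_items <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[order(x, method = "radix")]
}

# stable key identifying an itemset (items joined after canonical sort)
itemset_key <- function(items) {
  paste(sort_items(items), collapse = "\x1f")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
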