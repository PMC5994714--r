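# Small shared helpers.

.famex_cache <- new.env(parent = emptyenv())

#' Format a count over a denominator as a printed percentage
#'
#' `format_percent(355, 434)` gives `"81.8"`; with `digits = 0` it gives
#' `"82"`, the rounding style used in report prose. Values are stored at
#' full precision elsewhere; this is purely the printing rule.
#'
#' @param numerator,denominator counts (vectorised over the numerator).
#' @param digits decimal places (default 1).
#' @return Character vector of formatted percentages (no "%" sign).
#' @export
format_percent <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  sprintf(paste0("%.", digits, "f"), 100 * numerator / denominator)
}

# deterministic integer sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}
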