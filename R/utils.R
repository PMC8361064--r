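# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Decimal rounding where ties go up in absolute value (so 41.75 -> 41.8),
#' the convention used for the cohort percentage tables. Base R's `round()`
#' rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Tab-separated writer used for all table outputs; no quoting so files
# round-trip bit-identically.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = colClasses)
}

# Evaluate an expression under a temporary RNG seed, restoring global RNG
# state afterwards. All generator functions route their randomness here so
# one integer seed fully determines every output.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
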