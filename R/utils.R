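#' Round half away from zero
#'
#' Commercial rounding used for headline percent figures: 0.5 always rounds
#' away from zero, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(c(48.5, 49.4, -2.5))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic substream seeds derived from one master seed, so each table
# draws from its own stream and adding a table never shifts another's values.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
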