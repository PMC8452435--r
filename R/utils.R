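stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, what) {
  if (!is_scalar_number(x) || x <= 0) stopf("%s must be a single positive number", what)
  invisible(x)
}

#' Relative standard deviation
#'
#' Percent RSD, `100 * sd / mean`, using the sample (n - 1) standard
#' deviation. This is the precision, repeatability and cross-column
#' robustness metric used throughout the package.
#'
#' @param x Numeric vector of at least two measurements with nonzero mean.
#' @return Percent RSD as a single number.
#' @examples
#' rsd(c(1.925, 2.002, 1.876))  # ~3.28
#' @export
rsd <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stopf("rsd() needs at least 2 values, got %d", length(x))
  if (anyNA(x)) stopf("rsd() does not accept missing values")
  m <- mean(x)
  if (m == 0) stopf("rsd() undefined for zero mean")
  100 * stats::sd(x) / m
}
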