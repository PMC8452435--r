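#' Vector-angle cosine between two content vectors
#'
#' Agreement between two quantification methods for one analyte is
#' measured as the cosine of the angle between their per-sample content
#' vectors,
#'
#'   cos(theta) = sum(x_i * y_i) / (sqrt(sum(x_i^2)) * sqrt(sum(y_i^2)))
#'
#' A value of 1 means the two methods agree up to a common scale factor.
#' Censored slots (`NA`) are handled by pairwise deletion: a sample is
#' dropped when either vector lacks a value there.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks a censored
#'   slot. Present values must be nonnegative.
#' @return A `similarity_result` list: `cos_theta`, `n_used`
#'   (pairwise-complete samples), `n_dropped`.
#' @examples
#' cos_theta(c(1, 2, 3), c(2, 4, 6))$cos_theta  # 1
#' @export
cos_theta <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) == 0L) stopf("empty vectors")
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stopf("no pairwise-complete samples")
  xs <- x[keep]; ys <- y[keep]
  if (any(xs < 0) || any(ys < 0)) stopf("contents must be nonnegative")
  nx <- sqrt(sum(xs^2)); ny <- sqrt(sum(ys^2))
  if (nx == 0 || ny == 0) stopf("zero-norm vector after censoring")
  structure(list(cos_theta = sum(xs * ys) / (nx * ny),
                 n_used = sum(keep), n_dropped = sum(!keep)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Cos theta = %.5f (n used = %d, dropped = %d)\n",
              x$cos_theta, x$n_used, x$n_dropped))
  invisible(x)
}

#' Per-analyte cosine agreement between two quantification tables
#'
#' Aligns an external-standard and a single-marker result table by
#' sample and analyte and computes [cos_theta()] per target analyte.
#' Analytes present in only one table — in particular the internal
#' reference, which has no single-marker value — are skipped. The sample
#' sets must coincide; a mismatch is an error naming the difference.
#'
#' @param es,qams Quantification result tables
#'   (see [validate_quant_table()]).
#' @return Data frame `analyte`, `cos_theta`, `n_used`, `n_dropped`.
#' @export
similarity_report <- function(es, qams) {
  es <- validate_quant_table(es)
  qams <- validate_quant_table(qams)
  s1 <- sort(unique(es$sample_id)); s2 <- sort(unique(qams$sample_id))
  if (!identical(s1, s2)) {
    d1 <- setdiff(s1, s2); d2 <- setdiff(s2, s1)
    stopf("sample sets differ: %s%s",
          if (length(d1)) paste("only in first:", paste(d1, collapse = ", ")) else "",
          if (length(d2)) paste(" only in second:", paste(d2, collapse = ", ")) else "")
  }
  analytes <- sort(intersect(unique(es$analyte), unique(qams$analyte)))
  if (length(analytes) == 0L) stopf("no analytes in common")
  pick <- function(df, a) {
    d <- df[df$analyte == a, , drop = FALSE]
    d$content[match(s1, d$sample_id)]
  }
  rows <- lapply(analytes, function(a) {
    ct <- cos_theta(pick(es, a), pick(qams, a))
    data.frame(analyte = a, cos_theta = ct$cos_theta, n_used = ct$n_used,
               n_dropped = ct$n_dropped, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
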