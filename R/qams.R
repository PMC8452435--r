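#' Detector response factor
#'
#' The response factor of an analyte is the ratio of detector response
#' (peak area) to concentration, `f = A / C`, assumed constant over the
#' linear range.
#'
#' @param area Peak area, > 0.
#' @param conc Concentration, ng/mL, > 0.
#' @return The response factor (response per ng/mL).
#' @export
response_factor <- function(area, conc) {
  area <- as.numeric(area); conc <- as.numeric(conc)
  if (any(!is.finite(area)) || any(!is.finite(conc)) || any(area <= 0) || any(conc <= 0))
    stopf("response_factor() requires positive area and concentration")
  area / conc
}

#' Relative correction factor between a target and the reference
#'
#' The single-marker method quantifies each target analyte through a
#' fixed relative correction factor (RCF) linking its detector
#' sensitivity to that of the internal reference:
#'
#'   f_km = (C_k * A_m) / (C_m * A_k)
#'
#' where k is the internal reference and m the target, measured on the
#' same standard solution. Under linear zero-intercept responses this is
#' the ratio of the target's sensitivity (slope) to the reference's.
#' Intercepts are deliberately ignored here: the RCF is defined through
#' areas and concentrations directly, not through fitted curves.
#'
#' @param ref_area,ref_conc Reference analyte's area and concentration.
#' @param tgt_area,tgt_conc Target analyte's area and concentration.
#' @return The unitless RCF `f_km`, > 0.
#' @examples
#' compute_rcf(ref_area = 2000, ref_conc = 10, tgt_area = 3000, tgt_conc = 5)  # 3
#' @export
compute_rcf <- function(ref_area, ref_conc, tgt_area, tgt_conc) {
  vals <- c(ref_area, ref_conc, tgt_area, tgt_conc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("compute_rcf() requires all areas and concentrations > 0")
  (ref_conc * tgt_area) / (tgt_conc * ref_area)
}

#' Per-column RCF from a dilution series
#'
#' Applies [compute_rcf()] at every standard level shared by the
#' reference and target series on one column and returns the unweighted
#' arithmetic mean across levels.
#'
#' @param ref,tgt Data frames with columns `level` (solution label),
#'   `conc` (ng/mL) and `area`, for the reference and target analyte.
#' @return The per-column RCF (mean over shared levels), with the number
#'   of levels as attribute `n_levels`.
#' @export
rcf_from_dilution_series <- function(ref, tgt) {
  for (d in list(ref, tgt)) {
    missing_cols <- setdiff(c("level", "conc", "area"), names(d))
    if (length(missing_cols) > 0L)
      stopf("series is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  m <- merge(ref, tgt, by = "level", suffixes = c("_ref", "_tgt"))
  if (nrow(m) == 0L) stopf("reference and target series share no levels")
  per_level <- mapply(compute_rcf, m$area_ref, m$conc_ref, m$area_tgt, m$conc_tgt)
  structure(mean(per_level), n_levels = nrow(m))
}

#' RCF entries for every target analyte on every column
#'
#' Builds the full RCF table from standard-injection peak areas: for each
#' analytical column and each target analyte, the per-level RCFs against
#' the internal reference (matched by solution label and replicate) are
#' averaged into one entry.
#'
#' @param peaks Peak table of standard injections (`sample_id` = solution
#'   label), possibly spanning several columns.
#' @param solutions Data frame `label`, `analyte`, `conc_ng_ml`.
#' @param reference Name of the internal reference analyte.
#' @return Data frame `target`, `reference`, `column_id`, `f_km`.
#' @export
rcf_table <- function(peaks, solutions, reference) {
  peaks <- validate_peak_table(peaks)
  if (!reference %in% peaks$analyte)
    stopf("reference analyte '%s' absent from peak table", reference)
  merged <- merge(peaks, solutions,
                  by.x = c("sample_id", "analyte"), by.y = c("label", "analyte"))
  if (nrow(merged) == 0L) stopf("no peak rows match the solution labels")
  merged <- merged[merged$area > 0, , drop = FALSE]
  ref_rows <- merged[merged$analyte == reference, , drop = FALSE]
  tgt_rows <- merged[merged$analyte != reference, , drop = FALSE]
  if (nrow(ref_rows) == 0L) stopf("no usable reference injections")
  pairs <- merge(tgt_rows, ref_rows,
                 by = c("sample_id", "column_id", "replicate"),
                 suffixes = c("_tgt", "_ref"))
  if (nrow(pairs) == 0L) stopf("no shared (level, replicate) pairs between targets and reference")
  agg <- stats::aggregate(
    f_km ~ column_id + analyte_tgt,
    data = cbind(pairs,
                 f_km = mapply(compute_rcf, pairs$area_ref, pairs$conc_ng_ml_ref,
                               pairs$area_tgt, pairs$conc_ng_ml_tgt)),
    FUN = mean)
  out <- data.frame(target = agg$analyte_tgt, reference = reference,
                    column_id = agg$column_id, f_km = agg$f_km,
                    stringsAsFactors = FALSE)
  out[order(out$target, out$column_id), ]
}

#' Cross-column RCF summary
#'
#' Aggregates per-column RCF entries into the robustness summary used to
#' judge whether RCFs transfer across analytical columns: arithmetic
#' mean, sample (n - 1) standard deviation, and percent RSD per target.
#' Values are kept at full precision; display rounding (3 decimals for
#' mean/SD, 2 for RSD) is left to the reporting layer.
#'
#' @param entries Data frame `target`, `column_id`, `f_km` (one entry per
#'   column per target), e.g. from [rcf_table()].
#' @return Data frame `target`, `mean`, `sd`, `rsd_pct`, `n_columns`.
#' @examples
#' summarize_rcf(data.frame(target = "I", column_id = c("c1", "c2", "c3"),
#'                          f_km = c(1.925, 2.002, 1.876)))
#' @export
summarize_rcf <- function(entries) {
  missing_cols <- setdiff(c("target", "column_id", "f_km"), names(entries))
  if (length(missing_cols) > 0L)
    stopf("entries are missing columns: %s", paste(missing_cols, collapse = ", "))
  if (any(entries$f_km <= 0)) stopf("RCF entries must be > 0")
  pieces <- lapply(split(entries, entries$target), function(d) {
    if (anyDuplicated(d$column_id))
      stopf("multiple entries for target '%s' on one column", d$target[1])
    if (nrow(d) < 2L)
      stopf("target '%s' has %d column entr%s; at least 2 needed for SD",
            d$target[1], nrow(d), if (nrow(d) == 1L) "y" else "ies")
    m <- mean(d$f_km); s <- stats::sd(d$f_km)
    data.frame(target = d$target[1], mean = m, sd = s, rsd_pct = 100 * s / m,
               n_columns = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$target), ]
}

#' Single-marker (QAMS) back-calculation
#'
#' The central quantification step: given the reference analyte's
#' concentration and area in a sample, a target's concentration follows
#' from its area and the relative correction factor,
#'
#'   C_m = (C_k * A_m) / (f_km * A_k)
#'
#' the algebraic inverse of the RCF definition, so quantifying a
#' standard with an RCF computed from the same standard recovers its
#' concentration exactly.
#'
#' @param tgt_area Target analyte's peak area, >= 0.
#' @param ref_area Reference analyte's peak area, > 0.
#' @param ref_conc Reference analyte's concentration, ng/mL, >= 0.
#' @param f_km Relative correction factor, > 0.
#' @return The target concentration, ng/mL.
#' @export
quantify_qams <- function(tgt_area, ref_area, ref_conc, f_km) {
  if (any(!is.finite(c(tgt_area, ref_area, ref_conc, f_km))))
    stopf("quantify_qams() requires finite inputs")
  if (any(ref_area <= 0)) stopf("reference area must be > 0")
  if (any(f_km <= 0)) stopf("f_km must be > 0")
  if (any(tgt_area < 0) || any(ref_conc < 0)) stopf("areas and concentrations must be >= 0")
  (ref_conc * tgt_area) / (f_km * ref_area)
}

#' Write an RCF entry or summary CSV
#'
#' Entry columns: `target,reference,column_id,f_km`; summary columns:
#' `target,mean,sd,rsd_pct,n_columns`. Full precision.
#'
#' @param df An entries or summary data frame.
#' @param path File path.
#' @export
write_rcf_table <- function(df, path) {
  utils::write.csv(format(as.data.frame(df), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_rcf_table
#' @export
read_rcf_table <- function(path) {
  if (!file.exists(path)) stopf("RCF table not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
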