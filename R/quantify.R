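mean_sample_areas <- function(peaks, column_id) {
  peaks <- validate_peak_table(peaks)
  cols <- unique(peaks$column_id)
  if (is.null(column_id)) {
    if (length(cols) > 1L)
      stopf("peak table spans columns %s; name one via column_id",
            paste(cols, collapse = ", "))
    column_id <- cols
  }
  peaks <- peaks[peaks$column_id == column_id, , drop = FALSE]
  if (nrow(peaks) == 0L) stopf("no injections for column '%s'", column_id)
  stats::aggregate(area ~ sample_id + analyte, data = peaks, FUN = mean,
                   na.action = stats::na.pass)
}

#' Quantify samples by the external standard method
#'
#' For each sample and analyte, replicate areas are averaged, the
#' analyte's own calibration curve is inverted ([quantify_es()]), and the
#' concentration is converted to dry-weight content. Negative
#' back-calculations and missing areas are censored per analyte and
#' sample; one bad value never fails the run.
#'
#' @param peaks Sample peak table (one analytical column).
#' @param curves Named list of `calibration_curve` objects covering the
#'   analytes to quantify.
#' @param prep A [sample_prep()] object.
#' @param column_id Analytical column to use when the table spans several.
#' @return A quantification result table (see [validate_quant_table()])
#'   with method tag `"ES"`.
#' @export
es_quantify_table <- function(peaks, curves, prep, column_id = NULL) {
  areas <- mean_sample_areas(peaks, column_id)
  areas <- areas[areas$analyte %in% names(curves), , drop = FALSE]
  if (nrow(areas) == 0L) stopf("no analytes in common between peak table and curves")
  rows <- lapply(seq_len(nrow(areas)), function(i) {
    a <- areas$analyte[i]
    q <- quantify_es(areas$area[i], curves[[a]])
    data.frame(sample_id = areas$sample_id[i], analyte = a,
               solution_conc = q$conc,
               content = if (is.na(q$conc)) NA_real_ else content_from_solution(q$conc, prep),
               method = "ES", censored = q$censored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_quant_table(out[order(out$sample_id, out$analyte), ])
}

#' Quantify samples by the single-marker (QAMS) method
#'
#' Only the internal reference is quantified against its own calibration
#' curve; every other analyte is back-calculated from the reference's
#' concentration and area through its relative correction factor
#' ([quantify_qams()]). When the reference is censored or missing in a
#' sample, every target in that sample is censored (`missing_area`) —
#' the single marker is the sample's only anchor. The reference itself is
#' excluded from the output: it has no single-marker value.
#'
#' @param peaks Sample peak table (one analytical column).
#' @param ref_curve `calibration_curve` for the internal reference.
#' @param rcf Data frame with columns `target` and either `f_km` (entry
#'   table) or `mean` (cross-column summary); the summary's `mean` is
#'   used as the working RCF.
#' @param reference Internal reference analyte name.
#' @param prep A [sample_prep()] object.
#' @param column_id Analytical column to use when the table spans several.
#' @return A quantification result table with method tag `"QAMS"`.
#' @export
qams_quantify_table <- function(peaks, ref_curve, rcf, reference, prep,
                                column_id = NULL) {
  if (!"target" %in% names(rcf)) stopf("rcf must have a 'target' column")
  fcol <- if ("f_km" %in% names(rcf)) "f_km" else if ("mean" %in% names(rcf)) "mean"
          else stopf("rcf must carry 'f_km' or 'mean'")
  f_km <- rcf[[fcol]]
  names(f_km) <- rcf$target
  if (anyDuplicated(rcf$target)) stopf("rcf has several rows per target; summarize first")
  areas <- mean_sample_areas(peaks, column_id)
  if (!reference %in% areas$analyte)
    stopf("reference analyte '%s' absent from peak table", reference)
  targets <- setdiff(intersect(areas$analyte, names(f_km)), reference)
  if (length(targets) == 0L) stopf("no RCF targets present in peak table")
  samples <- sort(unique(areas$sample_id))
  area_of <- function(s, a) {
    v <- areas$area[areas$sample_id == s & areas$analyte == a]
    if (length(v) == 0L) NA_real_ else v
  }
  rows <- lapply(samples, function(s) {
    ref_area <- area_of(s, reference)
    ref_q <- quantify_es(ref_area, ref_curve)
    anchored <- is.na(ref_q$conc) || is.na(ref_area) || ref_area <= 0
    do.call(rbind, lapply(targets, function(a) {
      t_area <- area_of(s, a)
      if (anchored || is.na(t_area)) {
        data.frame(sample_id = s, analyte = a, solution_conc = NA_real_,
                   content = NA_real_, method = "QAMS",
                   censored = "missing_area", stringsAsFactors = FALSE)
      } else {
        conc <- quantify_qams(t_area, ref_area, ref_q$conc, f_km[[a]])
        data.frame(sample_id = s, analyte = a, solution_conc = conc,
                   content = content_from_solution(conc, prep),
                   method = "QAMS", censored = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }))
  })
  validate_quant_table(do.call(rbind, rows))
}
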