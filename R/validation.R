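#' Spike recovery
#'
#' Percentage of a known added amount recovered on top of the native
#' content: `100 * (found_spiked - native) / added`. All three arguments
#' share one unit (typically ug/g dry weight).
#'
#' @param found_spiked Content measured in the spiked sample.
#' @param native Native (unspiked) content.
#' @param added Amount added, > 0.
#' @return Percent recovery.
#' @examples
#' recovery_pct(302.85, 150, 150)  # 101.9
#' @export
recovery_pct <- function(found_spiked, native, added) {
  if (any(!is.finite(c(found_spiked, native, added)))) stopf("inputs must be finite")
  if (any(added <= 0)) stopf("added amount must be > 0")
  100 * (found_spiked - native) / added
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA over two or more groups of
#' replicate measurements: F statistic and p-value from the F
#' distribution. Groups with no between-group variance give F = 0 and
#' p = 1; zero within-group variance with unequal means gives an infinite
#' F and p = 0, with a warning.
#'
#' @param groups A list of numeric vectors, each of length >= 2.
#' @return A list with `f_stat`, `p_value`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stopf("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  grand <- mean(values)
  ss_w <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (ss_w == 0) {
    ss_b <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
    if (ss_b > 0) {
      warnf("zero within-group variance with unequal means; F is infinite")
      return(list(f_stat = Inf, p_value = 0, df_between = df_b, df_within = df_w))
    }
    return(list(f_stat = 0, p_value = 1, df_between = df_b, df_within = df_w))
  }
  tab <- stats::anova(stats::lm(values ~ g))
  list(f_stat = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

required_precision_designs <- c("intraday", "interday", "repeatability")

#' Assemble a method-validation report from design-labelled injections
#'
#' Takes a peak table whose `design` column assigns each injection to a
#' validation scheme and computes, per analyte: intraday and interday
#' precision (percent RSD of back-calculated standard concentrations),
#' repeatability (RSD of sample contents across replicate preparations),
#' and spike recovery (mean and RSD across spiked replicates, against
#' the mean native content). Schemes are driven by explicit labels, not
#' timestamps, so any injection schedule can be expressed.
#'
#' Design labels: `intraday`, `interday`, `repeatability` (all required),
#' and optionally `recovery_native` + `recovery_spiked` (both, plus
#' `added`, for recovery).
#'
#' @param peaks Peak table with an extra `design` column.
#' @param curves Named list of `calibration_curve` objects.
#' @param prep A [sample_prep()] object (for content-scale metrics).
#' @param added Data frame `analyte`, `added` (ug/g) — the spiked
#'   amounts; required when recovery designs are present.
#' @param column_id Analytical column to use when the table spans several.
#' @return A list with data frames `precision` (`analyte`, `kind`,
#'   `mean`, `rsd_pct`, `n`) and `recovery` (`analyte`,
#'   `mean_recovery_pct`, `rsd_pct`, `n`; `NULL` when not measured).
#' @export
validation_report <- function(peaks, curves, prep, added = NULL,
                              column_id = NULL) {
  peaks <- as.data.frame(peaks)
  if (!"design" %in% names(peaks)) stopf("peak table has no 'design' column")
  design <- as.character(peaks$design)
  peaks_core <- validate_peak_table(peaks[setdiff(names(peaks), "design")])
  peaks_core$design <- design
  cols <- unique(peaks_core$column_id)
  if (is.null(column_id)) {
    if (length(cols) > 1L) stopf("name a column via column_id")
    column_id <- cols
  }
  peaks_core <- peaks_core[peaks_core$column_id == column_id, , drop = FALSE]
  missing_designs <- setdiff(required_precision_designs, unique(peaks_core$design))
  if (length(missing_designs) > 0L)
    stopf("missing design labels: %s", paste(missing_designs, collapse = ", "))

  conc_of <- function(d) {
    q <- quantify_es(d$area, curves[[d$analyte[1]]])
    q$conc
  }
  precision_rows <- list()
  for (kind in required_precision_designs) {
    sub <- peaks_core[peaks_core$design == kind, , drop = FALSE]
    for (a in sort(intersect(unique(sub$analyte), names(curves)))) {
      d <- sub[sub$analyte == a, , drop = FALSE]
      conc <- conc_of(d)
      conc <- conc[!is.na(conc)]
      if (length(conc) < 2L)
        stopf("analyte '%s' has < 2 usable %s injections", a, kind)
      vals <- if (kind == "repeatability") content_from_solution(conc, prep) else conc
      precision_rows[[length(precision_rows) + 1L]] <-
        data.frame(analyte = a, kind = kind, mean = mean(vals),
                   rsd_pct = rsd(vals), n = length(vals),
                   stringsAsFactors = FALSE)
    }
  }
  precision <- do.call(rbind, precision_rows)

  recovery <- NULL
  has_native <- "recovery_native" %in% peaks_core$design
  has_spiked <- "recovery_spiked" %in% peaks_core$design
  if (has_native != has_spiked)
    stopf("recovery needs both recovery_native and recovery_spiked labels")
  if (has_native && has_spiked) {
    if (is.null(added) || !all(c("analyte", "added") %in% names(added)))
      stopf("recovery designs present but no added-amount table supplied")
    nat <- peaks_core[peaks_core$design == "recovery_native", , drop = FALSE]
    spk <- peaks_core[peaks_core$design == "recovery_spiked", , drop = FALSE]
    recovery_rows <- lapply(sort(intersect(unique(spk$analyte), names(curves))), function(a) {
      add_a <- added$added[added$analyte == a]
      if (length(add_a) != 1L) stopf("no added amount for analyte '%s'", a)
      nat_conc <- conc_of(nat[nat$analyte == a, , drop = FALSE])
      native_content <- mean(content_from_solution(nat_conc[!is.na(nat_conc)], prep))
      spk_conc <- conc_of(spk[spk$analyte == a, , drop = FALSE])
      found <- content_from_solution(spk_conc[!is.na(spk_conc)], prep)
      rec <- recovery_pct(found, native_content, add_a)
      data.frame(analyte = a, mean_recovery_pct = mean(rec),
                 rsd_pct = if (length(rec) >= 2L) rsd(rec) else NA_real_,
                 n = length(rec), stringsAsFactors = FALSE)
    })
    recovery <- do.call(rbind, recovery_rows)
  }
  list(precision = precision, recovery = recovery)
}
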