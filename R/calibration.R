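#' Fit an external-standard calibration curve
#'
#' Ordinary least squares fit of detector response on concentration,
#' `area = a * conc + b`, as used by the external standard (ES) method.
#' The fit is unweighted; the linear range is taken as the span of the
#' points actually fitted.
#'
#' @param conc Concentrations, ng/mL; at least two distinct values.
#' @param area Peak areas at those concentrations.
#' @param analyte Optional analyte name carried on the curve.
#' @return A `calibration_curve` object with elements `analyte`,
#'   `slope_a`, `intercept_b`, `r_squared`, `linear_range` (low, high)
#'   and `n_points`.
#' @examples
#' fit_calibration(c(1, 10, 100), 6564.29 * c(1, 10, 100) - 354.886)
#' @export
fit_calibration <- function(conc, area, analyte = NA_character_) {
  conc <- as.numeric(conc); area <- as.numeric(area)
  if (length(conc) != length(area)) stopf("conc and area differ in length")
  ok <- !is.na(conc) & !is.na(area)
  conc <- conc[ok]; area <- area[ok]
  if (length(conc) < 2L) stopf("calibration needs at least 2 points, got %d", length(conc))
  if (any(conc <= 0)) stopf("calibration concentrations must be > 0")
  if (length(unique(conc)) < 2L) stopf("singular design: all concentrations identical")
  fit <- stats::lm(area ~ conc)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(list(analyte = as.character(analyte),
                 slope_a = unname(co[["conc"]]),
                 intercept_b = unname(co[["(Intercept)"]]),
                 r_squared = r2,
                 linear_range = c(low = min(conc), high = max(conc)),
                 n_points = length(conc)),
            class = "calibration_curve")
}

#' Construct a calibration curve from known coefficients
#'
#' Used when the slope/intercept come from a report rather than a fresh
#' fit (e.g. a published regression table).
#'
#' @inheritParams fit_calibration
#' @param slope_a,intercept_b Line coefficients (response per ng/mL,
#'   response).
#' @param range_low,range_high Linear range, ng/mL.
#' @param r_squared Coefficient of determination, if known.
#' @param n_points Number of points behind the fit, if known.
#' @export
calibration_curve <- function(slope_a, intercept_b, range_low, range_high,
                              analyte = NA_character_, r_squared = NA_real_,
                              n_points = NA_integer_) {
  if (!is_scalar_number(slope_a) || slope_a <= 0)
    stopf("slope_a must be positive (detector response must increase with concentration)")
  if (!is_scalar_number(intercept_b)) stopf("intercept_b must be a number")
  if (!(range_low < range_high)) stopf("range_low must be < range_high")
  structure(list(analyte = as.character(analyte), slope_a = slope_a,
                 intercept_b = intercept_b, r_squared = as.numeric(r_squared),
                 linear_range = c(low = range_low, high = range_high),
                 n_points = as.integer(n_points)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve%s: area = %.6g * conc %+.6g (r2 = %s), range %.4g-%.4g ng/mL, n = %s\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$slope_a, x$intercept_b,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$linear_range[["low"]], x$linear_range[["high"]],
              ifelse(is.na(x$n_points), "NA", x$n_points)))
  invisible(x)
}

#' Back-calculate concentrations through a calibration curve
#'
#' The external-standard quantification step: `conc = (area - b) / a`.
#' Results outside the curve's linear range are flagged; a negative
#' back-calculated concentration is censored (reason `below_range`)
#' rather than reported as a negative number or clamped to zero, so that
#' downstream statistics can exclude it explicitly.
#'
#' @param area Peak area(s); `NA` areas are censored as `missing_area`.
#' @param curve A `calibration_curve`.
#' @return A data frame with one row per area: `conc` (ng/mL, `NA` when
#'   censored), `flag` (`"ok"`, `"below_range"`, `"above_range"`) and
#'   `censored` (`NA` or a reason).
#' @export
quantify_es <- function(area, curve) {
  if (!inherits(curve, "calibration_curve")) stopf("curve must be a calibration_curve")
  if (curve$slope_a == 0) stopf("zero slope: curve cannot be inverted")
  area <- as.numeric(area)
  conc <- (area - curve$intercept_b) / curve$slope_a
  flag <- rep("ok", length(area))
  censored <- rep(NA_character_, length(area))
  lo <- curve$linear_range[["low"]]; hi <- curve$linear_range[["high"]]
  flag[!is.na(conc) & conc < lo] <- "below_range"
  flag[!is.na(conc) & conc > hi] <- "above_range"
  neg <- !is.na(conc) & conc < 0
  censored[neg] <- "below_range"
  conc[neg] <- NA_real_
  missing <- is.na(area)
  censored[missing] <- "missing_area"
  flag[missing] <- "ok"
  conc[missing] <- NA_real_
  data.frame(conc = conc, flag = flag, censored = censored,
             stringsAsFactors = FALSE)
}

#' Estimate LOD and LOQ from a signal-to-noise dilution series
#'
#' The limits of detection and quantitation are the on-column amounts at
#' which the peak's signal-to-noise ratio reaches 3 and 10. Given
#' (concentration, S/N) pairs from a dilution series, the concentration
#' at each S/N threshold is found by linear interpolation in log-log
#' space between the bracketing points; when the threshold lies outside
#' the measured S/N span, the two nearest points are extrapolated, with a
#' warning. The interpolated concentration (ng/mL) is converted to an
#' on-column amount as `conc * injection_volume / 1000` (uL to mL, so ng).
#'
#' @param conc Concentrations of the injected dilutions, ng/mL.
#' @param snr Measured signal-to-noise ratios; must increase strictly
#'   with concentration.
#' @param injection_volume Injection volume, uL.
#' @param extrapolate Allow extrapolation beyond the measured S/N span
#'   (default `TRUE`).
#' @return A `lod_loq` object with `lod_ng`, `loq_ng` and
#'   `injection_volume`.
#' @export
estimate_lod_loq <- function(conc, snr, injection_volume, extrapolate = TRUE) {
  conc <- as.numeric(conc); snr <- as.numeric(snr)
  if (length(conc) != length(snr)) stopf("conc and snr differ in length")
  if (length(conc) < 2L) stopf("need at least 2 (conc, snr) points")
  if (any(conc <= 0) || any(snr <= 0)) stopf("conc and snr must be positive")
  ord <- order(conc)
  conc <- conc[ord]; snr <- snr[ord]
  if (any(diff(snr) <= 0)) stopf("snr must increase strictly with concentration")
  conc_at_snr <- function(target) {
    lx <- log(conc); ly <- log(snr); lt <- log(target)
    if (lt < ly[1] || lt > ly[length(ly)]) {
      if (!extrapolate)
        stopf("S/N = %g outside measured span [%g, %g] and extrapolation disabled",
              target, snr[1], snr[length(snr)])
      idx <- if (lt < ly[1]) 1:2 else (length(ly) - 1):length(ly)
      warnf("S/N = %g outside measured span; extrapolating from the two nearest points", target)
    } else {
      hi <- which(ly >= lt)[1]
      idx <- if (ly[hi] == lt) c(hi, hi) else c(hi - 1L, hi)
      if (idx[1] == idx[2]) return(conc[hi])
    }
    slope <- (ly[idx[2]] - ly[idx[1]]) / (lx[idx[2]] - lx[idx[1]])
    exp(lx[idx[1]] + (lt - ly[idx[1]]) / slope)
  }
  check_positive_scalar(injection_volume, "injection_volume")
  lod_conc <- conc_at_snr(3)
  loq_conc <- conc_at_snr(10)
  structure(list(lod_ng = lod_conc * injection_volume / 1000,
                 loq_ng = loq_conc * injection_volume / 1000,
                 injection_volume = injection_volume),
            class = "lod_loq")
}

#' Fit calibration curves for every analyte in a peak table
#'
#' Merges standard-injection peak areas with the known solution
#' concentrations (by solution label and analyte) and fits one curve per
#' analyte. Replicate injections at a level enter the fit individually.
#'
#' @param peaks Peak table of standard injections; `sample_id` holds the
#'   solution label.
#' @param solutions Data frame `label`, `analyte`, `conc_ng_ml` (e.g.
#'   from [build_dilution_ladder()]).
#' @param column_id Restrict to one analytical column (default: the
#'   single column present; an error if several and none named).
#' @return Named list of `calibration_curve` objects, one per analyte.
#' @export
fit_calibration_table <- function(peaks, solutions, column_id = NULL) {
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
  merged <- merge(peaks, solutions,
                  by.x = c("sample_id", "analyte"), by.y = c("label", "analyte"))
  if (nrow(merged) == 0L) stopf("no peak rows match the solution labels")
  out <- lapply(split(merged, merged$analyte), function(d)
    fit_calibration(d$conc_ng_ml, d$area, analyte = d$analyte[1]))
  out[order(names(out))]
}

#' Write or read a calibration report CSV
#'
#' Columns `analyte,slope,intercept,r_squared,range_low,range_high,
#' lod_ng,loq_ng`; LOD/LOQ columns are empty when not estimated. Values
#' round-trip at full precision.
#'
#' @param curves Named list of `calibration_curve` objects.
#' @param lodloq Optional named list of `lod_loq` objects (same names).
#' @param path File path.
#' @export
write_curve_table <- function(curves, path, lodloq = NULL) {
  rows <- lapply(names(curves), function(a) {
    cv <- curves[[a]]
    ll <- if (!is.null(lodloq) && a %in% names(lodloq)) lodloq[[a]] else NULL
    data.frame(analyte = a, slope = cv$slope_a, intercept = cv$intercept_b,
               r_squared = cv$r_squared,
               range_low = cv$linear_range[["low"]],
               range_high = cv$linear_range[["high"]],
               lod_ng = if (is.null(ll)) NA_real_ else ll$lod_ng,
               loq_ng = if (is.null(ll)) NA_real_ else ll$loq_ng,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_curve_table
#' @export
read_curve_table <- function(path) {
  if (!file.exists(path)) stopf("curve table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("analyte", "slope", "intercept", "range_low", "range_high")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stopf("curve table is missing columns: %s", paste(missing_cols, collapse = ", "))
  curves <- lapply(seq_len(nrow(df)), function(i)
    calibration_curve(df$slope[i], df$intercept[i], df$range_low[i],
                      df$range_high[i], analyte = df$analyte[i],
                      r_squared = if ("r_squared" %in% names(df)) df$r_squared[i] else NA_real_))
  names(curves) <- df$analyte
  curves
}
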