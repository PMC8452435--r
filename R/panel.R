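#' Analyte panels
#'
#' An analyte panel describes the compounds measured by a targeted MRM
#' assay: a short name, the precursor and product ion m/z values, the
#' cone voltage and collision energy used for the quantifier transition,
#' and a role. Exactly one analyte carries the role
#' `"internal_reference"`; all single-marker (QAMS) back-calculations are
#' made relative to that analyte.
#'
#' @param df A data frame with columns `name`, `long_name`, `role`,
#'   `parent_mz`, `quant_ion_mz`, `qual_ion_mz`, `cone_voltage`,
#'   `collision_energy`. `qual_ion_mz` may be `NA`.
#' @return A validated `analyte_panel` data frame; row order is preserved.
#' @export
as_analyte_panel <- function(df) {
  req <- c("name", "long_name", "role", "parent_mz", "quant_ion_mz",
           "qual_ion_mz", "cone_voltage", "collision_energy")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stopf("panel is missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$name <- as.character(df$name)
  df$role <- as.character(df$role)
  if (anyDuplicated(df$name))
    stopf("duplicate analyte name(s): %s",
          paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role), c("target", "internal_reference"))
  if (length(bad_role) > 0L)
    stopf("unknown role(s): %s", paste(bad_role, collapse = ", "))
  n_ref <- sum(df$role == "internal_reference")
  if (n_ref == 0L) stopf("no internal reference analyte in panel")
  if (n_ref > 1L) stopf("panel has %d internal reference analytes; exactly one is required", n_ref)
  for (col in c("parent_mz", "quant_ion_mz", "cone_voltage", "collision_energy")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || any(df[[col]] <= 0))
      stopf("column '%s' must be positive and complete", col)
  }
  df$qual_ion_mz <- as.numeric(df$qual_ion_mz)
  same <- !is.na(df$qual_ion_mz) & df$qual_ion_mz == df$quant_ion_mz
  if (any(same))
    stopf("quantifier and qualifier ion coincide for: %s",
          paste(df$name[same], collapse = ", "))
  class(df) <- c("analyte_panel", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read an analyte panel from a delimited file
#'
#' @param path Path to a CSV file with the panel columns (see
#'   [as_analyte_panel()]).
#' @return A validated `analyte_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_analyte_panel(df)
}

#' @rdname load_panel
#' @param panel An `analyte_panel`.
#' @export
write_panel <- function(panel, path) {
  panel <- as_analyte_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Name of a panel's internal reference analyte
#'
#' @param panel An `analyte_panel`.
#' @return The short name of the single internal-reference analyte.
#' @export
reference_analyte <- function(panel) {
  panel <- as_analyte_panel(panel)
  panel$name[panel$role == "internal_reference"]
}

#' Sample preparation parameters
#'
#' Mass of dry material extracted, final extract volume, and any further
#' dilution applied before injection. These convert between solution
#' concentrations (ng/mL) and dry-weight contents (ug/g).
#'
#' @param sample_mass Dry mass extracted, grams.
#' @param extract_volume Final extract volume, mL.
#' @param dilution_factor Post-extraction dilution (default 1).
#' @return A `sample_prep` object.
#' @export
sample_prep <- function(sample_mass, extract_volume, dilution_factor = 1) {
  check_positive_scalar(sample_mass, "sample_mass")
  check_positive_scalar(extract_volume, "extract_volume")
  check_positive_scalar(dilution_factor, "dilution_factor")
  structure(list(sample_mass = sample_mass, extract_volume = extract_volume,
                 dilution_factor = dilution_factor),
            class = "sample_prep")
}

#' Convert a solution concentration to dry-weight content
#'
#' content (ug/g) = conc (ng/mL) x extract_volume (mL) x dilution_factor
#' / sample_mass (g) / 1000, the ng-to-ug conversion being explicit. For
#' the default preparation of 0.5 g in 100 mL this is `conc * 0.2`.
#'
#' @param conc Solution concentration(s), ng/mL; nonnegative.
#' @param prep A [sample_prep()] object.
#' @return Content(s) in ug/g dry weight.
#' @examples
#' content_from_solution(929.5, sample_prep(0.5, 100))  # 185.9
#' @export
content_from_solution <- function(conc, prep) {
  if (!inherits(prep, "sample_prep")) stopf("prep must be a sample_prep object")
  conc <- as.numeric(conc)
  if (any(conc < 0, na.rm = TRUE))
    stopf("negative concentration; censoring must be decided upstream")
  conc * prep$extract_volume * prep$dilution_factor / prep$sample_mass / 1000
}

#' Convert a dry-weight content back to a solution concentration
#'
#' Inverse of [content_from_solution()]; used by the simulator to turn
#' true contents into injected concentrations.
#'
#' @inheritParams content_from_solution
#' @param content Content(s), ug/g dry weight.
#' @export
solution_from_content <- function(content, prep) {
  if (!inherits(prep, "sample_prep")) stopf("prep must be a sample_prep object")
  content <- as.numeric(content)
  if (any(content < 0, na.rm = TRUE)) stopf("negative content")
  content * prep$sample_mass * 1000 / (prep$extract_volume * prep$dilution_factor)
}

#' Standard solutions
#'
#' A labelled mixture of the panel analytes at known concentrations.
#' Working solutions are in ng/mL; stocks in mg/mL. The unit is carried
#' explicitly so that the two scales are never mixed silently.
#'
#' @param label Solution label (e.g. `"stock"`, `"I"` ... `"VIII"`).
#' @param concentrations Named numeric vector, analyte name to
#'   concentration; all strictly positive.
#' @param unit `"ng/mL"` (working solutions) or `"mg/mL"` (stocks).
#' @return A `standard_solution` object.
#' @export
standard_solution <- function(label, concentrations, unit = c("ng/mL", "mg/mL")) {
  unit <- match.arg(unit)
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    stopf("concentrations must be a fully named vector")
  concentrations <- vapply(concentrations, as.numeric, numeric(1))
  if (anyNA(concentrations) || any(concentrations <= 0))
    stopf("all concentrations must be strictly positive")
  structure(list(label = as.character(label), concentrations = concentrations,
                 unit = unit),
            class = "standard_solution")
}

peak_table_cols <- c("sample_id", "column_id", "analyte", "replicate", "area", "snr")

#' Peak tables
#'
#' A peak table holds one integrated peak area per injection and analyte:
#' `sample_id`, `column_id` (analytical column / system), `analyte`,
#' `replicate` (integer index), `area` and an optional signal-to-noise
#' ratio `snr`. The table is the sole input format for all downstream
#' stages; peak identity is assumed already established.
#'
#' @param df A data frame with the peak-table columns; `snr` may be
#'   missing or `NA`. An optional `design` column (validation schemes) is
#'   retained.
#' @return The validated data frame.
#' @export
validate_peak_table <- function(df) {
  df <- as.data.frame(df)
  if (!"snr" %in% names(df)) df$snr <- NA_real_
  missing_cols <- setdiff(peak_table_cols, names(df))
  if (length(missing_cols) > 0L)
    stopf("peak table is missing columns: %s", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$column_id <- as.character(df$column_id)
  df$analyte <- as.character(df$analyte)
  df$replicate <- as.integer(df$replicate)
  df$area <- as.numeric(df$area)
  df$snr <- as.numeric(df$snr)
  if (any(is.na(df$replicate))) stopf("replicate indices must be integers")
  if (any(!is.na(df$area) & df$area < 0)) stopf("areas must be >= 0")
  if (any(!is.na(df$snr) & df$snr <= 0)) stopf("snr must be > 0 when present")
  key <- paste(df$sample_id, df$column_id, df$analyte, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (sample_id, column_id, analyte, replicate) rows in peak table")
  df
}

#' Read or write a peak table CSV
#'
#' CSV dialect: UTF-8, comma-separated, header
#' `sample_id,column_id,analyte,replicate,area,snr`; empty field means
#' missing; decimal point `"."`; no thousands separators. Values are
#' written at full precision.
#'
#' @param path File path.
#' @return `read_peak_table()` returns a validated peak-table data frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stopf("peak table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L) stopf("peak table is empty: %s", path)
  validate_peak_table(df)
}

#' @rdname read_peak_table
#' @param df A peak-table data frame.
#' @export
write_peak_table <- function(df, path) {
  df <- validate_peak_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Quantification result tables
#'
#' One row per sample and analyte: the back-calculated solution
#' concentration (ng/mL), the dry-weight content (ug/g), the method tag
#' (`"ES"` external standard or `"QAMS"` single marker), and a censoring
#' reason (`NA` when the value is reported). Censored rows never carry a
#' numeric value: a below-LOQ cell is a flag, not a zero.
#'
#' @param df Data frame with columns `sample_id`, `analyte`,
#'   `solution_conc`, `content`, `method`, `censored`.
#' @return The validated data frame.
#' @export
validate_quant_table <- function(df) {
  req <- c("sample_id", "analyte", "solution_conc", "content", "method", "censored")
  df <- as.data.frame(df)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stopf("quant table is missing columns: %s", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$analyte <- as.character(df$analyte)
  df$solution_conc <- as.numeric(df$solution_conc)
  df$content <- as.numeric(df$content)
  df$method <- as.character(df$method)
  df$censored <- as.character(df$censored)
  bad_method <- setdiff(unique(df$method), c("ES", "QAMS"))
  if (length(bad_method) > 0L) stopf("unknown method tag(s): %s", paste(bad_method, collapse = ", "))
  ok_reason <- c("below_loq", "below_range", "above_range", "missing_area")
  bad_reason <- setdiff(unique(df$censored[!is.na(df$censored)]), ok_reason)
  if (length(bad_reason) > 0L)
    stopf("unknown censoring reason(s): %s", paste(bad_reason, collapse = ", "))
  cens <- !is.na(df$censored)
  if (any(cens & (!is.na(df$solution_conc) | !is.na(df$content))))
    stopf("censored rows must not carry numeric values")
  if (any(!cens & is.na(df$solution_conc)))
    stopf("uncensored rows must carry a solution concentration")
  df
}

#' @rdname validate_quant_table
#' @param path File path.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stopf("quant table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_quant_table(df)
}

#' @rdname validate_quant_table
#' @export
write_quant_table <- function(df, path) {
  df <- validate_quant_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
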