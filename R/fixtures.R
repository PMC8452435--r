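extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "qamsr")
  if (!nzchar(p)) stopf("bundled file '%s' not found; is qamsr installed?", file)
  p
}

#' Bundled ten-batch nucleoside study
#'
#' A complete worked dataset for a nine-nucleoside MRM assay of dried
#' *Tricholoma matsutake* fruiting bodies, with guanosine as the internal
#' reference: the MRM panel, stock-solution concentrations (mg/mL),
#' per-column relative correction factors measured on three C18 columns
#' (Waters BEH C18, Agilent ZORBAX SB-C18, Shimadzu Shim-pack XR-ODS),
#' the calibration/validation summary per analyte (regression
#' coefficients, linear range, LOD/LOQ at 10 uL injections, precision,
#' repeatability, recovery), dry-weight contents of ten batches
#' determined by both the external standard and the single-marker
#' method (empty cells are censored, below LOQ), and a three-replicate
#' comparison of ultrasonic versus boiling-water extraction.
#'
#' @return A list with elements `panel` (analyte_panel), `stocks` (named
#'   mg/mL vector), `prep` ([sample_prep()]: 0.5 g in 100 mL),
#'   `injection_volume` (uL), `rcf_columns`, `validation`, `contents`
#'   (long data frame with `es_ug_g`/`qams_ug_g`, `NA` = censored),
#'   `extraction`, and ready-made quantification tables `es` and `qams`
#'   (see [validate_quant_table()]).
#' @export
matsutake_study <- function() {
  panel <- load_panel(extdata_path("panel_nucleosides.csv"))
  stocks_df <- utils::read.csv(extdata_path("stock_solutions.csv"),
                               stringsAsFactors = FALSE)
  stocks <- stats::setNames(stocks_df$stock_mg_ml, stocks_df$analyte)
  prep <- sample_prep(0.5, 100)
  contents <- utils::read.csv(extdata_path("contents_es_qams.csv"),
                              stringsAsFactors = FALSE,
                              na.strings = c("", "NA"))
  as_quant <- function(values, method) {
    validate_quant_table(data.frame(
      sample_id = contents$sample_id, analyte = contents$analyte,
      solution_conc = solution_from_content(ifelse(is.na(values), NA, values), prep),
      content = values, method = method,
      censored = ifelse(is.na(values), "below_loq", NA_character_),
      stringsAsFactors = FALSE))
  }
  qams_rows <- contents$analyte != "G"
  list(panel = panel,
       stocks = stocks,
       prep = prep,
       injection_volume = 10,
       rcf_columns = utils::read.csv(extdata_path("rcf_columns.csv"),
                                     stringsAsFactors = FALSE),
       validation = utils::read.csv(extdata_path("method_validation.csv"),
                                    stringsAsFactors = FALSE),
       contents = contents,
       extraction = utils::read.csv(extdata_path("extraction_comparison.csv"),
                                    stringsAsFactors = FALSE),
       es = as_quant(contents$es_ug_g, "ES"),
       qams = as_quant(contents$qams_ug_g, "QAMS")[qams_rows, , drop = FALSE])
}

#' Default true-content ranges for the simulator
#'
#' Per-analyte `c(lo, hi)` ranges (ug/g dry weight) spanning the
#' uncensored external-standard contents observed in the bundled
#' ten-batch study, so that simulated specimens live on the same scale
#' as real ones.
#'
#' @return Named list analyte -> c(lo, hi).
#' @export
default_content_ranges <- function() {
  study <- matsutake_study()
  es <- study$contents
  out <- lapply(split(es$es_ug_g, es$analyte), function(v) {
    v <- v[!is.na(v)]
    range(v)
  })
  out[order(names(out))]
}

#' Default simulator truth patterned on the bundled study
#'
#' Convenience constructor: a [sim_config()] whose true detector
#' responses are the bundled per-analyte regression coefficients and
#' whose column drift/noise follow the package defaults.
#'
#' @param seed Integer seed (mandatory).
#' @param ... Passed on to [sim_config()] (e.g. `noise_cv`,
#'   `column_profiles`).
#' @return A list `config` ([sim_config()]) and `stocks` (named vector),
#'   ready for [simulate_study()].
#' @export
default_sim_setup <- function(seed, ...) {
  study <- matsutake_study()
  curves <- data.frame(analyte = study$validation$analyte,
                       slope = study$validation$slope,
                       intercept = study$validation$intercept,
                       stringsAsFactors = FALSE)
  list(config = sim_config(study$panel, curves, seed = seed, ...),
       stocks = study$stocks)
}
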