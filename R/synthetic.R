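ladder_dilutions <- c(2.5, 5, 10, 20, 50, 100)
names(ladder_dilutions) <- c("III", "IV", "V", "VI", "VII", "VIII")

#' Build the standard working-solution dilution ladder
#'
#' From per-analyte stock concentrations (mg/mL), builds the mixed
#' working solutions: solution I is a 1:100 dilution of the stocks,
#' solution II a further 1:100 dilution of I, and solutions III-VIII are
#' II diluted 2.5, 5, 10, 20, 50 and 100 times. The mg/mL to ng/mL
#' conversion (x 10^6) is applied explicitly at the stock boundary, so a
#' G stock of 0.987 mg/mL gives solution II = 98.7 ng/mL and solution
#' VIII = 0.987 ng/mL.
#'
#' @param stocks Named numeric vector of stock concentrations, mg/mL,
#'   one per analyte; all strictly positive.
#' @return Data frame `label`, `analyte`, `conc_ng_ml` covering
#'   solutions I-VIII, with the II-relative dilution factors as
#'   attribute `factor_vs_II`.
#' @export
build_dilution_ladder <- function(stocks) {
  if (is.null(names(stocks)) || any(!nzchar(names(stocks))))
    stopf("stocks must be a fully named vector (analyte -> mg/mL)")
  stocks <- vapply(stocks, as.numeric, numeric(1))
  if (anyNA(stocks) || any(stocks <= 0)) stopf("stock concentrations must be > 0")
  conc_I <- stocks * 1e6 / 100        # ng/mL
  conc_II <- conc_I / 100
  labels <- c("I", "II", names(ladder_dilutions))
  rows <- lapply(labels, function(lab) {
    conc <- switch(lab, I = conc_I, II = conc_II,
                   conc_II / ladder_dilutions[[lab]])
    data.frame(label = lab, analyte = names(stocks), conc_ng_ml = unname(conc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "factor_vs_II") <- c(II = 1, ladder_dilutions)
  out
}

#' Simulator configuration
#'
#' Bundles everything the peak-area simulator needs: the panel, the true
#' per-analyte linear detector responses, per-column multiplicative
#' sensitivity factors, the fractional CV of the multiplicative area
#' noise, the censoring thresholds, the sample preparation, and a
#' mandatory seed.
#'
#' By default three analytical columns are simulated whose per-analyte
#' sensitivities differ by +/-5% in a fixed cyclic pattern (the
#' reference analyte's gain is 1 on every column), emulating the
#' column-to-column sensitivity drift that the cross-column RCF summary
#' is meant to absorb.
#'
#' @param panel An `analyte_panel`.
#' @param true_curves Data frame `analyte`, `slope`, `intercept` — the
#'   true detector response per analyte (response per ng/mL, response).
#' @param column_profiles Data frame `column_id`, `analyte`, `factor`
#'   (multiplicative sensitivity, > 0), or `NULL` for the default
#'   three-column +/-5% drift pattern.
#' @param noise_cv Fractional CV of the multiplicative log-normal area
#'   noise (default 0.02, a typical targeted-MS injection CV).
#' @param seed Integer seed; mandatory — simulation without an explicit
#'   seed is an error, not a silent default.
#' @param loq_conc Optional named vector of per-analyte censoring
#'   thresholds, ng/mL.
#' @param prep A [sample_prep()] (default 0.5 g in 100 mL).
#' @return A `sim_config` object.
#' @export
sim_config <- function(panel, true_curves, column_profiles = NULL,
                       noise_cv = 0.02, seed, loq_conc = NULL,
                       prep = sample_prep(0.5, 100)) {
  panel <- as_analyte_panel(panel)
  if (missing(seed) || is.null(seed)) stopf("an explicit seed is required")
  if (!is_scalar_number(seed)) stopf("seed must be a single integer")
  missing_cols <- setdiff(c("analyte", "slope", "intercept"), names(true_curves))
  if (length(missing_cols) > 0L)
    stopf("true_curves missing columns: %s", paste(missing_cols, collapse = ", "))
  if (any(true_curves$slope <= 0)) stopf("true slopes must be > 0")
  missing_analytes <- setdiff(panel$name, true_curves$analyte)
  if (length(missing_analytes) > 0L)
    stopf("no true curve for: %s", paste(missing_analytes, collapse = ", "))
  if (!is_scalar_number(noise_cv) || noise_cv < 0) stopf("noise_cv must be >= 0")
  if (is.null(column_profiles))
    column_profiles <- default_column_profiles(panel)
  missing_cols <- setdiff(c("column_id", "analyte", "factor"), names(column_profiles))
  if (length(missing_cols) > 0L)
    stopf("column_profiles missing columns: %s", paste(missing_cols, collapse = ", "))
  if (any(column_profiles$factor <= 0)) stopf("sensitivity factors must be > 0")
  structure(list(panel = panel, true_curves = as.data.frame(true_curves),
                 column_profiles = as.data.frame(column_profiles),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 loq_conc = loq_conc, prep = prep),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_columns Number of simulated columns (default 3).
#' @param drift Half-width of the sensitivity drift (default 0.05).
#' @export
default_column_profiles <- function(panel, n_columns = 3, drift = 0.05) {
  panel <- as_analyte_panel(panel)
  ref <- reference_analyte(panel)
  base <- c(-1, 0, 1)
  rows <- lapply(seq_len(n_columns), function(j) {
    fac <- vapply(seq_len(nrow(panel)), function(i) {
      if (panel$name[i] == ref) return(1)
      shift <- (i - 1L) %% length(base)
      pattern <- base[((seq_along(base) + shift - 1L) %% length(base)) + 1L]
      1 + drift * pattern[((j - 1L) %% length(base)) + 1L]
    }, numeric(1))
    data.frame(column_id = sprintf("col%d", j), analyte = panel$name,
               factor = fac, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate peak areas from true concentrations
#'
#' For every injection row, the deterministic response is
#' `slope * column_factor * conc + intercept`, floored at 0, then
#' multiplied by log-normal noise `exp(N(0, noise_cv))`. With
#' `noise_cv = 0` the output is exactly the floored linear response. The
#' draw order is fixed by the row order of `truth` and the seed, so an
#' identical configuration reproduces the table bit for bit.
#'
#' @param truth Data frame `sample_id`, `column_id`, `analyte`,
#'   `replicate`, `conc_ng_ml` — one row per injection.
#' @param config A [sim_config()].
#' @param snr_per_conc Optional named per-analyte factor; when given, a
#'   noiseless `snr = snr_per_conc[analyte] * conc` column is filled in
#'   (for exercising LOD/LOQ estimation).
#' @return A peak table (see [validate_peak_table()]).
#' @export
simulate_areas <- function(truth, config, snr_per_conc = NULL) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  missing_cols <- setdiff(c("sample_id", "column_id", "analyte", "replicate", "conc_ng_ml"),
                          names(truth))
  if (length(missing_cols) > 0L)
    stopf("truth missing columns: %s", paste(missing_cols, collapse = ", "))
  if (any(truth$conc_ng_ml < 0)) stopf("true concentrations must be >= 0")
  tc <- config$true_curves
  slope <- tc$slope[match(truth$analyte, tc$analyte)]
  intercept <- tc$intercept[match(truth$analyte, tc$analyte)]
  if (anyNA(slope)) stopf("true curve missing for some analytes in truth")
  cp <- config$column_profiles
  fac <- cp$factor[match(paste(truth$column_id, truth$analyte),
                         paste(cp$column_id, cp$analyte))]
  if (anyNA(fac)) stopf("column profile missing for some (column, analyte) pairs")
  core <- pmax(slope * fac * truth$conc_ng_ml + intercept, 0)
  set.seed(config$seed)
  noise <- if (config$noise_cv > 0)
    exp(stats::rnorm(length(core), mean = 0, sd = config$noise_cv)) else 1
  snr <- if (is.null(snr_per_conc)) NA_real_
         else unname(snr_per_conc[truth$analyte]) * truth$conc_ng_ml
  validate_peak_table(data.frame(
    sample_id = truth$sample_id, column_id = truth$column_id,
    analyte = truth$analyte, replicate = truth$replicate,
    area = core * noise, snr = snr, stringsAsFactors = FALSE))
}

#' Censor quantification results below an LOQ threshold
#'
#' Rows whose back-calculated solution concentration falls strictly
#' below the analyte's threshold become censored with reason
#' `below_loq`; a value exactly at the threshold is retained. Censored
#' rows lose their numeric values — a below-LOQ result is a flag, never
#' a zero.
#'
#' @param results A quantification result table.
#' @param loq_conc Named numeric vector, analyte -> threshold (ng/mL).
#' @return The table with censoring applied.
#' @export
censor_below_loq <- function(results, loq_conc) {
  results <- validate_quant_table(results)
  if (is.null(names(loq_conc))) stopf("loq_conc must be a named vector")
  thr <- unname(loq_conc[results$analyte])
  hit <- !is.na(thr) & !is.na(results$solution_conc) & results$solution_conc < thr
  results$censored[hit] <- "below_loq"
  results$solution_conc[hit] <- NA_real_
  results$content[hit] <- NA_real_
  validate_quant_table(results)
}

#' Simulate a complete quantification study
#'
#' Draws true dry-weight contents for `n_samples` specimens (uniform
#' within per-analyte ranges), converts them to injected solution
#' concentrations through the configured sample preparation, and
#' simulates (a) standard-ladder injections of solutions II-VIII on every
#' configured column, for calibration and RCF estimation, and (b) sample
#' injections on the first column. All areas come from one
#' [simulate_areas()] call, so the study is reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param stocks Named stock concentrations, mg/mL, defining the ladder.
#' @param n_samples Number of specimens (default 10).
#' @param content_ranges Named list analyte -> c(lo, hi) true-content
#'   ranges, ug/g. Default: the span observed in the bundled
#'   ten-batch study ([matsutake_study()]).
#' @param n_replicates Injections per specimen (default 1).
#' @return A list: `truth` (sample_id, analyte, content, conc_ng_ml),
#'   `solutions` (ladder levels II-VIII), `standard_peaks`,
#'   `sample_peaks`, `primary_column`, `config`.
#' @export
simulate_study <- function(config, stocks, n_samples = 10,
                           content_ranges = NULL, n_replicates = 1) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  panel <- config$panel
  if (is.null(content_ranges)) content_ranges <- default_content_ranges()
  missing_analytes <- setdiff(panel$name, names(content_ranges))
  if (length(missing_analytes) > 0L)
    stopf("no content range for: %s", paste(missing_analytes, collapse = ", "))
  ladder <- build_dilution_ladder(stocks[panel$name])
  solutions <- ladder[ladder$label != "I", , drop = FALSE]
  columns <- unique(config$column_profiles$column_id)
  primary <- columns[1]

  set.seed(config$seed)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  truth <- do.call(rbind, lapply(panel$name, function(a) {
    rg <- content_ranges[[a]]
    data.frame(sample_id = sample_ids, analyte = a,
               content = stats::runif(n_samples, rg[1], rg[2]),
               stringsAsFactors = FALSE)
  }))
  truth$conc_ng_ml <- solution_from_content(truth$content, config$prep)

  std_truth <- do.call(rbind, lapply(columns, function(cid)
    data.frame(sample_id = solutions$label, column_id = cid,
               analyte = solutions$analyte, replicate = 1L,
               conc_ng_ml = solutions$conc_ng_ml, stringsAsFactors = FALSE)))
  smp_truth <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(sample_id = truth$sample_id, column_id = primary,
               analyte = truth$analyte, replicate = as.integer(r),
               conc_ng_ml = truth$conc_ng_ml, stringsAsFactors = FALSE)))
  all_peaks <- simulate_areas(rbind(std_truth, smp_truth), config)
  n_std <- nrow(std_truth)
  list(truth = truth, solutions = solutions,
       standard_peaks = all_peaks[seq_len(n_std), , drop = FALSE],
       sample_peaks = all_peaks[-seq_len(n_std), , drop = FALSE],
       primary_column = primary, config = config)
}

#' Run the full two-method workflow on peak tables
#'
#' Convenience composition of the pipeline stages: fit external-standard
#' curves on the primary column, derive per-column RCF entries and their
#' cross-column summary, quantify every sample by both the external
#' standard and the single-marker route, and compare the two with the
#' vector-angle cosine.
#'
#' @param standard_peaks Standard-injection peak table (all columns).
#' @param sample_peaks Sample peak table (primary column).
#' @param solutions Data frame `label`, `analyte`, `conc_ng_ml`.
#' @param reference Internal reference analyte name.
#' @param prep A [sample_prep()].
#' @param primary_column Column used for calibration and samples
#'   (default: the single column of `sample_peaks`).
#' @return A list: `curves`, `rcf_entries`, `rcf_summary` (`NULL` with a
#'   warning when only one column is available), `es`, `qams`,
#'   `similarity`.
#' @export
run_qams_workflow <- function(standard_peaks, sample_peaks, solutions,
                              reference, prep, primary_column = NULL) {
  if (is.null(primary_column)) {
    cols <- unique(validate_peak_table(sample_peaks)$column_id)
    if (length(cols) > 1L) stopf("sample peaks span several columns; name one")
    primary_column <- cols
  }
  curves <- fit_calibration_table(standard_peaks, solutions, column_id = primary_column)
  if (!reference %in% names(curves))
    stopf("reference analyte '%s' has no calibration data", reference)
  entries <- rcf_table(standard_peaks, solutions, reference)
  n_cols <- length(unique(entries$column_id))
  summary <- NULL
  if (n_cols >= 2L) {
    summary <- summarize_rcf(entries)
  } else {
    warnf("only one column in standard peaks; cross-column RCF summary omitted")
  }
  working_rcf <- if (is.null(summary)) entries else summary
  es <- es_quantify_table(sample_peaks, curves, prep, column_id = primary_column)
  qams <- qams_quantify_table(sample_peaks, curves[[reference]], working_rcf,
                              reference, prep, column_id = primary_column)
  list(curves = curves, rcf_entries = entries, rcf_summary = summary,
       es = es, qams = qams,
       similarity = similarity_report(es[es$analyte != reference, , drop = FALSE], qams))
}
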