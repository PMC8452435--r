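# Shared builders for the test suite. Everything is generated in code;
# the only on-disk inputs are the package's own bundled CSVs.

tiny_panel <- function() {
  as_analyte_panel(data.frame(
    name = c("G", "I", "U"),
    long_name = c("guanosine", "inosine", "uridine"),
    role = c("internal_reference", "target", "target"),
    parent_mz = c(282, 267, 243),
    quant_ion_mz = c(150, 135, 110),
    qual_ion_mz = c(133, 92, 152),
    cone_voltage = c(20, 40, 20),
    collision_energy = c(18, 22, 14),
    stringsAsFactors = FALSE))
}

tiny_curves <- function(intercepts = c(G = 0, I = 0, U = 0)) {
  data.frame(analyte = c("G", "I", "U"),
             slope = c(6564.29, 11955, 2565.74),
             intercept = unname(intercepts[c("G", "I", "U")]),
             stringsAsFactors = FALSE)
}

tiny_stocks <- function() c(G = 0.987, I = 0.928, U = 1.20)

# n_columns identical columns (factor 1 everywhere): no drift.
flat_profiles <- function(panel, n_columns = 3) {
  do.call(rbind, lapply(seq_len(n_columns), function(j)
    data.frame(column_id = sprintf("col%d", j), analyte = panel$name,
               factor = 1, stringsAsFactors = FALSE)))
}

# Standard + sample peak tables for a noiseless single-condition check.
noiseless_sim <- function(seed = 1, n_samples = 6, intercepts = c(G = 0, I = 0, U = 0),
                          profiles = NULL, noise_cv = 0) {
  panel <- tiny_panel()
  cfg <- sim_config(panel, tiny_curves(intercepts),
                    column_profiles = if (is.null(profiles)) flat_profiles(panel) else profiles,
                    noise_cv = noise_cv, seed = seed)
  ranges <- list(G = c(90, 190), I = c(30, 70), U = c(80, 190))
  simulate_study(cfg, tiny_stocks(), n_samples = n_samples,
                 content_ranges = ranges)
}
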