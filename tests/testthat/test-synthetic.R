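test_that("the dilution ladder reproduces the documented arithmetic", {
  lad <- build_dilution_ladder(c(G = 0.987, A = 1.1152))
  conc <- function(lab, a) lad$conc_ng_ml[lad$label == lab & lad$analyte == a]
  expect_equal(conc("II", "G"), 98.7)
  expect_equal(conc("VIII", "A"), 1.1152)
  expect_equal(conc("I", "G"), 9870)
  expect_error(build_dilution_ladder(c(G = -1)), "> 0")
  expect_error(build_dilution_ladder(c(0.5)), "named")
})

test_that("ladder ratios II -> VIII are exactly 1/{1,2.5,5,10,20,50,100}", {
  set.seed(41)
  stocks <- stats::setNames(runif(4, 0.1, 10), c("w", "x", "y", "z"))
  lad <- build_dilution_ladder(stocks)
  for (a in names(stocks)) {
    ii <- lad$conc_ng_ml[lad$label == "II" & lad$analyte == a]
    ratios <- vapply(c("II", "III", "IV", "V", "VI", "VII", "VIII"), function(lab)
      lad$conc_ng_ml[lad$label == lab & lad$analyte == a] / ii, numeric(1))
    expect_equal(unname(ratios), 1 / c(1, 2.5, 5, 10, 20, 50, 100))
    expect_equal(lad$conc_ng_ml[lad$label == "VIII" & lad$analyte == a] / ii, 0.01)
  }
})

test_that("noiseless areas are the exact floored linear response", {
  panel <- tiny_panel()
  cfg <- sim_config(panel, tiny_curves(c(G = -500, I = 10, U = 0)),
                    column_profiles = flat_profiles(panel, 1), noise_cv = 0, seed = 1)
  truth <- data.frame(sample_id = "s", column_id = "col1",
                      analyte = c("G", "I", "U"), replicate = 1L,
                      conc_ng_ml = c(10, 10, 0))
  peaks <- simulate_areas(truth, cfg)
  expect_equal(peaks$area, c(6564.29 * 10 - 500, 11955 * 10 + 10, 0))
  # conc 0 with negative intercept floors at 0 before noise
  truth0 <- truth; truth0$conc_ng_ml <- 0
  expect_equal(simulate_areas(truth0, cfg)$area, c(0, 10, 0))
})

test_that("simulation is bit-reproducible from its seed", {
  setup <- default_sim_setup(seed = 77)
  sim1 <- simulate_study(setup$config, setup$stocks, n_samples = 4)
  sim2 <- simulate_study(setup$config, setup$stocks, n_samples = 4)
  expect_identical(sim1$standard_peaks, sim2$standard_peaks)
  expect_identical(sim1$sample_peaks, sim2$sample_peaks)
  other <- default_sim_setup(seed = 78)
  sim3 <- simulate_study(other$config, other$stocks, n_samples = 4)
  expect_false(identical(sim1$sample_peaks$area, sim3$sample_peaks$area))
})

test_that("the multiplicative noise has the configured CV", {
  panel <- tiny_panel()
  cfg <- sim_config(panel, tiny_curves(), noise_cv = 0.02, seed = 13,
                    column_profiles = flat_profiles(panel, 1))
  truth <- data.frame(sample_id = sprintf("s%04d", 1:1000), column_id = "col1",
                      analyte = "G", replicate = 1L, conc_ng_ml = 50)
  area <- simulate_areas(truth, cfg)$area
  empirical_cv <- stats::sd(area) / mean(area)
  expect_lt(abs(empirical_cv - 0.02) / 0.02, 0.2)
})

test_that("below-LOQ censoring is strict and value-erasing", {
  q <- data.frame(sample_id = "s", analyte = c("I", "U", "G"),
                  solution_conc = c(5, 10, 20), content = c(1, 2, 4),
                  method = "ES", censored = NA_character_)
  out <- censor_below_loq(q, c(I = 10, U = 10, G = 10))
  expect_equal(out$censored, c("below_loq", NA, NA))  # exactly at threshold kept
  expect_true(is.na(out$solution_conc[1]) && is.na(out$content[1]))
  expect_equal(out$solution_conc[2], 10)
})

test_that("the bundled study matches its printed sources", {
  study <- matsutake_study()
  expect_equal(study$contents$es_ug_g[study$contents$sample_id == "SD-JL243" &
                                      study$contents$analyte == "G"], 186.1)
  rc <- study$rcf_columns
  expect_equal(rc$f_km[rc$target == "I" & rc$column_id == "BEH C18"], 1.925)
  expect_equal(unname(study$stocks["dA"]), 5.75)
  expect_equal(nrow(study$es), 90L)
  expect_equal(nrow(study$qams), 80L)  # no single-marker value for the marker
})

test_that("a noiseless simulated study is recovered exactly by both methods", {
  sim <- noiseless_sim(seed = 101, n_samples = 8)
  wf <- run_qams_workflow(sim$standard_peaks, sim$sample_peaks, sim$solutions,
                          "G", sim$config$prep)
  truth_key <- paste(sim$truth$sample_id, sim$truth$analyte)
  es_truth <- sim$truth$content[match(paste(wf$es$sample_id, wf$es$analyte), truth_key)]
  expect_equal(wf$es$content, es_truth, tolerance = 1e-9)
  qams_truth <- sim$truth$content[match(paste(wf$qams$sample_id, wf$qams$analyte), truth_key)]
  expect_equal(wf$qams$content, qams_truth, tolerance = 1e-9)
  expect_equal(wf$similarity$cos_theta, rep(1, nrow(wf$similarity)), tolerance = 1e-12)
})
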