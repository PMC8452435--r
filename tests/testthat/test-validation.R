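test_that("rsd matches hand computation and is scale invariant", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(0.447, 0.438, 0.480)), 4.86, tolerance = 1e-3)
  expect_equal(rsd(c(1.925, 2.002, 1.876)), 3.28, tolerance = 2e-3)
  expect_error(rsd(5), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
  set.seed(21)
  for (i in 1:10) {
    v <- runif(5, 1, 10); k <- runif(1, 0.1, 50)
    expect_equal(rsd(k * v), rsd(v), tolerance = 1e-12)
  }
})

test_that("spike recovery follows the standard definition", {
  expect_equal(recovery_pct(300, 150, 150), 100)
  expect_equal(recovery_pct(302.85, 150, 150), 101.9)
  expect_equal(recovery_pct(150, 150, 150), 0)
  expect_error(recovery_pct(1, 1, 0), "> 0")
  # invariant under common rescaling
  set.seed(22)
  for (i in 1:10) {
    f <- runif(1, 100, 400); n <- runif(1, 50, 200); a <- runif(1, 50, 200)
    k <- runif(1, 0.2, 5)
    expect_equal(recovery_pct(k * f, k * n, k * a), recovery_pct(f, n, a),
                 tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches textbook results and edge policies", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)

  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$f_stat, 13.5)                 # SSB = 13.5, SSW/df = 1
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  expect_error(one_way_anova(list(1, c(2, 3))), "at least 2")
  expect_warning(deg <- one_way_anova(list(c(1, 1), c(2, 2))), "infinite")
  expect_equal(deg$p_value, 0)
})

test_that("two-group ANOVA p-value equals the pooled t-test (F = t^2)", {
  set.seed(23)
  for (i in 1:10) {
    g1 <- rnorm(sample(3:8, 1), mean = runif(1, 0, 3))
    g2 <- rnorm(sample(3:8, 1), mean = runif(1, 0, 3))
    a <- one_way_anova(list(g1, g2))
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$f_stat, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-9)
  }
})

# Build a design-labelled validation peak table from the tiny panel by
# direct evaluation of the true response (optionally noisy).
make_validation_peaks <- function(noise_cv = 0, seed = 1) {
  panel <- tiny_panel()
  curves_df <- tiny_curves()
  prep <- sample_prep(0.5, 100)
  std_conc <- c(G = 39.48, I = 37.1, U = 48)        # a mid-ladder level
  native <- c(G = 150, I = 37, U = 100)             # ug/g
  added <- native                                   # 1:1 spike
  set.seed(seed)
  rows <- list()
  emit <- function(design, sample_id, analyte, replicate, conc) {
    slope <- curves_df$slope[curves_df$analyte == analyte]
    area <- slope * conc * exp(rnorm(1, 0, noise_cv))
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, column_id = "col1", analyte = analyte,
      replicate = replicate, area = area, snr = NA_real_, design = design,
      stringsAsFactors = FALSE)
  }
  for (a in panel$name) {
    for (r in 1:6) emit("intraday", "std_III", a, r, std_conc[[a]])
    for (r in 1:6) emit("interday", "std_III_d", a, r, std_conc[[a]])
    for (r in 1:6) emit("repeatability", "SMP", a, r, solution_from_content(native[[a]], prep))
    for (r in 1:6) emit("recovery_native", "SMP_nat", a, r, solution_from_content(native[[a]], prep))
    for (r in 1:6) emit("recovery_spiked", "SMP_spk", a, r,
                        solution_from_content(native[[a]] + added[[a]], prep))
  }
  list(peaks = do.call(rbind, rows),
       curves = lapply(stats::setNames(panel$name, panel$name), function(a)
         calibration_curve(curves_df$slope[curves_df$analyte == a], 0,
                           1e-6, 1e6, analyte = a)),
       prep = prep,
       added = data.frame(analyte = names(added), added = unname(added)))
}

test_that("a noiseless validation design yields zero RSDs and 100% recovery", {
  v <- make_validation_peaks(noise_cv = 0)
  rep <- validation_report(v$peaks, v$curves, v$prep, added = v$added)
  expect_equal(rep$precision$rsd_pct, rep(0, nrow(rep$precision)), tolerance = 1e-9)
  expect_equal(rep$precision$n, rep(6L, nrow(rep$precision)))
  expect_equal(rep$recovery$mean_recovery_pct, rep(100, 3), tolerance = 1e-9)
})

test_that("2% injection noise produces small but nonzero intraday RSDs", {
  v <- make_validation_peaks(noise_cv = 0.02, seed = 42)
  rep <- validation_report(v$peaks, v$curves, v$prep, added = v$added)
  intra <- rep$precision$rsd_pct[rep$precision$kind == "intraday"]
  expect_true(all(intra > 0 & intra < 6))
})

test_that("missing design labels are an error", {
  v <- make_validation_peaks()
  no_rep <- v$peaks[v$peaks$design != "repeatability", ]
  expect_error(validation_report(no_rep, v$curves, v$prep, added = v$added),
               "repeatability")
  nat_only <- v$peaks[v$peaks$design != "recovery_spiked", ]
  expect_error(validation_report(nat_only, v$curves, v$prep, added = v$added),
               "recovery")
})

test_that("recovery without an added-amount table is an error", {
  v <- make_validation_peaks()
  expect_error(validation_report(v$peaks, v$curves, v$prep, added = NULL),
               "added")
})
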