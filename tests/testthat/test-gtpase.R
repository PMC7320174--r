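test_that("standard curve fitting is exact at zero noise and shifts only the intercept under offsets", {
  pl <- simulate_gtpase_plate(rate_uM_per_s = 0.05, noise_sd = 0,
                              curve_slope = 0.02, curve_intercept = 0.05)
  cv <- fit_standard_curve(pl$standards, blank = 0)
  expect_equal(cv$slope, 0.02, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cv$r2, 1, tolerance = 1e-12)

  std2 <- pl$standards
  std2$absorbance <- std2$absorbance + 0.1
  cv2 <- fit_standard_curve(std2, blank = 0)
  expect_equal(cv2$slope, cv$slope, tolerance = 1e-12)
  expect_equal(cv2$intercept, cv$intercept + 0.1, tolerance = 1e-12)

  expect_error(fit_standard_curve(data.frame(conc_uM = c(1, 2, 3),
                                             absorbance = 1:3)), ">= 4")
  expect_error(fit_standard_curve(data.frame(conc_uM = rep(2, 5),
                                             absorbance = 1:5)), "dilution")
})

test_that("the zero-noise pipeline recovers the production rate exactly", {
  pl <- simulate_gtpase_plate(rate_uM_per_s = 0.05, noise_sd = 0)
  cv <- fit_standard_curve(pl$standards, blank = pl$blank_standard)
  act <- activity_from_timeseries(pl$samples$time_s, pl$samples$absorbance,
                                  cv, blank = pl$blank_sample)
  expect_equal(act$rate_well, 0.05, tolerance = 1e-10)
  expect_equal(act$rate_reaction, 0.05 * 50 / 13, tolerance = 1e-10)
  expect_equal(act$turnover, act$rate_reaction * 60 / 5, tolerance = 1e-12)

  # flat absorbances give rate 0
  act0 <- activity_from_timeseries(seq(0, 120, 20), rep(0.05, 7), cv,
                                   blank = 0.05)
  expect_equal(act0$rate_well, 0, tolerance = 1e-12)
})

test_that("normalization against a reference reports the phenotype fraction", {
  plw <- simulate_gtpase_plate(rate_uM_per_s = 0.06, noise_sd = 0, seed = 1)
  plm <- simulate_gtpase_plate(rate_uM_per_s = 0.03, noise_sd = 0, seed = 2)
  cv <- fit_standard_curve(plw$standards, blank = plw$blank_standard)
  wt <- activity_from_timeseries(plw$samples$time_s, plw$samples$absorbance,
                                 cv, blank = plw$blank_sample)
  mut <- activity_from_timeseries(plm$samples$time_s, plm$samples$absorbance,
                                  cv, blank = plm$blank_sample,
                                  reference = wt$rate_reaction)
  expect_equal(mut$normalized, 0.5, tolerance = 1e-10)
  # a reference normalized to itself is identically 1
  wt2 <- activity_from_timeseries(plw$samples$time_s, plw$samples$absorbance,
                                  cv, blank = plw$blank_sample,
                                  reference = wt$rate_reaction)
  expect_equal(wt2$normalized, 1)
})

test_that("rate recovery bias stays small at realistic absorbance noise", {
  rate <- 0.05
  rec <- vapply(1:40, function(s) {
    pl <- simulate_gtpase_plate(rate_uM_per_s = rate, noise_sd = 0.005,
                                seed = s)
    cv <- fit_standard_curve(pl$standards, blank = pl$blank_standard)
    activity_from_timeseries(pl$samples$time_s, pl$samples$absorbance, cv,
                             blank = pl$blank_sample)$rate_well
  }, 0)
  expect_lt(abs(mean(rec) - rate) / rate, 0.02)
})

test_that("negative fitted rates are flagged, not clamped", {
  cv <- structure(list(slope = 0.02, intercept = 0, r2 = 1,
                       concentrations = c(40, 20, 10, 5)),
                  class = "standard_curve")
  expect_warning(
    act <- activity_from_timeseries(c(0, 20, 40), c(0.30, 0.20, 0.10), cv),
    "negative")
  expect_lt(act$rate_well, 0)
  expect_true(act$negative_rate_warning)
})
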