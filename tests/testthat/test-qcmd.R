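test_that("Sauerbrey conversion: sign, overtone normalization, linearity", {
  expect_equal(sauerbrey_coverage(0), 0)
  # -9 Hz raw at the 9th overtone with the standard 5 MHz crystal constant
  expect_equal(sauerbrey_coverage(-9, overtone = 9, mass_sensitivity = 17.7),
               17.7)
  expect_equal(sauerbrey_coverage(-5, normalized = TRUE,
                                  mass_sensitivity = 17.7), 88.5)
  x <- c(-1, -2.5, 4)
  expect_equal(sauerbrey_coverage(2 * x), 2 * sauerbrey_coverage(x))
  expect_error(sauerbrey_coverage(-9, overtone = 8), "odd")
  expect_error(sauerbrey_coverage(-9, mass_sensitivity = 0), "sensitivity")
})

test_that("bilayer-formation check passes at -25 Hz and fails off-target", {
  tr <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 0,
                            noise_sd_hz = 0)
  res <- detect_slb_formation(tr)
  expect_true(res$pass)
  expect_equal(res$plateau_hz, -25, tolerance = 1e-3)

  tr40 <- simulate_qcmd_trace(slb_shift_hz = 40, protein_shift_hz = 0,
                              noise_sd_hz = 0)
  expect_false(detect_slb_formation(tr40)$pass)

  # median plateau is robust to realistic noise
  trn <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 0,
                             noise_sd_hz = 0.3, seed = 9)
  expect_true(detect_slb_formation(trn)$pass)
})

test_that("binding shifts are median step heights and antisymmetric under window swap", {
  flat <- data.frame(time = 0:99, delta_f = rep(-25, 100))
  expect_equal(extract_binding_shift(flat, c(0, 40), c(60, 99)), 0)

  tr <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 12,
                            noise_sd_hz = 0.2, seed = 3)
  ann <- attr(tr, "annotations")
  bw <- c(ann$t_protein_injection - 100, ann$t_protein_injection - 5)
  pw <- c(max(tr$time) - 100, max(tr$time))
  shift <- extract_binding_shift(tr, bw, pw)
  expect_lt(abs(shift - (-12)), 0.3)
  expect_equal(extract_binding_shift(tr, pw, bw), -shift)

  expect_error(extract_binding_shift(flat, c(0, 60), c(40, 99)), "overlap")
  expect_error(extract_binding_shift(flat, c(200, 300), c(60, 99)), "empty")
})

test_that("fold changes reproduce the printed construct comparisons", {
  tab <- data.frame(
    label = c("mts[FtsA]", "mts[L268E]", "mts[MinD]", "2xmts[MinD]"),
    concentration_uM = 5,
    coverage = c(102.2, 6.1, 16.4, 29.1))
  fc <- fold_changes(tab, reference_label = "mts[L268E]", at_concentration = 5)
  ftsa <- fc[fc$label == "mts[FtsA]", ]
  expect_equal(ftsa$fold, 102.2 / 6.1, tolerance = 1e-12)
  expect_equal(ftsa$display, "17-fold")

  fc2 <- fold_changes(tab, "mts[MinD]", 5)
  expect_equal(fc2$display[fc2$label == "mts[FtsA]"], "6-fold")
  fc3 <- fold_changes(tab, "2xmts[MinD]", 5)
  expect_equal(fc3$display[fc3$label == "mts[FtsA]"], "3.5-fold")

  expect_error(fold_changes(tab, "missing", 5), "absent")
})

test_that("simulated binding steps round-trip through shift extraction and Sauerbrey", {
  true_shift <- 10; noise <- 0.2
  tr <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = true_shift,
                            noise_sd_hz = noise, seed = 21)
  ann <- attr(tr, "annotations")
  bw <- c(ann$t_protein_injection - 150, ann$t_protein_injection - 10)
  pw <- c(max(tr$time) - 150, max(tr$time))
  shift <- extract_binding_shift(tr, bw, pw)
  cov <- sauerbrey_coverage(shift, normalized = TRUE)
  cov_true <- sauerbrey_coverage(-true_shift, normalized = TRUE)
  n <- 141
  sem <- 17.7 * 1.2533 * noise / sqrt(n) * sqrt(2)
  expect_lt(abs(cov - cov_true), 3 * sem + 17.7 * 0.05)
})
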