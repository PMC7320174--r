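test_that("config validation names the offending field and adjusts the pattern period", {
  expect_error(ring_sim_config(radius = -1), "radius")
  expect_error(ring_sim_config(peak_photons = 10, background_photons = 20),
               "peak_photons")
  expect_error(ring_sim_config(n_frames = 1), "n_frames")
  expect_error(ring_sim_config(frame_interval = 0), "frame_interval")

  cfg <- ring_sim_config(radius = 500, pattern_period = 600)
  circ <- 2 * pi * 500
  expect_equal(cfg$n_pattern_periods, round(circ / 600))
  expect_equal(cfg$pattern_period * cfg$n_pattern_periods, circ)
})

test_that("a static noise-free ring gives identical frames; equal seeds give identical movies", {
  cfg <- ring_sim_config(speed = 0, bleach_rate = 0, n_frames = 5, seed = 11)
  mv <- simulate_ring_movie(cfg, noise = FALSE)
  for (k in 2:5) expect_equal(mv$data[, , k], mv$data[, , 1])

  m1 <- simulate_ring_movie(ring_sim_config(seed = 42, n_frames = 4))
  m2 <- simulate_ring_movie(ring_sim_config(seed = 42, n_frames = 4))
  m3 <- simulate_ring_movie(ring_sim_config(seed = 43, n_frames = 4))
  expect_identical(m1$data, m2$data)
  expect_false(identical(m1$data, m3$data))
})

test_that("the angular step per frame follows speed * dt / radius", {
  cfg <- ring_sim_config(speed = 35, radius = 500, frame_interval = 3,
                         n_frames = 2)
  mv <- simulate_ring_movie(cfg, noise = FALSE)
  gt <- attr(mv, "ground_truth")
  expect_equal(gt$angular_step_per_frame, 35 * 3 / 500)  # 0.21 rad
  expect_equal(gt$angular_speed, 35 / 500)
})

test_that("expected photon flux is conserved over time without bleaching or drift", {
  cfg <- ring_sim_config(speed = 40, bleach_rate = 0, n_frames = 12, seed = 2)
  mv <- simulate_ring_movie(cfg, noise = FALSE)
  sums <- apply(mv$data, 3, sum)
  expect_lt(stats::sd(sums) / mean(sums), 1e-3)
})

test_that("noise-free rotation shifts the sampled azimuthal profile by the closed-form step", {
  # speed chosen so the pattern advances exactly 2 arc columns per frame
  r_px <- 500 / 65
  n <- round(2 * pi * r_px)
  arc_step_nm <- 2 * pi * 500 / n
  sp <- 2 * arc_step_nm / 3
  s <- sim_ring(speed = sp, noise = FALSE, bleach_rate = 0, n_frames = 10)
  prof0 <- sample_trajectory(s$movie$data[, , 1], s$roi)
  for (t in c(3, 7)) {
    proft <- sample_trajectory(s$movie$data[, , t + 1], s$roi)
    shifted <- prof0[((seq_len(n) - 1 - 2 * t) %% n) + 1]
    expect_gt(stats::cor(proft, shifted), 0.999)
  }
})

test_that("QCM-D trace plateaus at the prescribed shifts and is robust in the median", {
  tr <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 0,
                            noise_sd_hz = 0)
  expect_equal(tail(tr$delta_f, 1), -25, tolerance = 1e-6)

  tr2 <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 10,
                             noise_sd_hz = 0)
  expect_equal(tail(tr2$delta_f, 1), -35, tolerance = 1e-4)
  ann <- attr(tr2, "annotations")
  expect_equal(ann$final_plateau_hz, -35)
  # transient vesicle overshoot dips below the bilayer plateau
  slb_seg <- tr2$delta_f[tr2$time >= ann$t_vesicle_injection &
                         tr2$time < ann$t_protein_injection]
  expect_lt(min(slb_seg), -25)

  # Monte-Carlo: noisy plateau median within 3 SEM of the truth
  tr3 <- simulate_qcmd_trace(slb_shift_hz = 25, protein_shift_hz = 0,
                             noise_sd_hz = 0.2, seed = 5)
  last <- tail(tr3$delta_f, 100)
  sem <- 1.2533 * 0.2 / sqrt(100)  # SEM of a median under Gaussian noise
  expect_lt(abs(stats::median(last) - (-25)), 3 * sem)
})

test_that("plate simulator emits the 1:2 serial dilution and exact zero-noise responses", {
  pl <- simulate_gtpase_plate(rate_uM_per_s = 0, std_top_uM = 40, n_std = 7,
                              curve_slope = 0.02, curve_intercept = 0.05,
                              noise_sd = 0)
  expect_equal(pl$standards$conc_uM,
               c(40, 20, 10, 5, 2.5, 1.25, 0.625, 0))
  # rate 0, noise 0: every sample absorbance equals the intercept
  expect_equal(pl$samples$absorbance, rep(0.05, 7), tolerance = 1e-12)
  expect_equal(pl$samples$time_s, seq(0, 120, by = 20))

  # noise 0: the standards regress exactly onto the generating line
  cv <- fit_standard_curve(pl$standards, blank = pl$blank_standard)
  expect_equal(cv$slope, 0.02, tolerance = 1e-10)
  expect_equal(cv$r2, 1, tolerance = 1e-10)

  expect_error(simulate_gtpase_plate(timepoints = c(0, 10, 10)), "increasing")
  expect_error(simulate_gtpase_plate(n_std = 3), "n_std")
})
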