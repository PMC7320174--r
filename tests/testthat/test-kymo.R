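make_movie <- function(frames, pixel_size = 65, frame_interval = 3) {
  movie_stack(array(unlist(frames), c(dim(frames[[1]]), length(frames))),
              pixel_size, frame_interval)
}

test_that("temporal averaging takes exact block means and rescales the frame clock", {
  frames <- lapply(1:10, function(v) matrix(v, 8, 8))
  mv <- make_movie(frames)
  av <- temporal_average(mv, 5)
  expect_equal(dim(av)[3], 2)
  expect_equal(unique(as.vector(av$data[, , 1])), 3)
  expect_equal(unique(as.vector(av$data[, , 2])), 8)
  expect_equal(av$frame_interval, 15)

  expect_equal(temporal_average(mv, 1)$data, mv$data, ignore_attr = TRUE)
  expect_error(temporal_average(mv, 11), "window")

  const <- temporal_average(make_movie(lapply(1:6, function(i) matrix(7, 8, 8))), 3)
  expect_true(all(const$data == 7))
})

test_that("two clicked points define the circle (diameter and center-edge modes)", {
  r1 <- circle_from_two_points(c(0, 0), c(0, 10))
  expect_equal(r1$center, c(0, 5))
  expect_equal(r1$radius_px, 5)

  r2 <- circle_from_two_points(c(3, 4), c(-3, -4))
  expect_equal(r2$center, c(0, 0))
  expect_equal(r2$radius_px, 5)

  r3 <- circle_from_two_points(c(2.5, 2.5), c(7.5, 7.5))
  expect_equal(r3$radius_px, 2.5 * sqrt(2), tolerance = 1e-12)

  r4 <- circle_from_two_points(c(10, 10), c(10, 14), mode = "center_edge")
  expect_equal(r4$center, c(10, 10))
  expect_equal(r4$radius_px, 4)

  expect_error(circle_from_two_points(c(1, 1), c(1, 1)), "differ")
  expect_error(circle_from_two_points(c(5, 1), c(5, 15), image_size = c(10, 10)),
               "margin")
})

test_that("trajectory sampling is exact on constant and affine images", {
  roi <- ring_roi(c(10, 10), 5)
  const <- matrix(3.7, 20, 20)
  expect_equal(sample_trajectory(const, roi), rep(3.7, roi$n_arc_samples))

  # bilinear interpolation reproduces a linear ramp exactly:
  # I(row, col) = col sampled on the circle gives c_c + r*cos(theta)
  ramp <- matrix(seq_len(20), 20, 20, byrow = TRUE)
  prof <- sample_trajectory(ramp, roi)
  theta <- 2 * pi * (seq_len(roi$n_arc_samples) - 1) / roi$n_arc_samples
  expect_equal(prof, 10 + 5 * cos(theta), tolerance = 1e-12)

  # radially symmetric ring: inner and outer offsets agree by symmetry
  rr <- sqrt(outer((1:41) - 21, rep(1, 41))^2 + outer(rep(1, 41), (1:41) - 21)^2)
  ringimg <- exp(-(rr - 10)^2 / 8)
  roi2 <- ring_roi(c(21, 21), 10)
  p_in <- sample_trajectory(ringimg, roi2, -1)
  p_out <- sample_trajectory(ringimg, roi2, +1)
  expect_equal(p_in, p_out, tolerance = 0.02)

  expect_error(sample_trajectory(const, ring_roi(c(2, 2), 5)), "outside")
})

test_that("phase-correlation drift correction recovers known shifts", {
  s <- sim_ring(speed = 0, noise = FALSE, n_frames = 2, bleach_rate = 0)
  base <- s$movie$data[, , 1]
  shifts_true <- rbind(c(0, 0), c(2, -3), c(-1, 4), c(3, 0))
  frames <- lapply(seq_len(nrow(shifts_true)), function(i) {
    f <- ringdyn:::translate_frame(base, -shifts_true[i, ])
    f[f < 0] <- 0
    f
  })
  mv <- make_movie(frames)
  dc <- drift_correct(mv)
  expect_equal(dc$shifts, shifts_true, tolerance = 0.1,
               ignore_attr = TRUE)
  # inverse consistency: registered frames match frame 1 away from borders
  int <- 10:38
  for (k in 2:4)
    expect_equal(dc$movie$data[int, int, k], base[int, int],
                 tolerance = 0.05 * max(base))

  # zero drift: all shifts about zero
  mv0 <- make_movie(list(base, base, base))
  expect_true(all(abs(drift_correct(mv0)$shifts) < 0.05))

  expect_warning(drift_correct(make_movie(list(matrix(1, 8, 8), matrix(1, 8, 8)))),
                 "constant")
})

test_that("kymograph assembly: static movies give repeated rows, calibration is exact", {
  s <- sim_ring(speed = 0, noise = FALSE, bleach_rate = 0, n_frames = 6)
  k <- build_kymograph(s$movie, s$roi)
  for (t in 2:6) expect_equal(k$data[t, ], k$data[1, ])

  # uniform movie -> constant kymograph
  mvu <- make_movie(lapply(1:4, function(i) matrix(5, 30, 30)))
  roiu <- ring_roi(c(15, 15), 6)
  ku <- build_kymograph(mvu, roiu)
  expect_true(all(ku$data == 5))

  # calibration identity: arc_step * n = 2*pi*r*pixel_size
  expect_equal(k$arc_step * s$roi$n_arc_samples,
               2 * pi * s$roi$radius_px * s$movie$pixel_size)
})

test_that("rotating the ROI angular origin cyclically permutes kymograph columns", {
  s <- sim_ring(speed = 30, noise = FALSE, n_frames = 10)
  n <- s$roi$n_arc_samples
  k0 <- build_kymograph(s$movie, s$roi)
  kshift <- 5
  roi2 <- ring_roi(s$roi$center, s$roi$radius_px,
                   theta_offset = 2 * pi * kshift / n)
  k2 <- build_kymograph(s$movie, roi2)
  perm <- ((seq_len(n) - 1 + kshift) %% n) + 1
  expect_equal(k2$data, k0$data[, perm], tolerance = 1e-10)
})

test_that("simulated rotation appears as a cyclic column shift of the kymograph", {
  r_px <- 500 / 65
  n <- round(2 * pi * r_px)
  arc_step_nm <- 2 * pi * 500 / n
  sp <- 2 * arc_step_nm / 3  # exactly 2 columns per frame
  s <- sim_ring(speed = sp, noise = FALSE, bleach_rate = 0, n_frames = 8)
  k <- build_kymograph(s$movie, s$roi)
  for (t in c(2, 5)) {
    shifted <- k$data[1, ((seq_len(n) - 1 - 2 * (t - 1)) %% n) + 1]
    expect_gt(stats::cor(k$data[t, ], shifted), 0.999)
  }
})

test_that("three-trajectory averaging reduces pixel noise on a static ring", {
  s <- sim_ring(speed = 0, bleach_rate = 0, n_frames = 60, seed = 8)
  k3 <- build_kymograph(s$movie, s$roi)
  k1 <- t(apply(s$movie$data, 3, function(f) sample_trajectory(f, s$roi, 0)))
  var3 <- mean(apply(k3$data, 2, stats::var))
  var1 <- mean(apply(k1, 2, stats::var))
  expect_lt(var3, var1)
})
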