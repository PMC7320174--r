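# Independent oracles and small fixtures used across the suite.

# Brute-force stripe-alignment slope search: shear each time row backwards
# along the candidate slope (cyclic, linear interpolation) and score the
# candidate by the variance of the aligned column sums. The stripe-aligned
# shear maximizes that variance. Independent of the Fourier-phase route.
radon_slope <- function(K, slope_grid) {
  Tn <- nrow(K); N <- ncol(K)
  j0 <- seq_len(N) - 1
  score <- vapply(slope_grid, function(s) {
    prof <- numeric(N)
    for (t in seq_len(Tn)) {
      pos <- (j0 + s * (t - 1)) %% N
      i0 <- floor(pos); frac <- pos - i0
      prof <- prof + K[t, (i0 %% N) + 1] * (1 - frac) +
        K[t, ((i0 + 1) %% N) + 1] * frac
    }
    stats::var(prof)
  }, 0)
  slope_grid[which.max(score)]
}

# Emulated manual stripe annotation: track the ridge displacement between
# consecutive kymograph rows by circular cross-correlation (parabolic
# sub-sample refinement, step capped at half a pattern period), accumulate
# the path, and return two points on that ridge for estimate_slope_manual.
ridge_manual_points <- function(kymo, max_step) {
  K <- kymo$data
  Tn <- nrow(K); N <- ncol(K)
  total <- 0
  steps <- numeric(Tn - 1)
  for (t in seq_len(Tn - 1)) {
    a <- K[t, ] - mean(K[t, ]); b <- K[t + 1, ] - mean(K[t + 1, ])
    cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) / N
    j <- seq_len(N) - 1
    lags <- ifelse(j > N / 2, j - N, j)
    keep <- abs(lags) <= max_step
    i <- which(keep)[which.max(cc[keep])]
    # parabolic refinement on the cyclic grid
    im <- cc[((i - 2) %% N) + 1]; i0 <- cc[i]; ip <- cc[(i %% N) + 1]
    den <- im - 2 * i0 + ip
    d <- if (abs(den) < .Machine$double.eps) 0 else
      max(-0.5, min(0.5, 0.5 * (im - ip) / den))
    steps[t] <- lags[i] + d
  }
  slope <- mean(steps)
  # pick the second click so the annotated line stays on the displayed
  # kymograph (a user clicks before the stripe wraps)
  dt <- max(1, floor(min(Tn - 1, (N / 2 - 1) / max(abs(slope), 1e-3))))
  list(p_a = c(1, N / 2), p_b = c(1 + dt, N / 2 + slope * dt))
}

# standard simulated ring + matching two-point ROI, centered in the image
sim_ring <- function(speed = 35, seed = 1, noise = TRUE, ...) {
  cfg <- ring_sim_config(speed = speed, seed = seed, ...)
  movie <- simulate_ring_movie(cfg, noise = noise)
  r_px <- cfg$radius / cfg$pixel_size
  roi <- circle_from_two_points(c(cfg$center[1], cfg$center[2] - r_px),
                                c(cfg$center[1], cfg$center[2] + r_px),
                                image_size = cfg$image_size)
  list(cfg = cfg, movie = movie, roi = roi,
       truth = attr(movie, "ground_truth"))
}

# phase-plane stripe kymograph K[t, j] = cos(2*pi*(j - s*t)/lambda),
# lambda dividing N so the columns wrap consistently
stripe_kymo <- function(Tn = 100, N = 48, lambda = 8, s = 1.5,
                        arc_step = 65, frame_interval = 3) {
  tt <- matrix(0:(Tn - 1), Tn, N)
  jj <- matrix(0:(N - 1), Tn, N, byrow = TRUE)
  kymograph(cos(2 * pi * (jj - s * tt) / lambda), arc_step, frame_interval)
}
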