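#' Configuration for the rotating-ring movie simulator
#'
#' Defines the ground truth for a synthetic TIRF movie of one membrane-bound
#' FtsZ ring: a radially Gaussian annulus whose azimuthal intensity is
#' cos^2-modulated with a fixed arc period, rotating rigidly at a constant
#' tangential speed (the kinematic signature of treadmilling), imaged
#' through a Gaussian PSF with Poisson shot noise, exponential
#' photobleaching and optional lateral stage drift.
#'
#' The circumference `2*pi*radius` is forced to an integer number of pattern
#' periods by adjusting `pattern_period`, so the azimuthal pattern is
#' continuous across the wrap point. The ground-truth angular speed is
#' `speed / radius` rad/s; positive `speed` rotates the pattern toward
#' increasing theta (counter-clockwise in (row, col) coordinates).
#'
#' Defaults describe the imaging conditions the package targets: a 100x
#' TIRF objective with a 6.5 um sCMOS camera pixel (65 nm/px), a
#' diffraction-limited PSF for 488 nm excitation at NA 1.49 (sigma about
#' 110 nm), 3 s frame intervals, and rings of about 1 um diameter.
#'
#' @param image_size integer `(H, W)` in pixels.
#' @param pixel_size nm per pixel.
#' @param frame_interval s between frames.
#' @param n_frames number of frames (>= 2).
#' @param center sub-pixel `(row, col)` ring center (1-based); default image
#'   center.
#' @param radius ring radius in nm.
#' @param speed signed tangential treadmilling speed in nm/s; positive =
#'   counter-clockwise in image coordinates.
#' @param pattern_period azimuthal intensity period along the circumference,
#'   nm. Adjusted to the nearest value dividing the circumference.
#' @param ring_width radial Gaussian sigma of the annulus, nm.
#' @param psf_sigma Gaussian PSF sigma, nm.
#' @param peak_photons expected photons/pixel at pattern maxima (before PSF).
#' @param background_photons expected photons/pixel off the ring.
#' @param bleach_rate photobleaching rate, 1/s.
#' @param drift_velocity `(row, col)` lateral drift in nm/s.
#' @param seed integer RNG seed.
#' @return A validated list of class `ring_sim_config`. The adjusted pattern
#'   period and derived quantities are stored in fields `pattern_period`
#'   (adjusted), `n_pattern_periods`, and `angular_speed` (rad/s).
#' @export
ring_sim_config <- function(image_size = c(48L, 48L),
                            pixel_size = 65,
                            frame_interval = 3,
                            n_frames = 100L,
                            center = NULL,
                            radius = 500,
                            speed = 35,
                            pattern_period = 600,
                            ring_width = 100,
                            psf_sigma = 110,
                            peak_photons = 200,
                            background_photons = 20,
                            bleach_rate = 0.003,
                            drift_velocity = c(0, 0),
                            seed = 1L) {
  fail <- function(field, msg) stop(sprintf("ring_sim_config: field '%s' %s", field, msg))
  if (length(image_size) != 2L || any(image_size < 8)) fail("image_size", "must be (H, W), each >= 8")
  if (pixel_size <= 0) fail("pixel_size", "must be > 0")
  if (frame_interval <= 0) fail("frame_interval", "must be > 0")
  if (n_frames < 2) fail("n_frames", "must be >= 2")
  if (radius <= 0) fail("radius", "must be > 0")
  if (pattern_period <= 0) fail("pattern_period", "must be > 0")
  if (ring_width <= 0) fail("ring_width", "must be > 0")
  if (psf_sigma <= 0) fail("psf_sigma", "must be > 0")
  if (background_photons < 0) fail("background_photons", "must be >= 0")
  if (peak_photons <= background_photons) fail("peak_photons", "must exceed background_photons")
  if (length(drift_velocity) != 2L) fail("drift_velocity", "must be (row, col) nm/s")
  if (is.null(center)) center <- (as.numeric(image_size) + 1) / 2
  if (length(center) != 2L) fail("center", "must be (row, col)")

  circumference <- 2 * pi * radius
  m <- max(1L, round(circumference / pattern_period))
  structure(list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    center = as.numeric(center), radius = radius, speed = speed,
    pattern_period = circumference / m, n_pattern_periods = m,
    ring_width = ring_width, psf_sigma = psf_sigma,
    peak_photons = peak_photons, background_photons = background_photons,
    bleach_rate = bleach_rate, drift_velocity = as.numeric(drift_velocity),
    seed = as.integer(seed),
    angular_speed = speed / radius
  ), class = "ring_sim_config")
}

# Noise-free expectation image of one frame (photons/pixel), at time t_s.
ring_expectation_frame <- function(config, t_s) {
  H <- config$image_size[1]; W <- config$image_size[2]
  cr <- config$center[1] + config$drift_velocity[1] * t_s / config$pixel_size
  cc <- config$center[2] + config$drift_velocity[2] * t_s / config$pixel_size
  dr <- matrix(seq_len(H) - cr, H, W)
  dc <- matrix(seq_len(W) - cc, H, W, byrow = TRUE)
  r_nm <- sqrt(dr^2 + dc^2) * config$pixel_size
  theta <- atan2(dr, dc)
  ringprof <- exp(-(r_nm - config$radius)^2 / (2 * config$ring_width^2))
  m <- config$n_pattern_periods
  pattern <- cos((m / 2) * (theta - config$angular_speed * t_s))^2
  amp <- (config$peak_photons - config$background_photons) *
    exp(-config$bleach_rate * t_s)
  config$background_photons + amp * ringprof * pattern
}

#' Simulate a rotating-ring TIRF movie with known ground truth
#'
#' Renders the noise-free expectation of each frame (annulus, azimuthal
#' cos^2 pattern rotated by `speed * t / radius`, photobleaching, drift),
#' convolves it with the Gaussian PSF, and draws pixel values from a Poisson
#' distribution with that expectation. With `noise = FALSE` the expectation
#' movie itself is returned, which oracle tests rely on.
#'
#' @param config a [ring_sim_config].
#' @param noise draw Poisson photon noise? Default `TRUE`.
#' @param read_noise_sd optional Gaussian read-noise sd (photons), added after
#'   the Poisson draw and clamped at zero; 0 disables it.
#' @return A [movie_stack] with attribute `ground_truth`: a list with the
#'   config, the angular speed (rad/s), and the azimuthal column shift per
#'   frame implied by the kinematics.
#' @export
simulate_ring_movie <- function(config, noise = TRUE, read_noise_sd = 0) {
  stopifnot(inherits(config, "ring_sim_config"))
  set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  Tn <- config$n_frames
  frames <- array(0, c(H, W, Tn))
  for (k in seq_len(Tn)) {
    frames[, , k] <- ring_expectation_frame(config, (k - 1) * config$frame_interval)
  }
  sigma_px <- config$psf_sigma / config$pixel_size
  frames <- EBImage::gblur(frames, sigma = sigma_px)
  frames[frames < 0] <- 0
  if (noise) {
    frames[] <- stats::rpois(length(frames), frames)
    if (read_noise_sd > 0) {
      frames[] <- frames + stats::rnorm(length(frames), 0, read_noise_sd)
      frames[frames < 0] <- 0
    }
  }
  movie <- movie_stack(frames, config$pixel_size, config$frame_interval)
  radius_px <- config$radius / config$pixel_size
  n_arc <- max(8L, round(2 * pi * radius_px))
  attr(movie, "ground_truth") <- list(
    config = config,
    angular_speed = config$angular_speed,
    angular_step_per_frame = config$angular_speed * config$frame_interval,
    column_shift_per_frame = config$angular_speed * config$frame_interval /
      (2 * pi) * n_arc,
    speed_nm_s = config$speed
  )
  movie
}

#' Simulate a QCM-D frequency-shift trace
#'
#' Produces an overtone-normalized frequency trace (Hz) with the canonical
#' shape of supported-lipid-bilayer formation followed by protein
#' adsorption: a flat baseline at 0; on vesicle injection a transient
#' overshoot dipping below the final bilayer plateau (vesicle adsorption
#' followed by rupture), relaxing to `-slb_shift_hz`; on protein injection
#' an exponential approach to `-(slb_shift_hz + protein_shift_hz)`; plus
#' white Gaussian noise.
#'
#' @param baseline_s duration of the initial buffer baseline, s.
#' @param slb_shift_hz magnitude of the bilayer frequency shift, Hz
#'   (normalized by overtone). The conventional hallmark of a good bilayer
#'   is about 25 Hz.
#' @param protein_shift_hz additional shift after protein injection, Hz.
#' @param noise_sd_hz Gaussian noise sd, Hz.
#' @param sample_rate samples per second.
#' @param seed RNG seed.
#' @param overtone odd overtone order recorded in the trace metadata
#'   (default 9).
#' @param slb_s,protein_s durations of the bilayer-formation and
#'   protein-adsorption segments, s.
#' @param overshoot_frac transient vesicle overshoot amplitude as a fraction
#'   of `slb_shift_hz`.
#' @param tau_slb_s,tau_protein_s relaxation time constants, s.
#' @return An object of class `qcmd_trace`: data.frame columns `time` (s)
#'   and `delta_f` (Hz, overtone-normalized), with attributes `overtone`,
#'   `normalized = TRUE` and `annotations` (ground-truth event times and
#'   plateau levels).
#' @export
simulate_qcmd_trace <- function(baseline_s = 300, slb_shift_hz = 25,
                                protein_shift_hz = 10, noise_sd_hz = 0.2,
                                sample_rate = 1, seed = 1L, overtone = 9L,
                                slb_s = 600, protein_s = 600,
                                overshoot_frac = 0.4,
                                tau_slb_s = 30, tau_protein_s = 60) {
  if (sample_rate <= 0) stop("simulate_qcmd_trace: sample_rate must be > 0")
  if (noise_sd_hz < 0) stop("simulate_qcmd_trace: noise_sd_hz must be >= 0")
  set.seed(seed)
  total_s <- baseline_s + slb_s + protein_s
  time <- seq(0, total_s, by = 1 / sample_rate)
  f <- numeric(length(time))
  t_ves <- baseline_s
  t_prot <- baseline_s + slb_s
  in_slb <- time >= t_ves & time < t_prot
  u <- time[in_slb] - t_ves
  # saturating drop to the bilayer plateau plus a transient overshoot that
  # dips below it (peaks at u = tau_slb_s, unit height)
  f[in_slb] <- -slb_shift_hz * (1 - exp(-3 * u / tau_slb_s)) -
    overshoot_frac * slb_shift_hz * (u / tau_slb_s) * exp(1 - u / tau_slb_s)
  in_prot <- time >= t_prot
  v <- time[in_prot] - t_prot
  f[in_prot] <- -slb_shift_hz - protein_shift_hz * (1 - exp(-v / tau_protein_s))
  if (noise_sd_hz > 0) f <- f + stats::rnorm(length(f), 0, noise_sd_hz)
  trace <- data.frame(time = time, delta_f = f)
  class(trace) <- c("qcmd_trace", "data.frame")
  attr(trace, "overtone") <- as.integer(overtone)
  attr(trace, "normalized") <- TRUE
  attr(trace, "annotations") <- list(
    t_vesicle_injection = t_ves, t_protein_injection = t_prot,
    slb_plateau_hz = -slb_shift_hz,
    final_plateau_hz = -(slb_shift_hz + protein_shift_hz))
  trace
}

#' Simulate a colorimetric phosphate-release assay plate
#'
#' Emits the two measurement series of a malachite-green style GTPase assay
#' with known ground truth: (i) a standards table from a 1:2 serial dilution
#' of the top phosphate standard plus a blank, read through a linear
#' absorbance response; (ii) a stopped-timepoint sample series whose
#' underlying phosphate concentration grows linearly at `rate_uM_per_s`.
#'
#' @param rate_uM_per_s ground-truth Pi production rate in the stopped well,
#'   uM/s.
#' @param timepoints strictly increasing sampling times, s. Default the
#'   seven points 0, 20, ..., 120 s.
#' @param std_top_uM top standard concentration, uM (default 40).
#' @param n_std number of serial-dilution standards (>= 4, default 7).
#' @param curve_slope linear absorbance response, AU/uM.
#' @param curve_intercept assay background absorbance, AU.
#' @param noise_sd absorbance noise sd, AU.
#' @param seed RNG seed.
#' @return A list of class `gtpase_plate`: `standards` (data.frame
#'   `conc_uM`, `absorbance`; the blank is the `conc_uM = 0` row),
#'   `samples` (data.frame `time_s`, `absorbance`), `blank_standard`,
#'   `blank_sample` (AU), and `truth` (the generating parameters).
#' @export
simulate_gtpase_plate <- function(rate_uM_per_s = 0.05,
                                  timepoints = seq(0, 120, by = 20),
                                  std_top_uM = 40, n_std = 7L,
                                  curve_slope = 0.02, curve_intercept = 0.05,
                                  noise_sd = 0.005, seed = 1L) {
  if (any(diff(timepoints) <= 0))
    stop("simulate_gtpase_plate: timepoints must be strictly increasing")
  if (n_std < 4) stop("simulate_gtpase_plate: n_std must be >= 4")
  set.seed(seed)
  conc <- std_top_uM * 2^(-(0:(n_std - 1)))
  conc <- c(conc, 0)  # blank
  std_abs <- curve_slope * conc + curve_intercept +
    stats::rnorm(length(conc), 0, noise_sd)
  pi_t <- rate_uM_per_s * timepoints
  smp_abs <- curve_slope * pi_t + curve_intercept +
    stats::rnorm(length(timepoints), 0, noise_sd)
  blank_sample <- curve_intercept + stats::rnorm(1, 0, noise_sd)
  structure(list(
    standards = data.frame(conc_uM = conc, absorbance = std_abs),
    samples = data.frame(time_s = timepoints, absorbance = smp_abs),
    blank_standard = std_abs[length(conc)],
    blank_sample = blank_sample,
    truth = list(rate_uM_per_s = rate_uM_per_s, curve_slope = curve_slope,
                 curve_intercept = curve_intercept, noise_sd = noise_sd)
  ), class = "gtpase_plate")
}
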