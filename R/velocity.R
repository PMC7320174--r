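#' Convert a stripe slope to a treadmilling velocity
#'
#' Under the assumption that the ring rotates directionally by
#' treadmilling, the physical circumferential velocity is
#' `slope [columns/row] * arc_step [nm/column] / frame_interval [s/row]`.
#'
#' @param estimate a `slope_estimate` with a defined `mean_slope`.
#' @param kymo the calibrated [kymograph] the estimate was computed on.
#' @return Signed velocity in nm/s, or `NA` if the estimate carries no
#'   reliable slope.
#' @export
slope_to_velocity <- function(estimate, kymo) {
  stopifnot(inherits(estimate, "slope_estimate"), inherits(kymo, "kymograph"))
  if (!is.finite(kymo$arc_step) || !is.finite(kymo$frame_interval))
    stop("slope_to_velocity: kymograph is not calibrated")
  if (is.na(estimate$mean_slope)) return(NA_real_)
  estimate$mean_slope * kymo$arc_step / kymo$frame_interval
}

#' Estimate a ring's diameter from its radial intensity profile
#'
#' Refines the ring center by an intensity-weighted centroid within a
#' window around the ROI on the time-averaged image, computes the
#' angular-averaged radial intensity profile, and returns twice the radius
#' of its interior maximum (parabolic sub-pixel refinement) in nm.
#'
#' @param movie a [movie_stack].
#' @param roi a [ring_roi] giving the approximate geometry.
#' @param r_step radial profile step in pixels (default 0.25).
#' @param search_halfwidth_px half-width of the radial search band around
#'   `roi$radius_px` (default 3 px).
#' @return Diameter in nm.
#' @export
estimate_ring_diameter <- function(movie, roi, r_step = 0.25,
                                   search_halfwidth_px = 3) {
  stopifnot(inherits(movie, "movie_stack"), inherits(roi, "ring_roi"))
  avg <- rowMeans(movie$data, dims = 2)
  H <- nrow(avg); W <- ncol(avg)
  # centroid refinement in a box spanning the ring plus a margin
  half <- ceiling(roi$radius_px + 2)
  r0 <- max(1, floor(roi$center[1] - half)); r1 <- min(H, ceiling(roi$center[1] + half))
  c0 <- max(1, floor(roi$center[2] - half)); c1 <- min(W, ceiling(roi$center[2] + half))
  box <- avg[r0:r1, c0:c1]
  wgt <- box - min(box)
  if (sum(wgt) <= 0) stop("estimate_ring_diameter: empty intensity window")
  rows <- matrix(r0:r1, nrow(box), ncol(box))
  cols <- matrix(c0:c1, nrow(box), ncol(box), byrow = TRUE)
  center <- c(sum(rows * wgt), sum(cols * wgt)) / sum(wgt)

  radii <- seq(max(1, roi$radius_px - search_halfwidth_px),
               roi$radius_px + search_halfwidth_px, by = r_step)
  prof <- vapply(radii, function(r) {
    n <- max(16L, round(2 * pi * r))
    theta <- 2 * pi * (seq_len(n) - 1) / n
    pr <- center[1] + r * sin(theta)
    pc <- center[2] + r * cos(theta)
    if (any(pr < 1 | pr > H | pc < 1 | pc > W)) return(NA_real_)
    mean(bilinear_sample(avg, pr, pc))
  }, 0)
  ok <- is.finite(prof)
  radii <- radii[ok]; prof <- prof[ok]
  if (length(prof) < 3) stop("estimate_ring_diameter: radial profile too short")
  i <- which.max(prof)
  if (i == 1 || i == length(prof))
    stop("estimate_ring_diameter: no interior radial maximum (not a ring)")
  # parabolic sub-step refinement
  den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
  delta <- if (abs(den) < .Machine$double.eps) 0 else
    max(-0.5, min(0.5, 0.5 * (prof[i - 1] - prof[i + 1]) / den))
  r_hat <- radii[i] + delta * r_step
  2 * r_hat * movie$pixel_size
}

#' Classify a ring as static or dynamic
#'
#' A ring is static when the slope estimator found no reliable slope (no
#' accepted windows) or when the absolute velocity falls below the
#' threshold. A profoundly GTPase-impaired variant assembling into
#' non-rotating rings is the archetypal static phenotype.
#'
#' @param velocity signed velocity in nm/s, or `NA` when no reliable slope
#'   was found.
#' @param n_windows_accepted number of quality-accepted estimation windows.
#' @param threshold_nm_s static/dynamic decision threshold, nm/s
#'   (default 5).
#' @return `TRUE` if static.
#' @export
classify_static <- function(velocity, n_windows_accepted = NULL,
                            threshold_nm_s = 5) {
  if (threshold_nm_s < 0) stop("classify_static: threshold must be >= 0")
  if (!is.null(n_windows_accepted) && n_windows_accepted == 0) return(TRUE)
  if (is.na(velocity)) return(TRUE)
  abs(velocity) < threshold_nm_s
}

#' Full per-ring analysis: kymograph, slope, velocity, diameter
#'
#' Convenience wrapper running the standard per-ring pipeline: build the
#' three-trajectory kymograph, optionally preprocess it (Savitzky-Golay +
#' CLAHE), estimate the stripe slope by windowed Fourier phase analysis,
#' convert to nm/s, measure the diameter, and classify static vs dynamic.
#'
#' @param movie a [movie_stack].
#' @param roi a [ring_roi].
#' @param ring_id identifier copied into the record.
#' @param preprocess apply [preprocess_kymograph] before slope estimation
#'   (default `TRUE`).
#' @param static_threshold_nm_s threshold for [classify_static].
#' @param ... passed to [estimate_slope_auto].
#' @return A one-row data.frame (ring_id, velocity, speed, diameter,
#'   static_flag, n_windows_accepted), with the `slope_estimate` and
#'   [kymograph] attached as attributes `estimate` and `kymograph`.
#' @export
analyze_ring <- function(movie, roi, ring_id = "ring1", preprocess = TRUE,
                         static_threshold_nm_s = 5, ...) {
  kymo <- build_kymograph(movie, roi)
  kin <- if (preprocess) preprocess_kymograph(kymo) else kymo
  est <- estimate_slope_auto(kin, ...)
  vel <- slope_to_velocity(est, kymo)
  dia <- tryCatch(estimate_ring_diameter(movie, roi), error = function(e) NA_real_)
  rec <- data.frame(
    ring_id = ring_id,
    velocity = vel,
    speed = abs(vel),
    diameter = dia,
    static_flag = classify_static(vel, est$n_accepted, static_threshold_nm_s),
    n_windows_accepted = est$n_accepted,
    stringsAsFactors = FALSE)
  attr(rec, "estimate") <- est
  attr(rec, "kymograph") <- kymo
  rec
}
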