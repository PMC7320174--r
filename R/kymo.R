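#' Temporal block averaging of a movie
#'
#' Replaces non-overlapping blocks of `window` consecutive frames by their
#' mean, emulating the frame averaging commonly applied to time-lapse ring
#' movies before kymograph analysis (typically 5-10 frames). A trailing
#' partial block is dropped and the frame interval is scaled by `window`.
#'
#' @param movie a [movie_stack].
#' @param window block size in frames, `1 <= window <= T`. `window = 1` is
#'   the identity.
#' @param spatial also apply a 3x3 spatial mean filter to each output frame?
#'   Off by default.
#' @return A [movie_stack] with `floor(T / window)` frames and
#'   `frame_interval * window`.
#' @export
temporal_average <- function(movie, window, spatial = FALSE) {
  stopifnot(inherits(movie, "movie_stack"))
  Tn <- n_frames(movie)
  window <- as.integer(window)
  if (window < 1 || window > Tn)
    stop(sprintf("temporal_average: window must be in [1, %d]", Tn))
  nb <- Tn %/% window
  d <- dim(movie$data)
  out <- array(0, c(d[1], d[2], nb))
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * window + 1):(b * window)
    out[, , b] <- rowMeans(movie$data[, , idx, drop = FALSE], dims = 2)
  }
  if (spatial) {
    k <- matrix(1 / 9, 3, 3)
    out <- EBImage::filter2(out, k)
    out[out < 0] <- 0
  }
  movie_stack(out, movie$pixel_size, movie$frame_interval * window)
}

# phase correlation between two equal-size frames; returns the (row, col)
# translation s such that b ~= a shifted by s, with parabolic sub-pixel
# refinement of the correlation peak on the cyclic grid.
phase_corr_shift <- function(a, b) {
  FA <- stats::fft(a); FB <- stats::fft(b)
  R <- FB * Conj(FA)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- arrayInd(which.max(r), dim(r))
  refine <- function(vals, i, n) {
    im <- vals[((i - 2) %% n) + 1]; i0 <- vals[i]; ip <- vals[(i %% n) + 1]
    den <- im - 2 * i0 + ip
    if (abs(den) < .Machine$double.eps) return(0)
    d <- 0.5 * (im - ip) / den
    max(-0.5, min(0.5, d))
  }
  nr <- nrow(r); nc <- ncol(r)
  dr <- refine(r[, pk[2]], pk[1], nr)
  dc <- refine(r[pk[1], ], pk[2], nc)
  sr <- (pk[1] - 1) + dr; sc <- (pk[2] - 1) + dc
  if (sr > nr / 2) sr <- sr - nr
  if (sc > nc / 2) sc <- sc - nc
  c(sr, sc)
}

# translate a frame by (row, col) shift using bilinear interpolation;
# regions moved in from outside the frame are filled with the frame median.
translate_frame <- function(frame, shift, fill = stats::median(frame)) {
  H <- nrow(frame); W <- ncol(frame)
  rows <- matrix(seq_len(H), H, W) + shift[1]
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) + shift[2]
  inside <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  out <- matrix(fill, H, W)
  if (any(inside)) {
    out[inside] <- pracma::interp2(x = seq_len(W), y = seq_len(H), Z = frame,
                                   xp = cols[inside], yp = rows[inside],
                                   method = "linear")
  }
  out
}

#' Drift correction by phase correlation
#'
#' Registers every frame to frame 1 by phase correlation with parabolic
#' sub-pixel peak refinement, then resamples each frame by the negated shift
#' (bilinear interpolation; uncovered borders filled with the frame median).
#'
#' @param movie a [movie_stack] with at least 2 frames.
#' @return A list: `movie` (the registered [movie_stack]) and `shifts`
#'   (`T x 2` matrix of the detected (row, col) drift of each frame relative
#'   to frame 1; row 1 is `c(0, 0)`). For degenerate all-constant frames a
#'   zero shift is used and a warning is issued.
#' @export
drift_correct <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  Tn <- n_frames(movie)
  if (Tn < 2) stop("drift_correct: need at least 2 frames")
  ref <- movie$data[, , 1]
  d <- dim(movie$data)
  out <- array(0, d)
  out[, , 1] <- ref
  shifts <- matrix(0, Tn, 2, dimnames = list(NULL, c("row", "col")))
  degenerate <- FALSE
  for (k in 2:Tn) {
    frame <- movie$data[, , k]
    if (stats::sd(frame) < .Machine$double.eps || stats::sd(ref) < .Machine$double.eps) {
      degenerate <- TRUE
      out[, , k] <- frame
      next
    }
    s <- phase_corr_shift(ref, frame)
    shifts[k, ] <- s
    out[, , k] <- translate_frame(frame, s)
  }
  if (degenerate) warning("drift_correct: constant frame(s) encountered; zero shift applied")
  out[out < 0] <- 0
  list(movie = movie_stack(out, movie$pixel_size, movie$frame_interval),
       shifts = shifts)
}

#' Define a ring ROI from two clicked points
#'
#' The semi-manual workflow defines a ring by two coordinates from which the
#' matching circle is computed. In the default `"diameter"` mode the two
#' points are treated as diametrically opposite: the center is their
#' midpoint and the radius half their distance. In `"center_edge"` mode the
#' first point is the center and the second a point on the circle.
#'
#' @param p1,p2 `(row, col)` positions (sub-pixel allowed).
#' @param image_size optional `(H, W)` used to check that the circle plus a
#'   1-px margin fits inside the image.
#' @param mode `"diameter"` (default) or `"center_edge"`.
#' @param n_arc_samples optional override of the angular sampling density
#'   (default `round(2*pi*radius_px)`).
#' @return A [ring_roi].
#' @export
circle_from_two_points <- function(p1, p2, image_size = NULL,
                                   mode = c("diameter", "center_edge"),
                                   n_arc_samples = NULL) {
  mode <- match.arg(mode)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (isTRUE(all.equal(p1, p2)))
    stop("circle_from_two_points: the two points must differ")
  if (mode == "diameter") {
    center <- (p1 + p2) / 2
    radius <- sqrt(sum((p1 - p2)^2)) / 2
  } else {
    center <- p1
    radius <- sqrt(sum((p1 - p2)^2))
  }
  ring_roi(center, radius, n_arc_samples = n_arc_samples,
           image_size = image_size)
}

#' Sample intensity along a concentric circular trajectory
#'
#' Bilinearly interpolates one frame at `n_arc_samples` equally spaced
#' points on the circle of radius `radius_px + radius_offset` around the ROI
#' center: point j sits at `center + (r + offset) * (sin(theta_j),
#' cos(theta_j))`, `theta_j = 2*pi*(j-1)/n`.
#'
#' @param frame `H x W` numeric matrix.
#' @param roi a [ring_roi].
#' @param radius_offset radial offset in pixels; the three-trajectory
#'   kymograph uses -1, 0 and +1.
#' @return Numeric vector of length `roi$n_arc_samples`.
#' @export
sample_trajectory <- function(frame, roi, radius_offset = 0) {
  stopifnot(inherits(roi, "ring_roi"))
  n <- roi$n_arc_samples
  off <- if (is.null(roi$theta_offset)) 0 else roi$theta_offset
  theta <- off + 2 * pi * (seq_len(n) - 1) / n
  r <- roi$radius_px + radius_offset
  if (r <= 0) stop("sample_trajectory: offset radius must be positive")
  rows <- roi$center[1] + r * sin(theta)
  cols <- roi$center[2] + r * cos(theta)
  bilinear_sample(frame, rows, cols)
}

#' Build a ring kymograph from a movie
#'
#' For every frame, samples the three concentric trajectories at radii
#' `r - 1`, `r` and `r + 1` pixels and averages them; row t of the result is
#' that average for frame t. Calibration follows the ROI geometry:
#' `arc_step = 2*pi*radius_px*pixel_size / n_arc_samples`.
#'
#' @param movie a [movie_stack].
#' @param roi a [ring_roi]; the outer trajectory must stay inside the image.
#' @return A [kymograph] with `T` rows and `n_arc_samples` cyclic columns.
#' @export
build_kymograph <- function(movie, roi) {
  stopifnot(inherits(movie, "movie_stack"), inherits(roi, "ring_roi"))
  Tn <- n_frames(movie)
  n <- roi$n_arc_samples
  K <- matrix(0, Tn, n)
  for (t in seq_len(Tn)) {
    frame <- movie$data[, , t]
    K[t, ] <- (sample_trajectory(frame, roi, -1) +
               sample_trajectory(frame, roi, 0) +
               sample_trajectory(frame, roi, +1)) / 3
  }
  kymograph(K,
            arc_step = 2 * pi * roi$radius_px * movie$pixel_size / n,
            frame_interval = movie$frame_interval,
            radius_px = roi$radius_px, pixel_size = movie$pixel_size)
}
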