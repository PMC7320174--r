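#' Movie stack container
#'
#' A calibrated time-lapse fluorescence movie. Frames are stored as an
#' `H x W x T` numeric array (row, column, time; 1-based, matching R and
#' EBImage conventions). Sub-pixel positions throughout the package are
#' `(row, col)` doubles, and the polar angle theta is measured from the
#' +col axis, increasing toward +row.
#'
#' @param data numeric array `H x W x T` (a single `H x W` matrix is accepted
#'   and promoted to one frame). All values must be finite and non-negative.
#' @param pixel_size pixel size in nm/px.
#' @param frame_interval time between frames in seconds.
#' @return An object of class `movie_stack`: a list with elements `data`,
#'   `pixel_size` and `frame_interval`.
#' @export
movie_stack <- function(data, pixel_size, frame_interval) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("movie_stack: 'data' must be an H x W x T array")
  if (!all(is.finite(data)) || any(data < 0))
    stop("movie_stack: intensities must be finite and >= 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("movie_stack: 'pixel_size' must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("movie_stack: 'frame_interval' must be > 0")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d x %d px, %d frames, %.3g nm/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

#' Ring region of interest
#'
#' Sub-pixel circle defining a ring's sampling geometry. The default angular
#' sampling density is about one pixel of arc length
#' (`n_arc_samples = round(2*pi*radius_px)`), so kymograph columns are
#' commensurate with pixel units.
#'
#' @param center numeric `(row, col)` sub-pixel circle center.
#' @param radius_px circle radius in pixels; must be at least 2 so that the
#'   inner `r - 1` trajectory exists.
#' @param n_arc_samples number of samples along the circumference; defaults
#'   to `round(2*pi*radius_px)` and must be at least 8.
#' @param image_size optional `(H, W)`; when given, the circle plus a 1-px
#'   margin must lie fully inside the image.
#' @param theta_offset angular origin of the arc sampling, radians
#'   (default 0; rotating it by k sample steps cyclically permutes
#'   kymograph columns by k).
#' @return An object of class `ring_roi`.
#' @export
ring_roi <- function(center, radius_px, n_arc_samples = NULL,
                     image_size = NULL, theta_offset = 0) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop("ring_roi: 'center' must be a finite (row, col) pair")
  if (!is.numeric(radius_px) || radius_px < 2)
    stop("ring_roi: 'radius_px' must be >= 2 (inner r - 1 trajectory)")
  if (is.null(n_arc_samples)) n_arc_samples <- max(8L, round(2 * pi * radius_px))
  n_arc_samples <- as.integer(n_arc_samples)
  if (n_arc_samples < 8L) stop("ring_roi: 'n_arc_samples' must be >= 8")
  if (!is.null(image_size)) {
    margin <- radius_px + 1 + 1  # outer trajectory + 1-px margin
    if (center[1] - margin < 1 || center[1] + margin > image_size[1] ||
        center[2] - margin < 1 || center[2] + margin > image_size[2])
      stop(sprintf(
        "ring_roi: circle plus 1-px margin exceeds image bounds (need %.2f px around center)",
        margin))
  }
  structure(list(center = as.numeric(center), radius_px = radius_px,
                 n_arc_samples = n_arc_samples,
                 theta_offset = theta_offset),
            class = "ring_roi")
}

#' @export
print.ring_roi <- function(x, ...) {
  cat(sprintf("<ring_roi> center (%.2f, %.2f), radius %.2f px, %d arc samples\n",
              x$center[1], x$center[2], x$radius_px, x$n_arc_samples))
  invisible(x)
}

#' Kymograph container
#'
#' Time-by-arc-position intensity matrix sampled along a circular trajectory.
#' Rows are time points, columns are positions along the circumference;
#' columns are cyclic (the last column wraps to the first). Calibration:
#' `arc_step = 2*pi*radius_px*pixel_size / n_arc_samples` nm per column,
#' `frame_interval` seconds per row.
#'
#' @param data numeric `T x N` matrix (row = time, col = arc position).
#' @param arc_step nm per column.
#' @param frame_interval seconds per row.
#' @param radius_px,pixel_size geometry used to build the kymograph
#'   (optional, retained for provenance).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(data, arc_step, frame_interval,
                      radius_px = NA_real_, pixel_size = NA_real_) {
  if (!is.matrix(data) || !all(is.finite(data)))
    stop("kymograph: 'data' must be a finite numeric matrix")
  if (!is.numeric(arc_step) || arc_step <= 0)
    stop("kymograph: 'arc_step' must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("kymograph: 'frame_interval' must be > 0")
  structure(list(data = data, arc_step = arc_step,
                 frame_interval = frame_interval,
                 radius_px = radius_px, pixel_size = pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d time rows x %d arc columns, %.3g nm/col, %.3g s/row\n",
              nrow(x$data), ncol(x$data), x$arc_step, x$frame_interval))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$data)

#' Display a kymograph as an image
#'
#' @param x a [kymograph].
#' @param ... passed to [graphics::image].
#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = seq_len(ncol(x$data)) * x$arc_step,
                  y = (seq_len(nrow(x$data)) - 1) * x$frame_interval,
                  z = t(x$data)[, rev(seq_len(nrow(x$data))), drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "arc position (nm)", ylab = "time (s)", ...)
  invisible(x)
}

# bilinear sampling of a matrix at sub-pixel (row, col) positions;
# exact on affine images, which several oracle tests exploit.
bilinear_sample <- function(frame, rows, cols) {
  if (any(rows < 1 | rows > nrow(frame) | cols < 1 | cols > ncol(frame)))
    stop("bilinear_sample: sample point outside image")
  pracma::interp2(x = seq_len(ncol(frame)), y = seq_len(nrow(frame)),
                  Z = frame, xp = cols, yp = rows, method = "linear")
}
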