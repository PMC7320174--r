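new_slope_estimate <- function(per_window, method, kymo, params = list()) {
  acc <- per_window$accepted
  mean_slope <- if (any(acc)) mean(per_window$slope[acc]) else NA_real_
  structure(list(
    per_window = per_window,
    mean_slope = mean_slope,
    n_accepted = sum(acc),
    method = method,
    arc_step = kymo$arc_step,
    frame_interval = kymo$frame_interval,
    params = params
  ), class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> method: %s, windows: %d (%d accepted)\n",
              x$method, nrow(x$per_window), x$n_accepted))
  if (is.na(x$mean_slope)) {
    cat("  no reliable slope (static phenotype)\n")
  } else {
    cat(sprintf("  mean slope: %.4f columns/row", x$mean_slope))
    v <- x$mean_slope * x$arc_step / x$frame_interval
    cat(sprintf("  (velocity %.2f nm/s)\n", v))
  }
  invisible(x)
}

#' @export
summary.slope_estimate <- function(object, ...) {
  cat(sprintf("Stripe-slope estimate (%s)\n", object$method))
  print(object$per_window, row.names = FALSE, digits = 4)
  if (is.na(object$mean_slope)) {
    cat("No window passed the quality gates: no reliable slope.\n")
  } else {
    acc <- object$per_window$slope[object$per_window$accepted]
    cat(sprintf("Accepted windows: %d; mean slope %.4f +/- %.4f columns/row\n",
                length(acc), mean(acc),
                if (length(acc) > 1) stats::sd(acc) else 0))
  }
  invisible(object)
}

#' @export
coef.slope_estimate <- function(object, ...) {
  v <- if (is.na(object$mean_slope)) NA_real_ else
    object$mean_slope * object$arc_step / object$frame_interval
  c(slope = object$mean_slope, velocity_nm_s = v)
}

#' Plot per-window slopes of an estimate
#'
#' @param x a `slope_estimate`.
#' @param ... passed to [graphics::plot].
#' @export
plot.slope_estimate <- function(x, ...) {
  pw <- x$per_window
  graphics::plot(pw$window_start, pw$slope,
                 pch = ifelse(pw$accepted, 19, 1),
                 xlab = "window start (row)", ylab = "slope (columns/row)",
                 ...)
  if (!is.na(x$mean_slope)) graphics::abline(h = x$mean_slope, lty = 2)
  invisible(x)
}

#' Manual stripe-slope measurement
#'
#' Computes the slope of a user-identified kymograph stripe through two
#' points, in columns per row: `(col_b - col_a) / (row_b - row_a)`.
#'
#' @param kymo a [kymograph].
#' @param p_a,p_b `(row, col)` points on the stripe; rows must differ.
#' @return A `slope_estimate` with a single accepted window.
#' @export
estimate_slope_manual <- function(kymo, p_a, p_b) {
  stopifnot(inherits(kymo, "kymograph"))
  d <- dim(kymo$data)
  for (p in list(p_a, p_b))
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2])
      stop("estimate_slope_manual: point outside the kymograph")
  if (p_a[1] == p_b[1])
    stop("estimate_slope_manual: points on the same time row have no defined stripe slope")
  s <- (p_b[2] - p_a[2]) / (p_b[1] - p_a[1])
  per_window <- data.frame(window_start = min(p_a[1], p_b[1]), slope = s,
                           f_star = NA_real_, power_fraction = NA_real_,
                           phase_r2 = NA_real_, accepted = TRUE,
                           reject_reason = "")
  new_slope_estimate(per_window, "manual", kymo)
}

#' Kymograph preprocessing: Savitzky-Golay smoothing and CLAHE
#'
#' Smooths each kymograph column along the time axis with a 2nd-order
#' Savitzky-Golay filter (which preserves signal content up to quadratic in
#' time), then enhances local contrast with contrast-limited adaptive
#' histogram equalization. The cyclic column structure is untouched and the
#' output is rescaled to `[0, 1]`. A constant kymograph is returned
#' unchanged.
#'
#' @param kymo a [kymograph].
#' @param sg_window odd Savitzky-Golay window length in rows (>= 5, smaller
#'   than both kymograph dimensions); default 7. The window must stay short
#'   relative to the stripe period in time: a quadratic filter's stopband
#'   begins near 1.8 / sg_window cycles/row, and temporal signal
#'   frequencies up to speed * frame_interval * pattern_periods /
#'   circumference must pass.
#' @param sg_order polynomial order of the filter (default 2).
#' @param clahe_clip CLAHE clip limit as a fraction (default 0.01).
#' @param clahe_tile CLAHE tile size in pixels (default 16).
#' @param bleach_correct divide each time row by its mean intensity first,
#'   the exact correction for global multiplicative photobleaching (default
#'   `TRUE`). Without it the bleaching trend can dominate the low-frequency
#'   end of the temporal spectrum.
#' @return A preprocessed [kymograph] with values in `[0, 1]`.
#' @export
preprocess_kymograph <- function(kymo, sg_window = 7, sg_order = 2,
                                 clahe_clip = 0.01, clahe_tile = 16,
                                 bleach_correct = TRUE) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$data
  if (bleach_correct) {
    rm <- rowMeans(K)
    if (all(rm > 0)) K <- K / rm
  }
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2 == 0 || sg_window < 5 || sg_window >= min(dim(K)))
    stop("preprocess_kymograph: sg_window must be odd, >= 5 and < min(dim)")
  rng <- range(K)
  if (diff(rng) < .Machine$double.eps) return(kymo)  # constant: nothing to do
  S <- sg_smooth_columns(K, sg_order, sg_window)
  rng <- range(S)
  if (diff(rng) < .Machine$double.eps) {
    S[] <- 0.5
  } else {
    S <- (S - rng[1]) / diff(rng)
    # clip limit expressed as a fraction of the per-tile histogram; EBImage's
    # 'limit' is a multiple of the uniform bin height
    # tile only minimally along the time axis: equalizing short time tiles
    # independently fabricates temporal structure in a static ring, which
    # the phase analysis would then pick up. Contrast inhomogeneity lives
    # mainly along the arc (uneven labeling); bleaching is handled above.
    ntx <- 2L
    nty <- max(2L, as.integer(round(ncol(S) / clahe_tile)))
    # pad to dimensions divisible by the tile counts (edge-replicate in
    # time, wrap in the cyclic arc direction), then crop back
    nr0 <- nrow(S); nc0 <- ncol(S)
    nr <- ceiling(nr0 / ntx) * ntx
    nc <- ceiling(nc0 / nty) * nty
    Sp <- matrix(0, nr, nc)
    Sp[1:nr0, 1:nc0] <- S
    if (nr > nr0) Sp[(nr0 + 1):nr, 1:nc0] <- S[rep(nr0, nr - nr0), , drop = FALSE]
    if (nc > nc0) Sp[, (nc0 + 1):nc] <- Sp[, 1:(nc - nc0), drop = FALSE]
    Sp <- EBImage::clahe(Sp, nx = ntx, ny = nty, bins = 256,
                         limit = max(1, clahe_clip * 256))
    S <- Sp[1:nr0, 1:nc0, drop = FALSE]
    S <- S - min(S)
    if (max(S) > 0) S <- S / max(S)
  }
  kymograph(S, kymo$arc_step, kymo$frame_interval,
            radius_px = kymo$radius_px, pixel_size = kymo$pixel_size)
}

# columnwise Savitzky-Golay smoothing along the time axis
sg_smooth_columns <- function(K, order, window) {
  apply(K, 2, function(col) signal::sgolayfilt(col, p = order, n = window))
}

# divisor of n closest to target (EBImage's CLAHE needs tile counts that
# divide the image dimensions exactly)
nearest_divisor <- function(n, target) {
  divs <- which(n %% seq_len(n) == 0)
  divs <- divs[divs <= max(1, n %/% 2)]
  if (!length(divs)) return(1L)
  divs[which.min(abs(divs - target))]
}

# DTFT of the demeaned window columns at frequency f (cycles/row):
# returns one complex coefficient per column.
window_dtft <- function(X, f) {
  W <- nrow(X)
  e <- exp(-2i * pi * f * (0:(W - 1)))
  as.vector(crossprod(X, e))
}

#' Automatic stripe-slope estimation by windowed Fourier phase analysis
#'
#' Sweeps the kymograph with half-overlapping vertical windows of
#' `window_rows` time rows. In each window it (1) removes each column's
#' mean and takes the discrete Fourier transform along time; (2) finds the
#' dominant temporal frequency f* (cycles/row) as the argmax of the
#' column-summed power spectrum over positive frequencies, refined off the
#' DFT grid by parabolic interpolation of the log-power peak (lowest
#' frequency wins ties); (3) extracts the phase phi(j) of each column's
#' coefficient at f*; (4) unwraps phi along the cyclic column axis and fits
#' d(phi)/dj by least squares; (5) reports the window slope
#' `s = -2*pi*f* / (d phi / d j)` in columns per row, whose sign encodes the
#' rotation direction.
#'
#' A window is rejected when the power fraction at f* is below
#' `min_power_fraction`, the phase-line fit has R^2 below `min_phase_r2`,
#' the total phase change across the N cyclic columns is not within
#' `wrap_tol` of a non-zero multiple of 2*pi (a periodic ring pattern must
#' close on itself an integer number of times), the winding number of the
#' fitted phase line disagrees with the dominant spatial frequency of the
#' window (for a rotating periodic pattern both count the same number of
#' pattern repeats around the ring, so a mismatch marks noise-driven
#' phases), or the dominant frequency is the DC bin. If no window is
#' accepted the estimate is flagged as having no reliable slope, the
#' signature of a static ring.
#'
#' @param kymo a [kymograph] with at least `window_rows` rows.
#' @param window_rows vertical window size in time rows (default 50).
#' @param stride window stride in rows; default half-overlap
#'   (`window_rows / 2`).
#' @param min_power_fraction minimum fraction of total positive-frequency
#'   power carried by f* (default 0.2).
#' @param min_phase_r2 minimum R^2 of the phase-versus-column line fit
#'   (default 0.8).
#' @param wrap_tol tolerance (radians) on the wrap-around phase residual
#'   (default `pi / 2`).
#' @param refine_freq refine f* off the DFT grid by parabolic interpolation
#'   of the log-power peak (default `TRUE`).
#' @return A `slope_estimate`; `mean_slope` is the mean over accepted
#'   windows, or `NA` (no reliable slope) when none is accepted.
#' @export
estimate_slope_auto <- function(kymo, window_rows = 50, stride = NULL,
                                min_power_fraction = 0.2, min_phase_r2 = 0.8,
                                wrap_tol = pi / 2, refine_freq = TRUE) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$data
  Tn <- nrow(K); N <- ncol(K)
  window_rows <- as.integer(window_rows)
  if (Tn < window_rows)
    stop(sprintf("estimate_slope_auto: kymograph has %d rows, needs >= %d", Tn, window_rows))
  if (is.null(stride)) stride <- max(1L, window_rows %/% 2L)
  starts <- seq(1L, Tn - window_rows + 1L, by = as.integer(stride))

  res <- lapply(starts, function(s0) {
    Xraw <- K[s0:(s0 + window_rows - 1L), , drop = FALSE]
    X <- sweep(Xraw, 2, colMeans(Xraw))
    W <- window_rows
    Fc <- stats::mvfft(X)
    kmax <- (W - 1L) %/% 2L  # positive frequencies below Nyquist
    if (kmax < 1L)
      return(list(slope = NA_real_, f = NA_real_, pf = NA_real_, r2 = NA_real_,
                  reason = "window too short"))
    pw <- rowSums(Mod(Fc[2:(kmax + 1L), , drop = FALSE])^2)
    total <- sum(pw)
    if (total < .Machine$double.eps)
      return(list(slope = NA_real_, f = NA_real_, pf = 0, r2 = NA_real_,
                  reason = "no temporal signal"))
    kstar <- which.max(pw)  # which.max takes the lowest index on ties
    pf <- pw[kstar] / total
    fstar <- kstar / W
    if (refine_freq && kstar > 1L && kstar < kmax) {
      lp <- log(pw[(kstar - 1L):(kstar + 1L)] + .Machine$double.xmin)
      den <- lp[1] - 2 * lp[2] + lp[3]
      if (abs(den) > .Machine$double.eps) {
        delta <- max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))
        fstar <- (kstar + delta) / W
      }
    }
    coefs <- window_dtft(X, fstar)
    phi <- signal::unwrap(Arg(coefs))
    j <- seq_len(N) - 1
    fit <- stats::lm.fit(cbind(1, j), phi)
    dphi <- fit$coefficients[2]
    ss_tot <- sum((phi - mean(phi))^2)
    r2 <- if (ss_tot < 1e-12) 0 else 1 - sum(fit$residuals^2) / ss_tot
    if (pf < min_power_fraction)
      return(list(slope = NA_real_, f = fstar, pf = pf, r2 = r2,
                  reason = "low power fraction"))
    if (r2 < min_phase_r2)
      return(list(slope = NA_real_, f = fstar, pf = pf, r2 = r2,
                  reason = "poor phase fit"))
    total_phase <- dphi * N
    m_est <- round(abs(total_phase) / (2 * pi))
    wrap_resid <- abs(abs(total_phase) - 2 * pi * m_est)
    if (m_est < 1)
      return(list(slope = NA_real_, f = fstar, pf = pf, r2 = r2,
                  reason = "zero spatial frequency"))
    if (wrap_resid > wrap_tol)
      return(list(slope = NA_real_, f = fstar, pf = pf, r2 = r2,
                  reason = "wrap-around inconsistency"))
    # spatial consistency: the phase line's winding number must match the
    # pattern's dominant spatial frequency (both count pattern repeats
    # around the ring)
    sp <- rowSums(Mod(stats::mvfft(t(Xraw - rowMeans(Xraw))))^2)
    qmax <- (N - 1L) %/% 2L
    m_spatial <- which.max(sp[2:(qmax + 1L)])
    if (m_est != m_spatial)
      return(list(slope = NA_real_, f = fstar, pf = pf, r2 = r2,
                  reason = "spatial frequency mismatch"))
    list(slope = -2 * pi * fstar / dphi, f = fstar, pf = pf, r2 = r2,
         reason = "")
  })

  per_window <- data.frame(
    window_start = starts,
    slope = vapply(res, function(r) unname(r$slope), 0),
    f_star = vapply(res, function(r) unname(r$f), 0),
    power_fraction = vapply(res, function(r) unname(r$pf), 0),
    phase_r2 = vapply(res, function(r) unname(r$r2), 0),
    accepted = vapply(res, function(r) r$reason == "", TRUE),
    reject_reason = vapply(res, function(r) r$reason, "")
  )
  new_slope_estimate(per_window, "auto", kymo,
                     params = list(window_rows = window_rows, stride = stride,
                                   min_power_fraction = min_power_fraction,
                                   min_phase_r2 = min_phase_r2,
                                   wrap_tol = wrap_tol,
                                   refine_freq = refine_freq))
}

#' Cross-validate manual against automatic slope estimates
#'
#' Paired two-sided t-test on the per-ring differences (auto - manual)
#' between the two measurement routes.
#'
#' @param manual,auto paired lists of `slope_estimate` objects (or numeric
#'   vectors of slopes) of equal length >= 3.
#' @return A list of class `slope_crossval`: `mean_difference`, `ci95`,
#'   `t`, `df`, `p`, `n`.
#' @export
cross_validate <- function(manual, auto) {
  get_slopes <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(e) {
      if (inherits(e, "slope_estimate")) e$mean_slope else as.numeric(e)
    }, 0)
  }
  ms <- get_slopes(manual); as_ <- get_slopes(auto)
  if (length(ms) != length(as_))
    stop("cross_validate: manual and auto lists must have equal length")
  if (length(ms) < 3) stop("cross_validate: need at least 3 pairs")
  d <- as_ - ms
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps * max(1, abs(mean(d)))) {
    res <- list(mean_difference = mean(d), ci95 = c(mean(d), mean(d)),
                t = if (abs(mean(d)) < .Machine$double.eps) 0 else Inf,
                df = n - 1,
                p = if (abs(mean(d)) < .Machine$double.eps) 1 else 0,
                n = n)
  } else {
    tt <- stats::t.test(d)
    res <- list(mean_difference = unname(tt$estimate),
                ci95 = unname(tt$conf.int), t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, n = n)
  }
  class(res) <- "slope_crossval"
  res
}

#' @export
print.slope_crossval <- function(x, ...) {
  cat(sprintf(
    "<slope_crossval> n = %d pairs: auto - manual = %.4f [%.4f, %.4f], t = %.3g (df %.3g), p = %.3g\n",
    x$n, x$mean_difference, x$ci95[1], x$ci95[2], x$t, x$df, x$p))
  invisible(x)
}
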