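#' Fit a phosphate standard curve
#'
#' Ordinary least squares of blank-subtracted absorbance on phosphate
#' concentration for a serial-dilution standard series (classically a 1:2
#' dilution from a 40 uM Pi top standard).
#'
#' @param standards data.frame with columns `conc_uM` and `absorbance`
#'   (>= 4 points spanning at least two dilution steps).
#' @param blank blank absorbance (AU) subtracted from every standard.
#' @return A list of class `standard_curve`: `slope` (AU/uM), `intercept`
#'   (AU, after blank subtraction), `r2`, `concentrations`.
#' @export
fit_standard_curve <- function(standards, blank = 0) {
  conc <- standards$conc_uM
  if (length(conc) < 4) stop("fit_standard_curve: need >= 4 standards")
  if (length(unique(conc)) < 3)
    stop("fit_standard_curve: concentrations must span >= 2 dilution steps")
  a <- standards$absorbance - blank
  fit <- stats::lm(a ~ conc)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = suppressWarnings(summary(fit)$r.squared),
    concentrations = conc
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %.4g AU/uM, intercept %.4g AU, r2 = %.5f (%d standards)\n",
              x$slope, x$intercept, x$r2, length(x$concentrations)))
  invisible(x)
}

#' GTPase activity from a stopped-timepoint phosphate series
#'
#' Converts each absorbance to a phosphate concentration through the
#' standard curve, `[Pi](t) = (A(t) - blank - intercept) / slope`, fits the
#' production rate in the stopped well by OLS of `[Pi]` on time, and scales
#' it to the reaction: `rate_reaction = rate_well * dilution_factor`,
#' `turnover = rate_reaction * 60 / [FtsZ]` (mol Pi per mol FtsZ per
#' minute). A negative fitted rate is returned as-is with a warning flag,
#' not clamped.
#'
#' @param timepoints strictly increasing times, s (>= 3 points).
#' @param absorbances matched absorbances, AU.
#' @param curve a `standard_curve` with positive slope.
#' @param blank sample-series blank absorbance, AU.
#' @param dilution_factor stopped-well to reaction dilution; default 50/13
#'   (13 uL reaction into 37 uL stop solution).
#' @param ftsz_conc FtsZ concentration in the reaction, uM (default 5).
#' @param reference optional reference `rate_reaction` (uM/s) for
#'   normalization.
#' @return A list of class `activity_result`: `rate_well`, `rate_reaction`
#'   (uM Pi/s), `turnover` (min^-1), `normalized` (fraction of reference,
#'   or `NA`), `pi_uM` (the converted series), `negative_rate_warning`.
#' @export
activity_from_timeseries <- function(timepoints, absorbances, curve,
                                     blank = 0, dilution_factor = 50 / 13,
                                     ftsz_conc = 5, reference = NULL) {
  if (length(timepoints) < 3 || any(diff(timepoints) <= 0))
    stop("activity_from_timeseries: timepoints must be strictly increasing, >= 3")
  if (length(absorbances) != length(timepoints))
    stop("activity_from_timeseries: series length mismatch")
  if (!inherits(curve, "standard_curve") || curve$slope <= 0)
    stop("activity_from_timeseries: need a standard curve with positive slope")
  pi_uM <- (absorbances - blank - curve$intercept) / curve$slope
  fit <- stats::lm(pi_uM ~ timepoints)
  rate_well <- unname(stats::coef(fit)[2])
  neg <- rate_well < 0
  if (neg) warning("activity_from_timeseries: negative fitted rate (noise?)")
  rate_reaction <- rate_well * dilution_factor
  structure(list(
    rate_well = rate_well,
    rate_reaction = rate_reaction,
    turnover = rate_reaction * 60 / ftsz_conc,
    normalized = if (is.null(reference)) NA_real_ else rate_reaction / reference,
    pi_uM = pi_uM,
    negative_rate_warning = neg
  ), class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("<activity_result> rate (well) %.4g uM/s, (reaction) %.4g uM/s, turnover %.4g /min",
              x$rate_well, x$rate_reaction, x$turnover))
  if (!is.na(x$normalized)) cat(sprintf(", normalized %.3g", x$normalized))
  cat("\n")
  invisible(x)
}
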