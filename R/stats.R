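#' Group summary with notched-boxplot statistics
#'
#' Five-number boxplot summary plus mean, sd and the notch interval
#' `median +/- 1.58 * IQR / sqrt(n)` (an approximate 95% confidence
#' interval for comparing medians). Quartiles use the linear-interpolation
#' convention (R's default, type 7), matching standard plotting frameworks.
#'
#' @param values numeric vector, n >= 1.
#' @param label group label.
#' @param quartile_type quantile algorithm type as in [stats::quantile]
#'   (default 7, linear interpolation).
#' @return A one-row data.frame: label, mean, sd, n, median, q1, q3, iqr,
#'   notch_low, notch_high, quartile_type.
#' @export
summarize_group <- function(values, label = "group", quartile_type = 7) {
  if (!length(values)) stop("summarize_group: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  iqr <- q[3] - q[1]
  n <- length(values)
  half <- 1.58 * iqr / sqrt(n)
  data.frame(label = label, mean = mean(values),
             sd = if (n > 1) stats::sd(values) else 0, n = n,
             median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
             notch_low = q[2] - half, notch_high = q[2] + half,
             quartile_type = quartile_type, stringsAsFactors = FALSE)
}

#' Two-sided t-test from printed summary statistics
#'
#' Computes the two-sample t-test directly from group means, standard
#' deviations and sizes, as needed when only published summaries are
#' available. The default is the Welch (unequal-variance) form with
#' Welch-Satterthwaite degrees of freedom; `pooled = TRUE` gives the
#' classical equal-variance Student form.
#'
#' @param mean1,sd1,n1 first group's mean, sd and size (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 second group's.
#' @param pooled use the pooled-variance Student t instead of Welch?
#' @return A list of class `summary_t_test`: `t`, `df`, `p` (two-sided),
#'   `mean_difference`, `ci95`, `method`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("welch_t_from_summary: need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("welch_t_from_summary: sd must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) stop("welch_t_from_summary: degenerate (both sd 0, equal means)")
    se <- 0
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  diff <- mean1 - mean2
  t <- if (se == 0) sign(diff) * Inf else diff / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(t = t, df = df, p = p, mean_difference = diff, ci95 = ci,
                 method = if (pooled) "pooled" else "welch"),
            class = "summary_t_test")
}

#' Two-sided t-test from raw samples
#'
#' Identical to [welch_t_from_summary] applied to the samples' means, sds
#' and sizes.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance form?
#' @return A `summary_t_test` (see [welch_t_from_summary]).
#' @export
welch_t_from_samples <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_from_samples: need n >= 2 per group")
  welch_t_from_summary(mean(x), stats::sd(x), length(x),
                       mean(y), stats::sd(y), length(y), pooled = pooled)
}

#' @export
print.summary_t_test <- function(x, ...) {
  cat(sprintf(
    "<summary_t_test> %s: t = %.4g, df = %.4g, two-sided p = %.3g\n  mean difference %.4g [%.4g, %.4g]\n",
    x$method, x$t, x$df, x$p, x$mean_difference, x$ci95[1], x$ci95[2]))
  invisible(x)
}
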