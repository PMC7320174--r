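#' Sauerbrey conversion of a frequency shift to areal mass coverage
#'
#' For a thin rigid film, adsorbed areal mass is proportional to the
#' (overtone-normalized) resonance frequency shift:
#' `coverage = -C * delta_f / n`, with C the crystal's mass sensitivity.
#' Adsorption lowers the frequency, so negative shifts map to positive
#' coverage.
#'
#' @param delta_f frequency shift in Hz. By default treated as the raw
#'   overtone shift and divided by the overtone order; set
#'   `normalized = TRUE` for data already stored as `delta_f / n`.
#' @param overtone odd overtone order (default 9).
#' @param mass_sensitivity Sauerbrey constant in ng/(cm^2 Hz); default 17.7
#'   for a standard 5 MHz AT-cut crystal.
#' @param normalized is `delta_f` already overtone-normalized?
#' @return Coverage in ng/cm^2 (vectorized over `delta_f`).
#' @export
sauerbrey_coverage <- function(delta_f, overtone = 9L, mass_sensitivity = 17.7,
                               normalized = FALSE) {
  overtone <- as.integer(overtone)
  if (overtone < 1L || overtone %% 2L == 0L)
    stop("sauerbrey_coverage: overtone must be an odd integer >= 1")
  if (mass_sensitivity <= 0)
    stop("sauerbrey_coverage: mass_sensitivity must be > 0")
  if (normalized) -mass_sensitivity * delta_f
  else -mass_sensitivity * delta_f / overtone
}

# last stable window of a trace: rolling sd below a multiple of the
# baseline noise estimate
last_stable_window <- function(delta_f, window = 30L, sd_factor = 3) {
  n <- length(delta_f)
  if (n < window) return(NULL)
  base_n <- min(n, max(window, 30L))
  noise <- stats::sd(diff(delta_f[seq_len(base_n)])) / sqrt(2)
  noise <- max(noise, 0.01)  # instrument resolution floor, Hz
  starts <- seq_len(n - window + 1L)
  sds <- vapply(starts, function(s) stats::sd(delta_f[s:(s + window - 1L)]), 0)
  ok <- which(sds < sd_factor * noise)
  if (!length(ok)) return(NULL)
  s <- ok[length(ok)]
  s:(s + window - 1L)
}

#' Verify supported-lipid-bilayer formation from a QCM-D trace
#'
#' A good bilayer leaves a characteristic overtone-normalized frequency
#' shift of about 25 Hz. The plateau is measured as the median of the last
#' stable window (rolling-sd stability criterion) of the bilayer segment,
#' and the check passes when it sits within `tol_hz` of
#' `-expected_shift_hz`.
#'
#' @param trace a `qcmd_trace` (or data.frame with `time`, `delta_f`). If
#'   the trace is not overtone-normalized, `delta_f` is divided by the
#'   overtone first.
#' @param expected_shift_hz expected bilayer shift magnitude (default 25).
#' @param tol_hz tolerance (default 1).
#' @param segment_end optional time (s) marking the end of the bilayer
#'   segment, e.g. the protein injection; defaults to the trace's
#'   `t_protein_injection` annotation, else the full trace.
#' @param stable_window stability window length in samples (default 30).
#' @return A list: `pass` (logical), `plateau_hz` (measured plateau, Hz,
#'   normalized), `expected_hz`, `tol_hz`. If no stable window exists,
#'   `pass = FALSE` with `plateau_hz = NA` and a `diagnostic` message.
#' @export
detect_slb_formation <- function(trace, expected_shift_hz = 25, tol_hz = 1,
                                 segment_end = NULL, stable_window = 30L) {
  f <- trace$delta_f
  ov <- attr(trace, "overtone"); if (is.null(ov)) ov <- 9L
  nrm <- attr(trace, "normalized"); if (is.null(nrm)) nrm <- TRUE
  if (!nrm) f <- f / ov
  if (is.null(segment_end)) {
    ann <- attr(trace, "annotations")
    if (!is.null(ann$t_protein_injection)) segment_end <- ann$t_protein_injection
  }
  if (!is.null(segment_end)) f <- f[trace$time < segment_end]
  idx <- last_stable_window(f, window = stable_window)
  if (is.null(idx))
    return(list(pass = FALSE, plateau_hz = NA_real_,
                expected_hz = -expected_shift_hz, tol_hz = tol_hz,
                diagnostic = "no stable plateau window found"))
  plateau <- stats::median(f[idx])
  list(pass = abs(plateau - (-expected_shift_hz)) <= tol_hz,
       plateau_hz = plateau, expected_hz = -expected_shift_hz, tol_hz = tol_hz)
}

#' Extract a binding-event frequency shift from a trace
#'
#' `shift = median(delta_f in plateau window) - median(delta_f in baseline
#' window)`, the robust step height of an adsorption event.
#'
#' @param trace a `qcmd_trace` or data.frame with `time`, `delta_f`.
#' @param baseline_window,plateau_window numeric `(start, end)` times in s;
#'   must not overlap and must each contain samples.
#' @return Shift in Hz (same normalization as the stored trace).
#' @export
extract_binding_shift <- function(trace, baseline_window, plateau_window) {
  in_win <- function(w) trace$time >= w[1] & trace$time <= w[2]
  if (max(baseline_window[1], plateau_window[1]) <
      min(baseline_window[2], plateau_window[2]))
    stop("extract_binding_shift: windows overlap")
  b <- trace$delta_f[in_win(baseline_window)]
  p <- trace$delta_f[in_win(plateau_window)]
  if (!length(b) || !length(p))
    stop("extract_binding_shift: empty window")
  stats::median(p) - stats::median(b)
}

#' Coverage fold changes across constructs
#'
#' Ratios of membrane coverage relative to a reference construct at one
#' concentration, reported raw and as a display string following the
#' conventional reporting of whole-number folds: ratios of 10 and above are
#' rounded to an integer, smaller ratios to one decimal, except that a
#' ratio within 0.25 of a whole number is displayed as that integer.
#'
#' @param table a coverage table: data.frame with columns `label`,
#'   `concentration_uM`, `coverage` (ng/cm^2), optionally `nucleotide` and
#'   `coverage_sem`.
#' @param reference_label construct used as the denominator.
#' @param at_concentration concentration (uM) at which to compare.
#' @return data.frame (label, coverage, fold, display) with one row per
#'   non-reference construct present at that concentration.
#' @export
fold_changes <- function(table, reference_label, at_concentration) {
  sub <- table[table$concentration_uM == at_concentration, , drop = FALSE]
  if (!(reference_label %in% sub$label))
    stop(sprintf("fold_changes: reference '%s' absent at %g uM",
                 reference_label, at_concentration))
  ref <- sub$coverage[sub$label == reference_label][1]
  if (ref == 0) stop("fold_changes: reference coverage is zero")
  out <- sub[sub$label != reference_label, c("label", "coverage"), drop = FALSE]
  out$fold <- out$coverage / ref
  out$display <- vapply(out$fold, format_fold, "")
  rownames(out) <- NULL
  out
}

format_fold <- function(x) {
  if (x >= 10) return(sprintf("%d-fold", round(x)))
  if (abs(x - round(x)) <= 0.25) return(sprintf("%d-fold", round(x)))
  sprintf("%.1f-fold", round(x, 1))
}
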