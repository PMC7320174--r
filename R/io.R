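#' Write a movie as a multi-page 16-bit TIFF with side-car metadata
#'
#' One TIFF page per frame; intensities are scaled into the 16-bit range
#' and the scale factor, pixel size and frame interval are stored in a
#' side-car JSON file (`<path>.json`) so the movie round-trips losslessly
#' up to 16-bit quantization.
#'
#' @param movie a [movie_stack].
#' @param path output TIFF path.
#' @return Invisibly, the side-car path.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  mx <- max(movie$data, 1e-12)
  scale <- mx  # stored so counts can be recovered on read
  pages <- lapply(seq_len(n_frames(movie)),
                  function(k) movie$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_nm = movie$pixel_size,
               frame_interval_s = movie$frame_interval,
               intensity_scale = scale,
               n_frames = n_frames(movie))
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a movie written by [write_movie_tiff]
#'
#' @param path TIFF path; the side-car `<path>.json` must exist.
#' @return A [movie_stack].
#' @export
read_movie_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("read_movie_tiff: missing side-car metadata ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$intensity_scale
  movie_stack(arr, meta$pixel_size_nm, meta$frame_interval_s)
}

#' Write / read ring ROIs as CSV
#'
#' One ring per row with the two defining click points:
#' `ring_id, p1_row, p1_col, p2_row, p2_col`.
#'
#' @param rois list of `(p1, p2)` point pairs (each a list with `p1`,
#'   `p2`), or a data.frame already in the file layout.
#' @param path CSV path.
#' @return `write_rois_csv`: invisibly the path; `read_rois_csv`: a
#'   data.frame in the file layout.
#' @export
write_rois_csv <- function(rois, path) {
  if (is.data.frame(rois)) {
    df <- rois
  } else {
    df <- do.call(rbind, lapply(seq_along(rois), function(i) {
      r <- rois[[i]]
      data.frame(ring_id = if (!is.null(r$ring_id)) r$ring_id else paste0("ring", i),
                 p1_row = r$p1[1], p1_col = r$p1[2],
                 p2_row = r$p2[1], p2_col = r$p2[2])
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) utils::read.csv(path)

#' Write a kymograph as CSV (and optionally TIFF)
#'
#' The CSV stores the intensity matrix with a two-line header comment
#' carrying the calibration (nm/column, s/row).
#'
#' @param kymo a [kymograph].
#' @param path output CSV path.
#' @param tiff_path optional TIFF path for the same matrix (scaled to
#'   16-bit).
#' @return Invisibly, `path`.
#' @export
write_kymograph_csv <- function(kymo, path, tiff_path = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  con <- file(path, "w")
  writeLines(c(sprintf("# arc_step_nm,%.10g", kymo$arc_step),
               sprintf("# frame_interval_s,%.10g", kymo$frame_interval)), con)
  utils::write.table(kymo$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  if (!is.null(tiff_path)) {
    mx <- max(kymo$data, 1e-12)
    tiff::writeTIFF(kymo$data / mx, tiff_path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a kymograph written by [write_kymograph_csv]
#'
#' @param path CSV path.
#' @return A [kymograph].
#' @export
read_kymograph_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  arc_step <- as.numeric(sub("^# arc_step_nm,", "", hdr[1]))
  fi <- as.numeric(sub("^# frame_interval_s,", "", hdr[2]))
  data <- as.matrix(utils::read.csv(path, header = FALSE, skip = 2))
  dimnames(data) <- NULL
  kymograph(data, arc_step, fi)
}

#' Read a QCM-D trace CSV
#'
#' Expects columns `time` (s) and `delta_f` (Hz); additional columns are
#' kept. The overtone order and normalization dialect are supplied by the
#' caller because exports differ in whether they store raw overtone shifts
#' or shifts already divided by the overtone.
#'
#' @param path CSV path.
#' @param overtone odd overtone order (default 9).
#' @param normalized does the file store `delta_f / n` (default `FALSE`,
#'   i.e. raw overtone shifts)?
#' @return A `qcmd_trace`.
#' @export
read_qcmd_csv <- function(path, overtone = 9L, normalized = FALSE) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "delta_f") %in% names(df)))
    stop("read_qcmd_csv: need columns 'time' and 'delta_f'")
  if (any(diff(df$time) <= 0)) stop("read_qcmd_csv: time must be strictly increasing")
  class(df) <- c("qcmd_trace", "data.frame")
  attr(df, "overtone") <- as.integer(overtone)
  attr(df, "normalized") <- normalized
  df
}

#' Write a QCM-D trace or a coverage table as CSV
#'
#' @param x a `qcmd_trace` or coverage data.frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_qcmd_csv <- function(x, path) {
  con <- file(path, "w")
  ov <- attr(x, "overtone")
  if (!is.null(ov))
    writeLines(sprintf("# overtone,%d,normalized,%s", ov,
                       isTRUE(attr(x, "normalized"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a GTPase plate CSV (long format)
#'
#' Long-format plate export with columns `series` (`"standard"` or
#' `"sample"`), `conc_or_time` (uM for standards, s for samples) and
#' `absorbance` (AU).
#'
#' @param path CSV path.
#' @return A list with `standards` (conc_uM, absorbance) and `samples`
#'   (time_s, absorbance).
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("series", "conc_or_time", "absorbance")
  if (!all(need %in% names(df)))
    stop("read_plate_csv: need columns series, conc_or_time, absorbance")
  std <- df[df$series == "standard", ]
  smp <- df[df$series == "sample", ]
  list(standards = data.frame(conc_uM = std$conc_or_time,
                              absorbance = std$absorbance),
       samples = data.frame(time_s = smp$conc_or_time,
                            absorbance = smp$absorbance))
}

#' Write a GTPase plate in the long CSV format of [read_plate_csv]
#'
#' @param plate a `gtpase_plate` from [simulate_gtpase_plate].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_plate_csv <- function(plate, path) {
  df <- rbind(
    data.frame(series = "standard", conc_or_time = plate$standards$conc_uM,
               absorbance = plate$standards$absorbance),
    data.frame(series = "sample", conc_or_time = plate$samples$time_s,
               absorbance = plate$samples$absorbance))
  con <- file(path, "w")
  writeLines("# conc_or_time: uM for standards, s for samples; absorbance: AU",
             con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}
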