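# Reading and writing video as frame stacks, and report serialization.

# standard luma weights; a monochrome camera never triggers this, and any
# fixed linear map preserves periodicity
.to_gray <- function(a, what) {
  if (is.matrix(a)) return(a)
  d <- dim(a)
  if (length(d) == 3L && d[3] >= 3L) {
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  }
  if (length(d) == 3L && d[3] == 1L) return(a[, , 1])
  stop_io(sprintf("cannot interpret %s as a grayscale or RGB image", what))
}

.read_frame_dir <- function(path, frame_rate, max_frames) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop_io(sprintf("no PNG/TIFF frames found in '%s'", path))
  }
  if (is.finite(max_frames)) files <- utils::head(files, max_frames)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- if (grepl("\\.png$", files[i], ignore.case = TRUE)) {
      png::readPNG(files[i])
    } else {
      tiff::readTIFF(files[i])
    }
    frames[[i]] <- .to_gray(img, files[i])
    if (i > 1L && !identical(dim(frames[[i]]), dim(frames[[1]]))) {
      stop_dimension(sprintf(
        "frame '%s' is %s but the first frame is %s",
        basename(files[i]), paste(dim(frames[[i]]), collapse = "x"),
        paste(dim(frames[[1]]), collapse = "x")))
    }
  }
  frame_stack(frames, frame_rate)
}

#' Read a video into a frame stack
#'
#' Accepts either a directory of numbered PNG/TIFF frames (read in
#' lexicographic file-name order) or an uncompressed grayscale AVI as written
#' by [write_video()]. Colour inputs are converted to grayscale with standard
#' luma weights (0.299, 0.587, 0.114); grayscale inputs pass through
#' unchanged.
#'
#' @param path Directory of frames, or an `.avi` file.
#' @param frame_rate Acquisition frame rate in Hz. Always caller-supplied;
#'   container metadata is ignored because high-speed clips are commonly
#'   re-wrapped at playback rates.
#' @param max_frames Keep at most this many frames from the start.
#' @return A [frame_stack()].
#' @export
read_video <- function(path, frame_rate, max_frames = Inf) {
  if (missing(frame_rate)) stop_parameter("'frame_rate' must be supplied")
  if (dir.exists(path)) {
    return(.read_frame_dir(path, frame_rate, max_frames))
  }
  if (!file.exists(path)) {
    stop_io(sprintf("input '%s' does not exist", path))
  }
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    return(read_avi(path, frame_rate, max_frames))
  }
  stop_io(sprintf(
    "unsupported input '%s': expected a frame directory or an .avi file", path))
}

#' Write a frame stack to disk
#'
#' Writes either a directory of numbered 8-bit PNG frames or an uncompressed
#' 8-bit grayscale AVI (chosen by the `.avi` suffix). Both paths are
#' lossless for stacks whose intensities are already 8-bit quantized in
#' `[0, 1]` (see [quantize_frames()]): `read_video(write_video(s))`
#' reproduces the pixel values exactly. Other intensities are clamped to
#' `[0, 1]` and rounded to 8 bits.
#'
#' @param stack A [frame_stack()].
#' @param path Output directory (PNG frames) or `.avi` file path.
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path) {
  if (!inherits(stack, "frame_stack")) stop_parameter("'stack' must be a frame_stack")
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    return(write_avi(stack, path))
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop_io(sprintf("cannot create directory '%s'", path))
  k <- n_frames(stack)
  for (i in seq_len(k)) {
    f <- file.path(path, sprintf("frame_%06d.png", i))
    png::writePNG(pmin(pmax(stack$frames[, , i], 0), 1), f)
  }
  invisible(path)
}

#' Tabular form of an analysis result
#'
#' Flattens a frequency estimate, multi-channel estimate or monitor report
#' into a data frame with the canonical report columns `window_start_s`,
#' `window_end_s`, `mean_freq_hz`, `cv_percent`, `peak_power`, `n_frames`
#' (one row per window or per channel).
#'
#' @param x A `frequency_estimate`, `multichannel_estimate` or
#'   `monitor_report`.
#' @return A data frame.
#' @export
report_frame <- function(x) UseMethod("report_frame")

#' @export
report_frame.frequency_estimate <- function(x) {
  data.frame(window_start_s = 0,
             window_end_s = x$n_frames / x$frame_rate,
             mean_freq_hz = x$mean_freq,
             cv_percent = x$cv_percent,
             peak_power = x$peak_power,
             n_frames = x$n_frames)
}

#' @export
report_frame.multichannel_estimate <- function(x) {
  do.call(rbind, lapply(x$channels, report_frame))
}

#' @export
report_frame.monitor_report <- function(x) {
  rows <- lapply(seq_along(x$estimates), function(i) {
    df <- report_frame(x$estimates[[i]])
    df$window_start_s <- x$window_start_s[i]
    df$window_end_s <- x$window_end_s[i]
    df
  })
  do.call(rbind, rows)
}

#' Write an analysis report to CSV or JSON
#'
#' @param report A `frequency_estimate`, `multichannel_estimate` or
#'   `monitor_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  if (!is.character(format) || !all(format %in% c("csv", "json"))) {
    stop_parameter(sprintf("unknown report format '%s'",
                           paste(format, collapse = ",")))
  }
  format <- match.arg(format)
  df <- report_frame(report)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
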