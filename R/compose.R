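# Multi-channel composites: geometric reassembly of single-channel clips
# into one clip imaging several channels at once, emulating the standard
# video-editor reconstruction (zoom, rotate, place).

# zoom (percent) then rotate (degrees), bilinear with zero fill
.transform_frame <- function(mat, zoom, rotation) {
  out <- mat
  if (abs(zoom - 100) > 1e-9) {
    z <- zoom / 100
    out <- EBImage::resize(out, w = max(2L, round(nrow(out) * z)),
                           h = max(2L, round(ncol(out) * z)),
                           filter = "bilinear")
  }
  if (abs(rotation) > 1e-9) {
    out <- EBImage::rotate(out, rotation, filter = "bilinear")
  }
  as.matrix(EBImage::imageData(out))
}

# centre-crop (or zero-pad) a matrix to target rows x cols; returns the
# matrix plus the row/col selections so a mask can be cropped identically
.fit_to <- function(mat, rows, cols) {
  out <- matrix(0, rows, cols)
  sr <- nrow(mat); sc <- ncol(mat)
  take_r <- min(sr, rows); take_c <- min(sc, cols)
  src_r <- floor((sr - take_r) / 2) + seq_len(take_r)
  src_c <- floor((sc - take_c) / 2) + seq_len(take_c)
  dst_r <- floor((rows - take_r) / 2) + seq_len(take_r)
  dst_c <- floor((cols - take_c) / 2) + seq_len(take_c)
  out[dst_r, dst_c] <- mat[src_r, src_c]
  out
}

#' Compose single-channel clips into a multi-channel clip
#'
#' Two layouts are supported. `"vstack"` stacks the clips vertically into
#' parallel channels of equal width (no geometric transform applied);
#' `"canvas"` zooms and rotates each clip (bilinear interpolation, zero
#' fill), centre-crops the result to a horizontal band, and places the bands
#' top to bottom on a fixed canvas, emulating a multi-channel field of view
#' with channels of different apparent widths and directions. Frame `t` of
#' the composite is assembled from frame `t` of every input, so each
#' channel's periodicity is preserved and all fundamentals appear in a
#' single spectrum.
#'
#' @param clips A list of [frame_stack()] objects with equal frame counts and
#'   frame rates.
#' @param zooms Zoom percentages, one per clip (100 = unchanged); `"canvas"`
#'   layout only.
#' @param rotations Rotation angles in degrees, one per clip; `"canvas"`
#'   layout only.
#' @param layout `"vstack"` or `"canvas"`.
#' @param canvas_dim `c(rows, cols)` of the canvas for the `"canvas"` layout.
#' @param background Intensity filling canvas areas not covered by any
#'   transformed clip (default 0, i.e. zero fill).
#' @return A composite `frame_stack`.
#' @export
compose_multichannel <- function(clips, zooms = NULL, rotations = NULL,
                                 layout = c("vstack", "canvas"),
                                 canvas_dim = c(512L, 512L), background = 0) {
  layout <- match.arg(layout)
  if (!is.list(clips) || length(clips) < 1L ||
      !all(vapply(clips, inherits, logical(1), "frame_stack"))) {
    stop_parameter("'clips' must be a list of frame_stack objects")
  }
  counts <- vapply(clips, n_frames, integer(1))
  rates <- vapply(clips, function(s) s$frame_rate, numeric(1))
  if (length(unique(counts)) != 1L) {
    stop_dimension(sprintf("frame counts differ across clips: %s",
                           paste(counts, collapse = ", ")))
  }
  if (max(rates) - min(rates) > 1e-9) {
    stop_dimension("frame rates differ across clips; resample to a common rate first")
  }
  k <- counts[1]
  nc <- length(clips)

  if (layout == "vstack") {
    widths <- vapply(clips, function(s) frame_dim(s)[2], integer(1))
    if (length(unique(widths)) != 1L) {
      stop_dimension("'vstack' layout needs equal frame widths")
    }
    heights <- vapply(clips, function(s) frame_dim(s)[1], integer(1))
    out <- array(0, dim = c(sum(heights), widths[1], k))
    off <- cumsum(c(0L, heights))
    for (j in seq_len(nc)) {
      out[(off[j] + 1):off[j + 1], , ] <- clips[[j]]$frames
    }
    return(frame_stack(out, rates[1]))
  }

  if (is.null(zooms)) zooms <- rep(100, nc)
  if (is.null(rotations)) rotations <- rep(0, nc)
  if (length(zooms) != nc || length(rotations) != nc) {
    stop_parameter("'zooms' and 'rotations' must have one entry per clip")
  }
  cm <- as.integer(canvas_dim[1]); cn <- as.integer(canvas_dim[2])
  band_h <- cm %/% nc
  out <- array(background, dim = c(cm, cn, k))
  for (j in seq_len(nc)) {
    mask <- .fit_to(.transform_frame(matrix(1, frame_dim(clips[[j]])[1],
                                            frame_dim(clips[[j]])[2]),
                                     zooms[j], rotations[j]),
                    band_h, cn)
    mask <- pmin(pmax(mask, 0), 1)
    r0 <- (j - 1L) * band_h
    bg_part <- background * (1 - mask)
    for (i in seq_len(k)) {
      tf <- .fit_to(.transform_frame(clips[[j]]$frames[, , i],
                                     zooms[j], rotations[j]),
                    band_h, cn)
      out[(r0 + 1):(r0 + band_h), , i] <- pmax(tf + bg_part, 0)
      # keep transient transform buffers from inflating the heap while the
      # (large) output array is live
      if (i %% 100L == 0L) gc(FALSE)
    }
  }
  frame_stack(out, rates[1])
}
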