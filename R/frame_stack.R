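#' Construct a frame stack
#'
#' A frame stack is the canonical in-memory form of a video clip: an ordered
#' sequence of grayscale frames of identical spatial resolution, together with
#' the (constant) acquisition frame rate. Pixel intensities are non-negative
#' reals on an arbitrary linear scale; cosine similarity is invariant to the
#' scale, so 8-bit and 16-bit sources need no special treatment beyond a
#' constant normalization.
#'
#' @param frames A numeric array of dimension `m x n x n_frames` (rows,
#'   columns, frames), or a list of `m x n` matrices.
#' @param frame_rate Acquisition frame rate in frames per second (Hz). Must be
#'   supplied by the caller: container fps metadata is unreliable for
#'   high-speed captures, which are routinely re-wrapped at playback rates.
#' @return An object of class `frame_stack` with elements `frames` (3-d array)
#'   and `frame_rate`.
#' @examples
#' f1 <- matrix(runif(12), 3, 4)
#' f2 <- matrix(runif(12), 3, 4)
#' s <- frame_stack(list(f1, f2), frame_rate = 1000)
#' n_frames(s)
#' @export
frame_stack <- function(frames, frame_rate) {
  if (is.list(frames)) {
    if (length(frames) == 0L) {
      stop_parameter("a frame stack needs at least 2 frames, got 0")
    }
    frames <- lapply(frames, as.matrix)
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop_dimension(sprintf(
        "all frames must share one resolution; found %s",
        paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", ")))
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_parameter("'frames' must be an m x n x n_frames array or a list of matrices")
  }
  if (dim(frames)[3] < 2L) {
    stop_parameter(sprintf("a frame stack needs at least 2 frames, got %d",
                           dim(frames)[3]))
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      !is.finite(frame_rate) || frame_rate <= 0) {
    stop_parameter("'frame_rate' must be a single positive number (Hz)")
  }
  rng <- range(frames)  # single pass, no large temporaries
  if (anyNA(rng) || !all(is.finite(rng))) {
    stop_parameter("frame intensities must all be finite")
  }
  if (rng[1] < 0) {
    stop_parameter("frame intensities must be non-negative")
  }
  if (!is.double(frames)) storage.mode(frames) <- "double"
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate)),
            class = "frame_stack")
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Spatial resolution of a stack
#' @param stack A `frame_stack`.
#' @return Integer vector `c(m, n)` (rows, columns).
#' @export
frame_dim <- function(stack) dim(stack$frames)[1:2]

#' Extract one frame as a matrix
#' @param stack A `frame_stack`.
#' @param i Frame index (1-based).
#' @return An `m x n` numeric matrix.
#' @export
get_frame <- function(stack, i) {
  k <- n_frames(stack)
  if (i < 1L || i > k) {
    stop_parameter(sprintf("frame index %d outside 1..%d", i, k))
  }
  stack$frames[, , i]
}

#' Clip duration in seconds
#' @param stack A `frame_stack`.
#' @return Duration `n_frames / frame_rate` in seconds.
#' @export
clip_duration <- function(stack) n_frames(stack) / stack$frame_rate

#' Subset a frame stack
#'
#' Returns a new stack holding frames `i` (at least two) at the same frame
#' rate; used by the windowed monitor.
#'
#' @param x A `frame_stack`.
#' @param i Frame indices.
#' @param ... Ignored.
#' @return A `frame_stack`.
#' @export
`[.frame_stack` <- function(x, i, ...) {
  frame_stack(x$frames[, , i, drop = FALSE], x$frame_rate)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.6g fps (%.4g s)\n",
              n_frames(x), d[1], d[2], x$frame_rate, clip_duration(x)))
  invisible(x)
}

#' Quantize stack intensities to a fixed bit depth
#'
#' Clamps intensities to `[0, 1]` and rounds them to `2^bits` levels, i.e. the
#' representable values of a `bits`-bit camera. Stacks quantized this way
#' round-trip bit-exactly through [write_video()] / [read_video()].
#'
#' @param stack A `frame_stack`.
#' @param bits Bit depth, 8 or 16.
#' @return A quantized `frame_stack`.
#' @export
quantize_frames <- function(stack, bits = 8) {
  if (!bits %in% c(8, 16)) stop_parameter("'bits' must be 8 or 16")
  lv <- 2^bits - 1
  q <- round(pmin(pmax(stack$frames, 0), 1) * lv) / lv
  frame_stack(q, stack$frame_rate)
}
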