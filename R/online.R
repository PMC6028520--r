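# FIFO-buffered streaming estimation and windowed monitoring.
#
# Two index-aligned ring buffers hold the most recent frames and their cosine
# similarities against a reference fixed at stream init. Admitting a frame
# costs one dot product over the pixels (the reference norm is cached), so
# the per-update cost is independent of the buffer length; the spectrum is
# recomputed from the buffered similarity vector on demand.

#' Initialize a streaming state
#'
#' @param reference_frame The (non-zero) grayscale reference frame as an
#'   `m x n` matrix; all pushed frames are compared against it.
#' @param capacity Ring-buffer capacity in frames (default 5000). The stream
#'   is in its build-up phase until the buffer first fills, then switches to
#'   the real-time phase in which each admitted frame evicts the oldest one.
#' @param frame_rate Acquisition frame rate in Hz.
#' @return An object of class `stream_state` (mutable; [push_frame()] updates
#'   it in place and also returns it).
#' @export
init_stream <- function(reference_frame, capacity = 5000L, frame_rate) {
  reference_frame <- as.matrix(reference_frame)
  if (capacity < 16L) {
    stop_parameter(sprintf("'capacity' must be at least 16 frames, got %d",
                           capacity))
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_parameter("'frame_rate' must be positive")
  }
  ref <- as.vector(reference_frame)
  ref2 <- sum(ref * ref)
  if (ref2 == 0) stop_zero_vector("reference frame is all zero")
  e <- new.env(parent = emptyenv())
  e$ref <- ref
  e$ref_norm <- sqrt(ref2)
  e$dim <- dim(reference_frame)
  e$capacity <- as.integer(capacity)
  e$frame_rate <- frame_rate
  e$frames <- array(0, dim = c(dim(reference_frame), capacity))
  e$sims <- numeric(capacity)
  e$frames_seen <- 0L
  e$count <- 0L
  e$last_push_ops <- NA_real_
  class(e) <- "stream_state"
  e
}

#' Current phase of a stream
#' @param state A `stream_state`.
#' @return `"build_up"` while the buffer is filling, `"real_time"` once full.
#' @export
stream_phase <- function(state) {
  if (state$count < state$capacity) "build_up" else "real_time"
}

#' Admit one frame into the stream
#'
#' Appends the frame and its cosine similarity against the cached reference
#' to the ring buffers; once the buffers are full, each push evicts exactly
#' the oldest frame/similarity pair. The similarity update is a single
#' multiply-add pass over the pixels (cost recorded in
#' `state$last_push_ops`), independent of the buffer length.
#'
#' @param state A `stream_state` from [init_stream()].
#' @param frame An `m x n` matrix matching the reference resolution.
#' @return The updated `state`, invisibly.
#' @export
push_frame <- function(state, frame) {
  frame <- as.matrix(frame)
  if (!identical(dim(frame), state$dim)) {
    stop_dimension(sprintf("frame is %s but the reference is %s",
                           paste(dim(frame), collapse = "x"),
                           paste(state$dim, collapse = "x")))
  }
  v <- as.vector(frame)
  s <- .similarity_to_ref(v, state$ref, state$ref_norm,
                          label = sprintf("pushed frame %d",
                                          state$frames_seen + 1L))
  pos <- (state$frames_seen %% state$capacity) + 1L
  state$frames[, , pos] <- frame
  state$sims[pos] <- s
  state$frames_seen <- state$frames_seen + 1L
  state$count <- min(state$count + 1L, state$capacity)
  state$last_push_ops <- 2 * length(v)  # multiplies in sum(v*ref) + sum(v*v)
  invisible(state)
}

#' Buffered similarities in chronological order
#' @param state A `stream_state`.
#' @return Numeric vector of the `min(frames_seen, capacity)` most recent
#'   similarities, oldest first.
#' @export
stream_similarities <- function(state) {
  if (state$count < state$capacity) {
    state$sims[seq_len(state$count)]
  } else {
    idx <- ((state$frames_seen + 0:(state$capacity - 1L)) %% state$capacity) + 1L
    state$sims[idx]
  }
}

#' Frequency estimate from the current stream buffer
#'
#' Runs the spectral pipeline on the buffered similarity vector. The
#' estimate carries the current buffer length, making the spectral
#' resolution `delta_f = frame_rate / buffered_frames` explicit; during the
#' build-up phase the estimate is flagged provisional (coarser `delta_f`,
#' limited accuracy).
#'
#' @param state A `stream_state`.
#' @param ... Passed to [estimate_frequency()].
#' @return A `frequency_estimate`.
#' @export
stream_estimate <- function(state, ...) {
  if (state$count < 16L) {
    stop_insufficient(sprintf(
      "only %d similarities buffered; need at least 16", state$count))
  }
  sims <- stream_similarities(state)
  ref_idx <- NA_integer_
  if (state$frames_seen <= state$capacity) {
    # reference is conventionally the first pushed frame while it survives
    hit <- which(abs(sims - 1) <= 1e-12)
    if (length(hit) > 0 && hit[1] == 1L) ref_idx <- 1L
  }
  sv <- similarity_vector(sims, ref_idx, state$frame_rate)
  est <- estimate_frequency(compute_auto_spectrum(sv), ...)
  est$provisional <- stream_phase(state) == "build_up"
  est
}

#' Re-designate the streaming reference frame
#'
#' Replaces the reference with a buffered or supplied frame and recomputes
#' the buffered similarities against it (one pass over the buffer). Useful
#' after a large regime change, when the original reference pattern may no
#' longer recur.
#'
#' @param state A `stream_state`.
#' @param frame New reference frame; default: the most recently pushed frame.
#' @return The updated `state`, invisibly.
#' @export
reref_stream <- function(state, frame = NULL) {
  if (is.null(frame)) {
    if (state$count < 1L) stop_insufficient("no frames buffered to re-reference from")
    pos <- ((state$frames_seen - 1L) %% state$capacity) + 1L
    frame <- state$frames[, , pos]
  }
  frame <- as.matrix(frame)
  ref <- as.vector(frame)
  ref2 <- sum(ref * ref)
  if (ref2 == 0) stop_zero_vector("new reference frame is all zero")
  state$ref <- ref
  state$ref_norm <- sqrt(ref2)
  for (p in seq_len(state$count)) {
    state$sims[p] <- .similarity_to_ref(as.vector(state$frames[, , p]),
                                        state$ref, state$ref_norm)
  }
  invisible(state)
}

#' @export
print.stream_state <- function(x, ...) {
  cat(sprintf("<stream_state> %s: %d/%d frames buffered, %d seen, %.6g fps\n",
              stream_phase(x), x$count, x$capacity, x$frames_seen,
              x$frame_rate))
  invisible(x)
}

#' Windowed monitoring of a droplet generation process
#'
#' Partitions a clip (or a frame iterator) into consecutive windows of
#' `window_frames` frames starting every `interval_frames` frames, designates
#' each window's first frame as its reference, and runs the batch pipeline
#' per window. The per-window mean frequency tracks rate changes at the
#' window cadence, and the per-window CV flags disturbed periods.
#'
#' @param stack_stream A [frame_stack()], or a function that returns the next
#'   `m x n` frame matrix on each call and `NULL` at end of stream.
#' @param window_frames Frames per analysis window (at least 16).
#' @param interval_frames Frames between window starts; defaults to
#'   `window_frames` (non-overlapping windows).
#' @param frame_rate Frame rate in Hz; required for iterator input, taken
#'   from the stack otherwise.
#' @param ... Passed to [estimate_frequency()].
#' @return An object of class `monitor_report`: window bounds in seconds plus
#'   one `frequency_estimate` per window.
#' @export
monitor_process <- function(stack_stream, window_frames,
                            interval_frames = window_frames,
                            frame_rate = NULL, ...) {
  if (window_frames < 16L) stop_parameter("'window_frames' must be at least 16")
  if (interval_frames < 1L) stop_parameter("'interval_frames' must be at least 1")

  if (is.function(stack_stream)) {
    if (is.null(frame_rate)) stop_parameter("'frame_rate' required for iterator input")
    frames <- list()
    repeat {
      f <- stack_stream()
      if (is.null(f)) break
      frames[[length(frames) + 1L]] <- as.matrix(f)
    }
    if (length(frames) < window_frames) {
      stop_insufficient(sprintf("stream has %d frames; one window needs %d",
                                length(frames), window_frames))
    }
    stack_stream <- frame_stack(frames, frame_rate)
  }
  if (!inherits(stack_stream, "frame_stack")) {
    stop_parameter("'stack_stream' must be a frame_stack or frame iterator")
  }
  k <- n_frames(stack_stream)
  fr <- stack_stream$frame_rate
  if (k < window_frames) {
    stop_insufficient(sprintf("clip has %d frames; one window needs %d",
                              k, window_frames))
  }
  starts <- seq.int(1L, k - window_frames + 1L, by = interval_frames)
  ests <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + window_frames - 1L)
    sv <- build_similarity_vector(stack_stream[idx], reference_index = 1L)
    ests[[j]] <- estimate_frequency(compute_auto_spectrum(sv), ...)
  }
  structure(list(window_start_s = (starts - 1L) / fr,
                 window_end_s = (starts - 1L + window_frames) / fr,
                 interval_s = interval_frames / fr,
                 estimates = ests),
            class = "monitor_report")
}

#' @export
print.monitor_report <- function(x, ...) {
  cat(sprintf("<monitor_report> %d windows, interval %.4g s\n",
              length(x$estimates), x$interval_s))
  print(report_frame(x), row.names = FALSE)
  invisible(x)
}
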