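# Core similarity machinery: frame flattening, cosine similarity, and the
# per-clip similarity vector.

# Shared similarity kernel. Both the batch path and the streaming path call
# the same compiled accumulation loop with an identical reference vector and
# cached reference norm, so their results agree bit for bit. Cost is one
# multiply-add pass over the pixels, with no temporaries.
.similarity_to_ref <- function(v, ref, ref_norm, label = "frame") {
  s <- .cpp_cos_sim_one(v, ref, ref_norm)
  if (is.na(s)) {
    stop_zero_vector(sprintf("all-zero %s: cosine similarity undefined", label))
  }
  s
}

#' Flatten a grayscale frame into its pixel vector
#'
#' Pixels are listed column by column: all rows of column 1, then all rows of
#' column 2, and so on (R's native column-major order). Any fixed order works
#' for cosine similarity -- dot products are permutation invariant -- but this
#' one is the package's canonical convention.
#'
#' @param frame An `m x n` numeric matrix.
#' @param index Optional source frame index, kept as an attribute.
#' @return A numeric vector of length `m * n` with attribute `source_index`.
#' @examples
#' flatten_frame(matrix(c(10, 20), 2, 1))
#' @export
flatten_frame <- function(frame, index = NA_integer_) {
  frame <- as.matrix(frame)
  if (length(frame) < 1L) stop_parameter("empty frame")
  v <- as.vector(frame)
  if (sum(v * v) == 0) {
    stop_zero_vector("all-zero frame: grayscale vector has zero norm")
  }
  attr(v, "source_index") <- index
  v
}

#' Cosine similarity of two grayscale vectors
#'
#' The cosine of the angle between two non-zero vectors,
#' `sum(a*b) / (||a|| ||b||)`, in `[-1, 1]`. It is symmetric and invariant to
#' positive rescaling of either argument, which is why bit depth and exposure
#' scaling do not affect the analysis.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return A number in `[-1, 1]`; 1 for identical (or proportional) frames.
#' @examples
#' cosine_similarity(c(3, 4), c(4, 3))  # 24/25
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_dimension(sprintf("vector lengths differ: %d vs %d",
                           length(a), length(b)))
  }
  b2 <- sum(b * b)
  if (b2 == 0) stop_zero_vector("all-zero vector: cosine similarity undefined")
  .similarity_to_ref(a, b, sqrt(b2))
}

#' Build the similarity vector of a clip
#'
#' Computes the cosine similarity between every frame (including the reference
#' itself) and the designated reference frame, in frame order. For a stable
#' droplet generation process the reference pattern reappears once per
#' generation period, so this vector oscillates at the droplet generation
#' frequency.
#'
#' @param stack A [frame_stack()].
#' @param reference_index Index of the reference frame (default 1, the first
#'   frame of the clip).
#' @param roi Optional region of interest `c(row1, row2, col1, col2)` cropped
#'   identically from every frame before comparison. Default: whole frames.
#' @return An object of class `similarity_vector` with elements
#'   `similarities`, `reference_index`, `frame_rate`.
#' @export
build_similarity_vector <- function(stack, reference_index = 1L, roi = NULL) {
  if (!inherits(stack, "frame_stack")) stop_parameter("'stack' must be a frame_stack")
  k <- n_frames(stack)
  r <- as.integer(reference_index)
  if (is.na(r) || r < 1L || r > k) {
    stop_parameter(sprintf("reference index %s outside 1..%d",
                           as.character(reference_index), k))
  }
  frames <- stack$frames
  if (!is.null(roi)) {
    if (length(roi) != 4L) stop_parameter("'roi' must be c(row1, row2, col1, col2)")
    d <- dim(frames)
    if (roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 || roi[4] > d[2] ||
        roi[1] > roi[2] || roi[3] > roi[4]) {
      stop_parameter("'roi' outside frame bounds")
    }
    frames <- frames[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  }
  ref <- as.vector(frames[, , r])
  ref2 <- sum(ref * ref)
  if (ref2 == 0) {
    stop_zero_vector(sprintf("reference frame %d is all zero", r))
  }
  ref_norm <- sqrt(ref2)
  sims <- .cpp_cos_sim_stack(frames, prod(dim(frames)[1:2]), ref, ref_norm)
  if (anyNA(sims)) {
    stop_zero_vector(sprintf("frame %d is all zero: cosine similarity undefined",
                             which(is.na(sims))[1]))
  }
  similarity_vector(sims, r, stack$frame_rate)
}

#' Construct a similarity vector object
#'
#' Low-level constructor; most users obtain one from
#' [build_similarity_vector()] or the streaming buffer.
#'
#' @param similarities Numeric vector of per-frame cosine similarities.
#' @param reference_index Index of the reference frame within the vector, or
#'   `NA` when the reference is external to it (streaming window after the
#'   reference was evicted).
#' @param frame_rate Frame rate in Hz.
#' @return A `similarity_vector`.
#' @export
similarity_vector <- function(similarities, reference_index, frame_rate) {
  s <- as.numeric(similarities)
  if (any(abs(s) > 1 + 1e-9)) {
    stop_parameter("similarities outside [-1, 1]")
  }
  s <- pmin(1, pmax(-1, s))  # absorb <=1e-9 floating-point overshoot
  r <- reference_index
  if (!is.na(r)) {
    r <- as.integer(r)
    if (r < 1L || r > length(s)) stop_parameter("reference index outside vector")
    if (abs(s[r] - 1) > 1e-12) {
      stop_parameter("self-similarity at the reference index must be 1")
    }
  }
  structure(list(similarities = s, reference_index = r,
                 frame_rate = as.numeric(frame_rate)),
            class = "similarity_vector")
}

#' @export
print.similarity_vector <- function(x, ...) {
  cat(sprintf("<similarity_vector> %d frames @ %.6g fps, reference %s, range [%.4f, %.4f]\n",
              length(x$similarities), x$frame_rate,
              ifelse(is.na(x$reference_index), "external", x$reference_index),
              min(x$similarities), max(x$similarities)))
  invisible(x)
}

#' @export
length.similarity_vector <- function(x) length(x$similarities)
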