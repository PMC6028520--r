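# Minimal uncompressed grayscale AVI (RIFF) writer and reader.
#
# 8-bit 'DIB ' frames with a grayscale palette, bottom-up rows padded to
# 4-byte boundaries -- the raw-AVI layout any standard player accepts. The
# reader handles this layout (and 24-bit BGR) only; compressed streams are
# rejected. Written by hand because no installed package reads or writes AVI
# containers.

#' Write a stack as an uncompressed grayscale AVI
#'
#' Frames are clamped to `[0, 1]` and stored at 8 bits; for stacks already
#' quantized to 8-bit levels the file round-trips bit-exactly through
#' [read_avi()].
#'
#' @param stack A [frame_stack()].
#' @param path Output `.avi` path.
#' @return `path`, invisibly.
#' @export
write_avi <- function(stack, path) {
  if (!inherits(stack, "frame_stack")) stop_parameter("'stack' must be a frame_stack")
  d <- frame_dim(stack)
  h <- d[1]; w <- d[2]
  k <- n_frames(stack)
  fr <- stack$frame_rate
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  frame_bytes <- row_bytes * h

  con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop_io(sprintf("cannot open '%s' for writing", path))
  on.exit(close(con))
  u32 <- function(...) writeBin(as.integer(c(...)), con, size = 4,
                                endian = "little")
  u16 <- function(...) writeBin(as.integer(c(...)), con, size = 2,
                                endian = "little")
  tag <- function(s) writeBin(charToRaw(s), con)

  strf_sz <- 40L + 256L * 4L
  strl_sz <- 4L + (8L + 56L) + (8L + strf_sz)
  hdrl_sz <- 4L + (8L + 56L) + (8L + strl_sz)
  movi_sz <- 4L + k * (8L + frame_bytes)
  idx_sz <- 16L * k
  riff_sz <- 4L + (8L + hdrl_sz) + (8L + movi_sz) + (8L + idx_sz)

  tag("RIFF"); u32(riff_sz); tag("AVI ")
  tag("LIST"); u32(hdrl_sz); tag("hdrl")
  tag("avih"); u32(56L)
  u32(round(1e6 / fr), frame_bytes * ceiling(fr), 0L, 16L, k, 0L, 1L,
      frame_bytes, w, h, 0L, 0L, 0L, 0L)
  tag("LIST"); u32(strl_sz); tag("strl")
  tag("strh"); u32(56L)
  tag("vids"); tag("DIB ")
  u32(0L); u16(0L, 0L); u32(0L, 1000L, round(fr * 1000), 0L, k, frame_bytes,
                            0L, 0L)
  u16(0L, 0L, w, h)
  tag("strf"); u32(strf_sz)
  u32(40L, w, h); u16(1L, 8L); u32(0L, frame_bytes, 0L, 0L, 256L, 0L)
  pal <- as.raw(rep(0:255, each = 4) * c(1L, 1L, 1L, 0L))
  writeBin(pal, con)

  tag("LIST"); u32(movi_sz); tag("movi")
  for (i in seq_len(k)) {
    tag("00db"); u32(frame_bytes)
    q <- round(pmin(pmax(stack$frames[, , i], 0), 1) * 255)
    buf <- matrix(0L, row_bytes, h)
    buf[seq_len(w), ] <- t(q[h:1, , drop = FALSE])
    writeBin(as.raw(buf), con)
  }
  tag("idx1"); u32(idx_sz)
  for (i in seq_len(k)) {
    tag("00db")
    u32(16L, 4L + (i - 1L) * (8L + frame_bytes), frame_bytes)
  }
  invisible(path)
}

.u32_at <- function(raw, pos) {
  sum(as.numeric(raw[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

.tag_at <- function(raw, pos) rawToChar(raw[pos:(pos + 3L)])

#' Read an uncompressed grayscale AVI
#'
#' Supports the raw-DIB layout produced by [write_avi()]: 8-bit palettized or
#' 24-bit BGR frames, bottom-up, no compression.
#'
#' @param path Input `.avi` path.
#' @param frame_rate Frame rate in Hz (caller-supplied; the container's
#'   timing header is ignored).
#' @param max_frames Keep at most this many frames from the start.
#' @return A [frame_stack()].
#' @export
read_avi <- function(path, frame_rate, max_frames = Inf) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 24) stop_io(sprintf("cannot read AVI '%s'", path))
  raw <- readBin(path, "raw", n = sz)
  if (.tag_at(raw, 1L) != "RIFF" || .tag_at(raw, 9L) != "AVI ") {
    stop_io(sprintf("'%s' is not an AVI (RIFF) file", path))
  }

  w <- h <- bits <- compression <- NULL
  pal_gray <- NULL
  frame_offsets <- numeric(0)
  frame_sizes <- numeric(0)

  walk <- function(pos, end) {
    while (pos + 8 <= end + 1) {
      ck <- .tag_at(raw, pos)
      ck_sz <- .u32_at(raw, pos + 4L)
      body <- pos + 8L
      if (ck == "LIST") {
        walk(body + 4L, body + ck_sz - 1L)
      } else if (ck == "strf") {
        w <<- .u32_at(raw, body + 4L)
        h <<- .u32_at(raw, body + 8L)
        bits <<- .u32_at(raw, body + 14L) %% 65536
        compression <<- .u32_at(raw, body + 16L)
        if (bits == 8 && ck_sz >= 40 + 256 * 4) {
          pal <- matrix(as.numeric(raw[(body + 40L):(body + 40L + 1023L)]),
                        nrow = 4)
          pal_gray <<- if (all(pal[1, ] == pal[2, ] & pal[2, ] == pal[3, ])) {
            pal[1, ] / 255  # pure grayscale palette: exact mapping
          } else {
            (0.114 * pal[1, ] + 0.587 * pal[2, ] + 0.299 * pal[3, ]) / 255
          }
        }
      } else if (ck %in% c("00db", "00dc")) {
        frame_offsets <<- c(frame_offsets, body)
        frame_sizes <<- c(frame_sizes, ck_sz)
      }
      pos <- body + ck_sz + (ck_sz %% 2)  # chunks are word-aligned
    }
  }
  walk(13L, sz)

  if (is.null(w) || length(frame_offsets) == 0L) {
    stop_io(sprintf("no video frames found in '%s'", path))
  }
  if (!is.null(compression) && compression != 0) {
    stop_io(sprintf("compressed AVI stream (codec 0x%x) not supported; use an uncompressed clip or a frame directory",
                    compression))
  }
  if (!bits %in% c(8, 24)) {
    stop_io(sprintf("unsupported AVI bit depth %d (expect 8 or 24)", bits))
  }
  if (is.finite(max_frames)) {
    keep <- seq_len(min(length(frame_offsets), max_frames))
    frame_offsets <- frame_offsets[keep]
    frame_sizes <- frame_sizes[keep]
  }
  row_bytes <- if (bits == 8) ((w + 3) %/% 4) * 4 else ((3 * w + 3) %/% 4) * 4
  if (is.null(pal_gray)) pal_gray <- (0:255) / 255

  frames <- vector("list", length(frame_offsets))
  for (i in seq_along(frame_offsets)) {
    o <- frame_offsets[i]
    if (frame_sizes[i] < row_bytes * h) {
      stop_io(sprintf("frame %d truncated in '%s'", i, path))
    }
    bytes <- as.integer(raw[o:(o + row_bytes * h - 1)])
    if (bits == 8) {
      mb <- matrix(bytes, nrow = row_bytes)[seq_len(w), , drop = FALSE]
      g <- matrix(pal_gray[mb + 1L], nrow = w)
      frames[[i]] <- t(g)[h:1, , drop = FALSE]
    } else {
      mb <- matrix(bytes, nrow = row_bytes)
      bgr <- array(mb[seq_len(3 * w), , drop = FALSE], dim = c(3, w, h))
      g <- (0.114 * bgr[1, , ] + 0.587 * bgr[2, , ] + 0.299 * bgr[3, , ]) / 255
      frames[[i]] <- t(matrix(g, nrow = w))[h:1, , drop = FALSE]
    }
  }
  frame_stack(frames, frame_rate)
}
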