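# Synthetic droplet-generation video generator with exact ground truth.
#
# The model is deliberately an image-recurrence model, not fluid dynamics:
# dark anti-aliased circular droplets are born at a nozzle at a scheduled
# instantaneous rate, advected along the channel at speed spacing x rate, and
# rendered on a bright channel background with optional Gaussian pixel noise.
# For a constant schedule the rendered pattern is exactly periodic with the
# droplet generation period, which is the only property the similarity
# analysis relies on.

#' Specify a synthetic droplet video
#'
#' @param frequency_schedule Either a single droplet generation frequency
#'   (Hz), constant over the clip, or a data frame with columns `start`,
#'   `end` (seconds) and `freq` (Hz) tiling `[0, n_frames / frame_rate]`
#'   without gaps or overlaps.
#' @param frame_rate Acquisition frame rate (Hz). Must exceed twice every
#'   scheduled frequency; a warning is issued below 5x (the acquisition
#'   rule for faithful tracking).
#' @param n_frames Number of frames to render.
#' @param resolution `c(m, n)`: frame height and width in pixels. Default
#'   62 x 512, a typical high-speed crop of a single channel.
#' @param channel_width Channel bore in pixels (across the flow axis).
#' @param droplet_diameter Droplet diameter in pixels; must be smaller than
#'   the channel width and the droplet spacing.
#' @param spacing_px Centre-to-centre droplet spacing in pixels; advection
#'   speed is `spacing_px * f(t)` px/s, so consecutive droplets sit one
#'   spacing apart.
#' @param contrast Intensity drop at the droplet centre relative to the
#'   channel background (droplets are dark on bright).
#' @param jitter Relative standard deviation of inter-droplet intervals
#'   (0 = perfectly regular generation).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (intensity units; frames are clipped at 0).
#' @param background Channel background intensity in `[0, 1]`.
#' @param transition_s Duration (s) of the linear frequency ramp inserted at
#'   each schedule boundary; 0 gives a hard step. Pump-driven flow changes
#'   sweep the rate continuously, which is what a ramp emulates.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `synthetic_video_config`.
#' @export
synthetic_video_config <- function(frequency_schedule, frame_rate, n_frames,
                                   resolution = c(62L, 512L),
                                   channel_width = 48, droplet_diameter = 24,
                                   spacing_px = 64, contrast = 0.6,
                                   jitter = 0, noise_sigma = 0.02,
                                   background = 0.9, transition_s = 0,
                                   seed = 1L) {
  duration <- n_frames / frame_rate
  if (is.numeric(frequency_schedule) && is.null(dim(frequency_schedule))) {
    if (length(frequency_schedule) != 1L) {
      stop_parameter("a bare numeric schedule must be a single frequency")
    }
    frequency_schedule <- data.frame(start = 0, end = duration,
                                     freq = frequency_schedule)
  }
  sch <- as.data.frame(frequency_schedule)
  if (!all(c("start", "end", "freq") %in% names(sch))) {
    stop_parameter("schedule needs columns start, end, freq")
  }
  sch <- sch[order(sch$start), , drop = FALSE]
  if (abs(sch$start[1]) > 1e-9 || abs(sch$end[nrow(sch)] - duration) > 1e-9 ||
      (nrow(sch) > 1 && any(abs(sch$start[-1] - sch$end[-nrow(sch)]) > 1e-9))) {
    stop_parameter("schedule must tile [0, n_frames/frame_rate] without gaps or overlaps")
  }
  if (any(sch$freq <= 0)) stop_parameter("scheduled frequencies must be positive")
  if (any(sch$freq >= frame_rate / 2)) {
    stop_parameter("scheduled frequency at or above the Nyquist rate (frame_rate / 2)")
  }
  if (frame_rate < 5 * max(sch$freq)) {
    warning(sprintf(
      "frame rate %.4g fps is below 5x the maximum scheduled frequency %.4g Hz; estimates may degrade",
      frame_rate, max(sch$freq)))
  }
  m <- as.integer(resolution[1]); n <- as.integer(resolution[2])
  if (!(droplet_diameter < channel_width && channel_width <= min(m, n))) {
    stop_parameter("need droplet_diameter < channel_width <= min(resolution)")
  }
  if (spacing_px <= droplet_diameter) {
    stop_parameter("'spacing_px' must exceed the droplet diameter")
  }
  structure(list(schedule = sch, frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), resolution = c(m, n),
                 channel_width = channel_width,
                 droplet_diameter = droplet_diameter, spacing_px = spacing_px,
                 contrast = contrast, jitter = jitter,
                 noise_sigma = noise_sigma, background = background,
                 transition_s = transition_s, seed = as.integer(seed)),
            class = "synthetic_video_config")
}

# Piecewise-linear instantaneous rate f(t) (constant segments joined by
# linear ramps of length transition_s) and its exact integral F(t).
# F is linear on constant pieces and quadratic on ramps, so a constant
# schedule yields exactly periodic droplet positions.
.make_rate_fun <- function(schedule, transition_s) {
  eps <- 1e-12
  kt <- schedule$start[1]
  kf <- schedule$freq[1]
  if (nrow(schedule) > 1) {
    for (j in 2:nrow(schedule)) {
      tb <- schedule$start[j]
      ramp <- min(max(transition_s, eps),
                  schedule$end[j] - schedule$start[j])
      kt <- c(kt, tb, tb + ramp)
      kf <- c(kf, schedule$freq[j - 1], schedule$freq[j])
    }
  }
  kt <- c(kt, schedule$end[nrow(schedule)])
  kf <- c(kf, schedule$freq[nrow(schedule)])
  # cumulative integral at the knots (trapezoid is exact for linear pieces)
  kF <- c(0, cumsum(diff(kt) * (kf[-1] + kf[-length(kf)]) / 2))
  f_at <- function(t) {
    tc <- pmin(pmax(t, kt[1]), kt[length(kt)])
    stats::approx(kt, kf, xout = tc, rule = 2, ties = "ordered")$y
  }
  F_at <- function(t) {
    out <- numeric(length(t))
    below <- t < kt[1]
    out[below] <- (t[below] - kt[1]) * kf[1]
    above <- t > kt[length(kt)]
    out[above] <- kF[length(kF)] +
      (t[above] - kt[length(kt)]) * kf[length(kf)]
    mid <- !below & !above
    if (any(mid)) {
      i <- findInterval(t[mid], kt, rightmost.closed = TRUE)
      dt <- t[mid] - kt[i]
      slope <- (kf[i + 1L] - kf[i]) / pmax(kt[i + 1L] - kt[i], eps)
      out[mid] <- kF[i] + kf[i] * dt + 0.5 * slope * dt^2
    }
    out
  }
  list(f = f_at, F = F_at)
}

#' Generate a synthetic droplet video with ground truth
#'
#' Renders the clip described by a [synthetic_video_config()] and returns both
#' the frame stack and the exact generative ground truth (droplet birth times
#' and the per-frame instantaneous generation frequency), the oracle against
#' which recovery is judged.
#'
#' @param config A `synthetic_video_config`.
#' @return A list with `stack` (a [frame_stack()]) and `truth` (class
#'   `ground_truth`: `birth_times` in seconds, possibly negative for droplets
#'   pre-filling the channel at t = 0; `frame_freq`, the scheduled
#'   instantaneous frequency at each frame time; `config`).
#' @export
generate_video <- function(config) {
  if (!inherits(config, "synthetic_video_config")) {
    stop_parameter("'config' must be a synthetic_video_config")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  m <- config$resolution[1]; n <- config$resolution[2]
  fr <- config$frame_rate
  k <- config$n_frames
  rate <- .make_rate_fun(config$schedule, config$transition_s)
  spacing <- config$spacing_px
  r <- config$droplet_diameter / 2

  # droplet birth times: start far enough in the past to pre-fill the channel
  t0 <- -(n + config$droplet_diameter) / (spacing * rate$f(0))
  duration <- k / fr
  births <- numeric(0)
  b <- t0
  guard <- 0L
  max_births <- ceiling((duration - t0) * max(config$schedule$freq) * 2) + 64L
  while (b <= duration && guard < max_births) {
    births <- c(births, b)
    gap <- 1 / rate$f(b)
    if (config$jitter > 0) {
      gap <- gap * max(0.1, 1 + config$jitter * stats::rnorm(1))
    }
    b <- b + gap
    guard <- guard + 1L
  }

  # static background: bright channel bore, dimmer walls
  yc <- (m + 1) / 2
  half_w <- config$channel_width / 2
  rows <- seq_len(m)
  base_col <- ifelse(abs(rows - yc) <= half_w,
                     config$background, config$background * 0.8)
  base <- matrix(base_col, m, n)

  frames <- array(0, dim = c(m, n, k))
  t_frames <- (0:(k - 1)) / fr
  F_frames <- rate$F(t_frames)
  F_births <- rate$F(births)
  drop_floor <- config$background - config$contrast

  for (i in seq_len(k)) {
    fm <- base
    x <- spacing * (F_frames[i] - F_births)
    vis <- which(x >= -r - 1 & x <= n + r + 1)
    for (j in vis) {
      xc <- x[j]
      cols <- max(1L, floor(xc - r - 1)):min(n, ceiling(xc + r + 1))
      rws <- max(1L, floor(yc - r - 1)):min(m, ceiling(yc + r + 1))
      if (length(cols) < 1L || length(rws) < 1L) next
      d <- sqrt(outer((rws - yc)^2, (cols - xc)^2, `+`))
      cov <- pmin(1, pmax(0, r + 0.5 - d))
      fm[rws, cols] <- pmax(drop_floor, fm[rws, cols] - config$contrast * cov)
    }
    if (config$noise_sigma > 0) {
      fm <- fm + matrix(stats::rnorm(m * n, 0, config$noise_sigma), m, n)
      fm <- pmax(fm, 0)
    }
    frames[, , i] <- fm
  }

  truth <- structure(list(birth_times = births,
                          frame_freq = rate$f(t_frames),
                          frame_times = t_frames,
                          config = config),
                     class = "ground_truth")
  list(stack = frame_stack(frames, fr), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d droplet births over [%.4g, %.4g] s\n",
              length(x$birth_times), min(x$birth_times), max(x$birth_times)))
  invisible(x)
}

#' Interval statistics of the generative ground truth
#'
#' The simulator-side analogue of the manual counting-timing baseline: the
#' mean generation frequency over a window is the number of inter-droplet
#' intervals divided by their summed duration, and the CV is the standard
#' deviation over the mean of those intervals, in percent.
#'
#' @param truth A `ground_truth` from [generate_video()].
#' @param window `c(start, end)` in seconds.
#' @return A list with `mean_freq` (Hz), `cv_percent`, and `n_intervals`.
#' @export
truth_statistics <- function(truth, window) {
  if (!inherits(truth, "ground_truth")) stop_parameter("not a ground_truth")
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_parameter("'window' must be c(start, end) with start < end")
  }
  b <- truth$birth_times
  b <- b[b >= window[1] & b <= window[2]]
  if (length(b) < 2L) {
    stop_insufficient("fewer than 2 droplet births inside the window")
  }
  iv <- diff(b)
  cv <- if (length(iv) >= 2L) 100 * stats::sd(iv) / mean(iv) else 0
  list(mean_freq = length(iv) / sum(iv),
       cv_percent = cv,
       n_intervals = length(iv))
}
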