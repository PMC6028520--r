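# Cyclic auto-spectrum of the similarity vector and frequency estimation.
#
# The similarity vector hovers just below 1 with a small periodic dip per
# droplet, so the DC offset is removed before the FFT; the fundamental peak of
# the one-sided periodogram locates the droplet generation frequency.

#' Cyclic auto-spectrum of a similarity vector
#'
#' Computes the one-sided power spectrum (periodogram) of the mean-subtracted
#' similarity vector. Power is scaled as `|FFT|^2 / n` with interior bins
#' doubled, so the total one-sided power equals `n` times the population
#' variance of the vector (Parseval). The spectral resolution is
#' `delta_f = frame_rate / n_frames`: frequency accuracy improves linearly
#' with clip length.
#'
#' @param sv A [similarity_vector()] (or plain numeric vector plus
#'   `frame_rate`) of length at least 16.
#' @param frame_rate Frame rate in Hz; only needed when `sv` is a bare vector.
#' @return An object of class `auto_spectrum` with `freqs` (Hz, from 0 to the
#'   Nyquist frequency), `power`, `delta_f`, `n_frames`, `frame_rate`, a
#'   `degenerate` flag (constant input: no oscillation present), and the
#'   detrended signal used for local spectral refinement.
#' @export
compute_auto_spectrum <- function(sv, frame_rate = NULL) {
  if (inherits(sv, "similarity_vector")) {
    x <- sv$similarities
    frame_rate <- sv$frame_rate
  } else {
    x <- as.numeric(sv)
    if (is.null(frame_rate)) stop_parameter("'frame_rate' required for a bare vector")
  }
  n <- length(x)
  if (n < 16L) {
    stop_insufficient(sprintf("need at least 16 samples for a spectrum, got %d", n))
  }
  x <- x - mean(x)
  degenerate <- max(abs(x)) < 1e-12
  ft <- stats::fft(x)
  K <- n %/% 2L
  pw <- Mod(ft[seq_len(K + 1L)])^2 / n
  # one-sided doubling: every bin except DC and (for even n) Nyquist
  top <- if (n %% 2L == 0L) K else K + 1L
  if (top >= 2L) pw[2:top] <- 2 * pw[2:top]
  pw[1] <- 0  # exactly zero by detrending, up to rounding
  delta_f <- frame_rate / n
  structure(list(freqs = (0:K) * delta_f, power = pw, delta_f = delta_f,
                 n_frames = n, frame_rate = frame_rate,
                 degenerate = degenerate, signal = if (degenerate) NULL else x),
            class = "auto_spectrum")
}

#' Construct an auto-spectrum from explicit grid and power values
#'
#' For externally computed or hand-constructed spectra (no underlying signal,
#' so no sub-bin refinement is possible).
#'
#' @param freqs Uniformly spaced frequency grid starting at 0 (Hz).
#' @param power Non-negative spectral power per grid point.
#' @param frame_rate Frame rate in Hz; defaults to twice the top grid
#'   frequency.
#' @return An `auto_spectrum`.
#' @export
as_auto_spectrum <- function(freqs, power, frame_rate = NULL) {
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power) || length(freqs) < 2L) {
    stop_parameter("'freqs' and 'power' must be equal-length vectors (>= 2)")
  }
  d <- diff(freqs)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * d[1]) {
    stop_parameter("'freqs' must be strictly increasing with uniform spacing")
  }
  if (any(power < 0)) stop_parameter("'power' must be non-negative")
  delta_f <- d[1]
  if (is.null(frame_rate)) frame_rate <- 2 * max(freqs)
  structure(list(freqs = freqs, power = power, delta_f = delta_f,
                 n_frames = round(frame_rate / delta_f), frame_rate = frame_rate,
                 degenerate = all(power == 0), signal = NULL),
            class = "auto_spectrum")
}

#' @export
print.auto_spectrum <- function(x, ...) {
  cat(sprintf("<auto_spectrum> %d bins, delta_f = %.6g Hz, Nyquist %.6g Hz%s\n",
              length(x$freqs), x$delta_f, max(x$freqs),
              if (x$degenerate) " [degenerate: no oscillation]" else ""))
  invisible(x)
}

# indices of strict-left / weak-right local maxima, excluding the DC bin;
# plateau ties resolve to the lower frequency (determinism)
.local_maxima <- function(p) {
  L <- length(p)
  if (L < 3L) return(integer(0))
  left <- c(Inf, p[-L])
  right <- c(p[-1], -Inf)
  idx <- which(p > left & p >= right)
  idx[idx >= 2L]
}

# qualifying peaks: local maxima prominent against both the global maximum
# and the broadband noise floor
.qualifying_peaks <- function(spectrum, prominence_frac, min_snr) {
  p <- spectrum$power
  lm <- .local_maxima(p)
  if (length(lm) == 0L) return(integer(0))
  gm <- max(p[-1])
  floor_p <- stats::median(p[-1])
  keep <- p[lm] >= prominence_frac * gm & p[lm] >= min_snr * floor_p
  lm[keep]
}

# FWHM band around peak index `pk`, capped at +/- max_extent_frac of the peak
# frequency and optionally at hard index bounds (multi-channel separation)
.fwhm_band <- function(spectrum, pk, max_extent_frac = 0.05,
                       lo_cap = 2L, hi_cap = length(spectrum$power)) {
  p <- spectrum$power
  f <- spectrum$freqs
  half <- p[pk] / 2
  fmin <- f[pk] * (1 - max_extent_frac)
  fmax <- f[pk] * (1 + max_extent_frac)
  lo <- pk
  while (lo - 1L >= max(2L, lo_cap) && p[lo - 1L] >= half && f[lo - 1L] >= fmin) {
    lo <- lo - 1L
  }
  hi <- pk
  while (hi + 1L <= min(length(p), hi_cap) && p[hi + 1L] >= half && f[hi + 1L] <= fmax) {
    hi <- hi + 1L
  }
  structure(list(lo = lo, hi = hi, peak = pk,
                 lo_hz = f[lo], hi_hz = f[hi], peak_hz = f[pk]),
            class = "peak_band")
}

#' Locate the fundamental peak band of a spectrum
#'
#' The fundamental is the lowest-frequency prominent local maximum, not the
#' global maximum: droplet passage produces sharp similarity dips whose
#' harmonics can rival the fundamental, but the droplet generation rate is
#' always the lowest line of the family. A peak qualifies when its power
#' reaches `prominence_frac` of the global maximum and stands at least
#' `min_snr` times above the median spectral power (the broadband noise
#' floor); a flat noise spectrum therefore yields a no-peak error rather than
#' a spurious detection. The band is the contiguous run of bins around the
#' peak with at least half its power (FWHM), capped at +/-5% of the peak
#' frequency, minimum one bin.
#'
#' @param spectrum An `auto_spectrum`.
#' @param prominence_frac Minimum peak power as a fraction of the global
#'   maximum (default 0.5).
#' @param max_extent_frac Band cap as a fraction of the peak frequency
#'   (default 0.05).
#' @param min_snr Minimum peak-to-median power ratio (default 50).
#' @return A `peak_band` with bin indices `lo`, `hi`, `peak` and their
#'   frequencies.
#' @export
find_fundamental_band <- function(spectrum, prominence_frac = 0.5,
                                  max_extent_frac = 0.05, min_snr = 50) {
  if (!inherits(spectrum, "auto_spectrum")) stop_parameter("not an auto_spectrum")
  if (spectrum$degenerate) {
    stop_no_peak("degenerate spectrum: the similarity vector is constant (no oscillation)")
  }
  qual <- .qualifying_peaks(spectrum, prominence_frac, min_snr)
  if (length(qual) == 0L) {
    stop_no_peak("no prominent spectral peak found")
  }
  .fwhm_band(spectrum, min(qual), max_extent_frac)
}

# Zoomed periodogram: direct DFT of the stored signal on a fine local grid.
# Used to refine the band centroid below the natural bin spacing.
.zoom_periodogram <- function(x, frame_rate, f_lo, f_hi, step, max_pts = 1537L) {
  npts <- floor((f_hi - f_lo) / step) + 1L
  if (npts > max_pts) {
    step <- (f_hi - f_lo) / (max_pts - 1L)
    npts <- max_pts
  }
  fg <- f_lo + step * (0:(npts - 1L))
  n <- length(x)
  ph <- outer(0:(n - 1L), fg) * (-2i * pi / frame_rate)
  X <- as.vector(x %*% exp(ph))
  list(freqs = fg, power = Mod(X)^2 * (2 / n))
}

# weighted first/second moments of power over a band
.band_moments <- function(f, p) {
  tot <- sum(p)
  ctr <- sum(f * p) / tot
  sd <- sqrt(sum(p * (f - ctr)^2) / tot)
  list(centroid = ctr, sd = sd)
}

#' Convert a fundamental band into a frequency estimate
#'
#' The mean frequency is the power-weighted centroid of the band and the
#' frequency CV is the power-weighted standard deviation over the centroid
#' (in percent): a pure tone concentrated in one bin gives CV = 0, while a
#' drifting or disturbed process spreads power across the band and inflates
#' the CV. When the spectrum carries its source signal, the centroid and
#' width are refined on a locally zoomed DFT grid (spacing `delta_f /
#' refine_oversample`) spanning the band, which removes most of the
#' bin-quantization error of the natural grid; hand-constructed spectra are
#' estimated on the natural grid.
#'
#' @param spectrum An `auto_spectrum`.
#' @param band A `peak_band` from [find_fundamental_band()], or a numeric
#'   `c(lo_hz, hi_hz)` frequency range to integrate over; found automatically
#'   when `NULL`.
#' @param refine Refine the centroid on a zoomed local grid when the source
#'   signal is available (default `TRUE`).
#' @param refine_oversample Fine-grid oversampling factor (default 32).
#' @param ... Passed to [find_fundamental_band()] when `band` is `NULL`.
#' @return An object of class `frequency_estimate` with `mean_freq` (Hz),
#'   `cv_percent`, `sigma_f` (Hz), `peak_freq` (Hz, maximum-power bin of the
#'   natural grid), `peak_band` (Hz bounds), `peak_power`, `delta_f`,
#'   `n_frames`, `frame_rate`, `provisional`.
#' @export
estimate_frequency <- function(spectrum, band = NULL, refine = TRUE,
                               refine_oversample = 32L, ...) {
  if (!inherits(spectrum, "auto_spectrum")) stop_parameter("not an auto_spectrum")
  if (is.null(band)) band <- find_fundamental_band(spectrum, ...)
  if (is.numeric(band)) {
    if (length(band) != 2L || band[2] < band[1]) {
      stop_parameter("a numeric band must be c(lo_hz, hi_hz)")
    }
    sel <- which(spectrum$freqs >= band[1] & spectrum$freqs <= band[2])
    if (length(sel) == 0L) stop_no_peak("no spectral bins inside the band")
    band <- structure(list(lo = min(sel), hi = max(sel),
                           peak = sel[which.max(spectrum$power[sel])],
                           lo_hz = spectrum$freqs[min(sel)],
                           hi_hz = spectrum$freqs[max(sel)],
                           peak_hz = spectrum$freqs[sel[which.max(spectrum$power[sel])]]),
                      class = "peak_band")
  }
  idx <- band$lo:band$hi
  p <- spectrum$power[idx]
  f <- spectrum$freqs[idx]
  if (sum(p) <= 0) stop_no_peak("zero power in the fundamental band")
  mom <- .band_moments(f, p)
  if (refine && !is.null(spectrum$signal)) {
    df <- spectrum$delta_f
    f_lo <- max(spectrum$freqs[band$lo] - df, df / 4)
    f_hi <- min(spectrum$freqs[band$hi] + df, spectrum$frame_rate / 2)
    zp <- .zoom_periodogram(spectrum$signal, spectrum$frame_rate,
                            f_lo, f_hi, df / refine_oversample)
    im <- which.max(zp$power)
    half <- zp$power[im] / 2
    fmin <- zp$freqs[im] * 0.95
    fmax <- zp$freqs[im] * 1.05
    lo <- im
    while (lo > 1L && zp$power[lo - 1L] >= half && zp$freqs[lo - 1L] >= fmin) lo <- lo - 1L
    hi <- im
    while (hi < length(zp$power) && zp$power[hi + 1L] >= half && zp$freqs[hi + 1L] <= fmax) hi <- hi + 1L
    mom <- .band_moments(zp$freqs[lo:hi], zp$power[lo:hi])
  }
  f_star <- spectrum$freqs[band$peak]
  if (f_star > 0.4 * spectrum$frame_rate) {
    warn_aliasing(sprintf(
      "fundamental at %.4g Hz is above 0.4x the frame rate (%.4g fps): likely undersampled (acquisition rule: frame rate > 5x droplet frequency)",
      f_star, spectrum$frame_rate))
  }
  structure(list(
    mean_freq = mom$centroid,
    cv_percent = 100 * mom$sd / mom$centroid,
    sigma_f = mom$sd,
    peak_freq = f_star,
    peak_band = c(max(spectrum$freqs[band$lo] - spectrum$delta_f / 2, 0),
                  spectrum$freqs[band$hi] + spectrum$delta_f / 2),
    peak_power = spectrum$power[band$peak],
    delta_f = spectrum$delta_f,
    n_frames = spectrum$n_frames,
    frame_rate = spectrum$frame_rate,
    provisional = FALSE
  ), class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf(
    "<frequency_estimate> mean %.4f Hz, CV %.4f%%, peak bin %.4f Hz, delta_f %.4g Hz (%d frames @ %.6g fps)%s\n",
    x$mean_freq, x$cv_percent, x$peak_freq, x$delta_f, x$n_frames,
    x$frame_rate, if (isTRUE(x$provisional)) " [provisional: buffer filling]" else ""))
  invisible(x)
}

#' Detect multiple fundamental frequencies in one spectrum
#'
#' Parallel microfluidic channels with non-overlapping generation frequencies
#' each contribute their own oscillation to the similarity vector, so one
#' spectrum of a composite clip carries one fundamental (plus harmonics) per
#' channel. All prominent local maxima are collected; any peak lying within
#' `harmonic_tol` (relative) of an integer multiple (2x..6x) of an already
#' accepted lower fundamental is grouped with it as a harmonic, so reported
#' fundamentals are never near-multiples of each other. Each surviving
#' fundamental receives its own band, truncated halfway to its neighbours so
#' bands stay disjoint, and its own [estimate_frequency()] fit.
#'
#' @param spectrum An `auto_spectrum`.
#' @param max_channels Maximum number of fundamentals to report; if more
#'   qualify, the strongest are kept.
#' @param prominence_frac Minimum peak power as a fraction of the global
#'   maximum (default 0.5; lower it for composites whose channels differ in
#'   apparent area and hence spectral power).
#' @param harmonic_tol Relative tolerance for harmonic grouping (default 0.02).
#' @param min_snr Minimum peak-to-median power ratio (default 50).
#' @param refine Passed to [estimate_frequency()].
#' @return An object of class `multichannel_estimate`: a list with `channels`
#'   (one `frequency_estimate` per fundamental, ascending in frequency) and
#'   `n_channels`.
#' @export
detect_fundamentals <- function(spectrum, max_channels = 3L,
                                prominence_frac = 0.5, harmonic_tol = 0.02,
                                min_snr = 50, refine = TRUE) {
  if (!inherits(spectrum, "auto_spectrum")) stop_parameter("not an auto_spectrum")
  if (max_channels < 1L) stop_parameter("'max_channels' must be >= 1")
  if (spectrum$degenerate) {
    stop_no_peak("degenerate spectrum: the similarity vector is constant (no oscillation)")
  }
  qual <- .qualifying_peaks(spectrum, prominence_frac, min_snr)
  if (length(qual) == 0L) stop_no_peak("no prominent spectral peak found")
  qual <- qual[order(spectrum$freqs[qual])]
  fq <- spectrum$freqs[qual]
  accepted <- integer(0)
  for (j in seq_along(qual)) {
    is_harm <- FALSE
    for (g in accepted) {
      ratio <- fq[j] / spectrum$freqs[g]
      k <- round(ratio)
      if (k >= 2 && k <= 6 && abs(ratio - k) <= harmonic_tol * k) {
        is_harm <- TRUE
        break
      }
    }
    if (!is_harm) accepted <- c(accepted, qual[j])
  }
  if (length(accepted) > max_channels) {
    keep <- order(spectrum$power[accepted], decreasing = TRUE)[seq_len(max_channels)]
    accepted <- sort(accepted[keep])
  }
  # disjoint bands: truncate each at the midpoint to its neighbours
  bounds_lo <- c(2L, floor((accepted[-1] + accepted[-length(accepted)]) / 2) + 1L)
  bounds_hi <- c(floor((accepted[-1] + accepted[-length(accepted)]) / 2),
                 length(spectrum$power))
  channels <- vector("list", length(accepted))
  for (j in seq_along(accepted)) {
    bd <- .fwhm_band(spectrum, accepted[j],
                     lo_cap = bounds_lo[j], hi_cap = bounds_hi[j])
    channels[[j]] <- estimate_frequency(spectrum, bd, refine = refine)
  }
  structure(list(channels = channels, n_channels = length(channels)),
            class = "multichannel_estimate")
}

#' @export
print.multichannel_estimate <- function(x, ...) {
  cat(sprintf("<multichannel_estimate> %d channel(s)\n", x$n_channels))
  for (ch in x$channels) {
    cat(sprintf("  mean %.4f Hz, CV %.4f%%, peak bin %.4f Hz\n",
                ch$mean_freq, ch$cv_percent, ch$peak_freq))
  }
  invisible(x)
}
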