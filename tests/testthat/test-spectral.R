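test_that("a pure tone concentrates power in its own frequency bin", {
  i <- 0:4999
  sv <- 0.9 + 0.05 * cos(2 * pi * 1200 * i / 10000)
  spec <- compute_auto_spectrum(sv, frame_rate = 10000)
  expect_equal(spec$delta_f, 2)
  expect_equal(spec$freqs[which.max(spec$power)], 1200)
  # dominant bin carries essentially all the oscillation power
  expect_gt(max(spec$power) / sum(spec$power), 0.999)
})

test_that("a constant similarity vector is flagged degenerate with no peak", {
  spec <- compute_auto_spectrum(rep(0.97, 64), frame_rate = 1000)
  expect_true(spec$degenerate)
  expect_lt(max(spec$power), 1e-20)
  expect_error(find_fundamental_band(spec), class = "dropfreq_no_peak_error")
})

test_that("one-sided power obeys Parseval: total equals n times the variance", {
  set.seed(3)
  for (n in c(64, 101, 500)) {
    x <- runif(n)
    spec <- compute_auto_spectrum(x, frame_rate = 1000)
    v <- mean((x - mean(x))^2)
    expect_equal(sum(spec$power), n * v, tolerance = 1e-6)
    expect_identical(spec$power[1], 0)
  }
})

test_that("spectral resolution is frame_rate over n_frames", {
  x <- cos(2 * pi * 50 * (0:4999) / 2000)
  s5000 <- compute_auto_spectrum(x, frame_rate = 2000)
  s1000 <- compute_auto_spectrum(x[1:1000], frame_rate = 2000)
  expect_equal(s5000$delta_f, 2000 / 5000)
  expect_equal(s1000$delta_f / s5000$delta_f, 5)
  expect_error(compute_auto_spectrum(x[1:10], frame_rate = 2000),
               class = "dropfreq_insufficient_data_error")
})

test_that("band centroid and width reproduce hand-computed moments", {
  freqs <- seq(0, 2500, by = 2)
  power <- numeric(length(freqs))
  power[freqs == 1198] <- 1
  power[freqs == 1202] <- 1
  spec <- as_auto_spectrum(freqs, power, frame_rate = 10000)
  est <- estimate_frequency(spec, band = c(1190, 1210))
  expect_equal(est$mean_freq, 1200)
  expect_equal(est$sigma_f, 2)
  expect_equal(est$cv_percent, 100 * 2 / 1200, tolerance = 1e-12)

  # all power in one bin: zero width, zero CV
  power2 <- numeric(length(freqs))
  power2[freqs == 1200] <- 3
  est2 <- estimate_frequency(as_auto_spectrum(freqs, power2, 10000),
                             band = c(1190, 1210))
  expect_equal(est2$mean_freq, 1200)
  expect_equal(est2$cv_percent, 0)
})

test_that("the fundamental is the lowest prominent peak, not the strongest harmonic", {
  freqs <- seq(0, 2500, by = 2)
  power <- numeric(length(freqs))
  power[freqs == 400] <- 1.0
  power[freqs == 800] <- 0.6
  spec <- as_auto_spectrum(freqs, power, frame_rate = 5000)
  band <- find_fundamental_band(spec)
  expect_equal(band$peak_hz, 400)

  # prominence threshold: a sub-threshold low peak is skipped
  power[freqs == 200] <- 0.3
  band2 <- find_fundamental_band(as_auto_spectrum(freqs, power, 5000),
                                 prominence_frac = 0.5)
  expect_equal(band2$peak_hz, 400)
})

test_that("a flat noise spectrum yields a no-peak error", {
  set.seed(5)
  freqs <- seq(0, 1000, by = 1)
  power <- c(0, stats::rexp(1000))
  spec <- as_auto_spectrum(freqs, power, frame_rate = 2000)
  expect_error(find_fundamental_band(spec), class = "dropfreq_no_peak_error")
})

test_that("harmonic families collapse onto their fundamental", {
  freqs <- seq(0, 2500, by = 2)
  power <- numeric(length(freqs))
  power[freqs == 400] <- 1.0
  power[freqs == 800] <- 0.8
  power[freqs == 1200] <- 0.6
  mc <- detect_fundamentals(as_auto_spectrum(freqs, power, 5000),
                            max_channels = 3, prominence_frac = 0.3)
  expect_equal(mc$n_channels, 1)
  expect_equal(mc$channels[[1]]$peak_freq, 400)

  # three non-multiple peaks survive as three channels
  power2 <- numeric(length(freqs))
  power2[freqs == 410] <- 0.7
  power2[freqs == 1584] <- 1.0
  power2[freqs == 1920] <- 0.8
  mc2 <- detect_fundamentals(as_auto_spectrum(freqs, power2, 5000),
                             max_channels = 3, prominence_frac = 0.3)
  expect_equal(mc2$n_channels, 3)
  got <- vapply(mc2$channels, function(ch) ch$peak_freq, numeric(1))
  expect_equal(got, c(410, 1584, 1920))
  # reported fundamentals are never near-multiples of each other
  for (a in got) for (b in got) if (b > a) {
    r <- b / a
    expect_gt(abs(r - round(r)), 0.02 * round(r))
  }
})

test_that("a fundamental near the Nyquist rate triggers an aliasing warning", {
  freqs <- seq(0, 500, by = 1)
  power <- numeric(length(freqs))
  power[freqs == 450] <- 1
  spec <- as_auto_spectrum(freqs, power, frame_rate = 1000)
  expect_warning(estimate_frequency(spec, band = c(440, 460)),
                 class = "dropfreq_aliasing_warning")
})

test_that("estimates on real clips expose a consistent structure", {
  vid <- small_clip()
  est <- droplet_frequency(vid$stack)
  expect_s3_class(est, "frequency_estimate")
  expect_gt(est$mean_freq, 0)
  expect_lt(est$mean_freq, est$frame_rate / 2)
  expect_gte(est$cv_percent, 0)
  expect_true(est$peak_band[1] <= est$mean_freq &&
                est$mean_freq <= est$peak_band[2])
  expect_true(est$peak_band[1] <= est$peak_freq &&
                est$peak_freq <= est$peak_band[2])
  expect_equal(est$delta_f, 2000 / 600)
})
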