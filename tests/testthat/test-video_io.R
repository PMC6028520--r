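test_that("PNG frame directories round-trip 8-bit stacks exactly", {
  vid <- small_clip(n_frames = 24)
  q <- quantize_frames(vid$stack)
  dir <- file.path(tempdir(), "rt_png")
  write_video(q, dir)
  back <- read_video(dir, frame_rate = 2000)
  expect_identical(back$frames, q$frames)
  expect_equal(back$frame_rate, 2000)
  expect_equal(n_frames(back), 24)

  trunc <- read_video(dir, frame_rate = 2000, max_frames = 10)
  expect_equal(n_frames(trunc), 10)
  expect_identical(trunc$frames, q$frames[, , 1:10])
  unlink(dir, recursive = TRUE)
})

test_that("uncompressed AVI round-trips 8-bit stacks exactly", {
  vid <- small_clip(n_frames = 24)
  q <- quantize_frames(vid$stack)
  path <- file.path(tempdir(), "rt.avi")
  write_video(q, path)
  back <- read_video(path, frame_rate = 2000)
  expect_identical(back$frames, q$frames)
  expect_equal(n_frames(read_video(path, frame_rate = 2000, max_frames = 7)), 7)
  unlink(path)
})

test_that("the round-tripped clip yields an identical similarity vector", {
  vid <- small_clip(n_frames = 60)
  q <- quantize_frames(vid$stack)
  path <- file.path(tempdir(), "rt2.avi")
  write_video(q, path)
  back <- read_video(path, frame_rate = 2000)
  expect_identical(build_similarity_vector(back)$similarities,
                   build_similarity_vector(q)$similarities)
  unlink(path)
})

test_that("colour frames are converted with luma weights; grayscale passes through", {
  dir <- file.path(tempdir(), "rgb_frames")
  dir.create(dir, showWarnings = FALSE)
  set.seed(15)
  rgb <- array(round(runif(6 * 8 * 3) * 255) / 255, dim = c(6, 8, 3))
  for (i in 1:2) {
    png::writePNG(rgb, file.path(dir, sprintf("f%d.png", i)))
  }
  stack <- read_video(dir, frame_rate = 100)
  expected <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  expect_equal(stack$frames[, , 1], expected, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("unreadable inputs and mixed resolutions raise classed errors", {
  expect_error(read_video(file.path(tempdir(), "nope_dir_xyz"), 100),
               class = "dropfreq_io_error")
  dir <- file.path(tempdir(), "mixed_frames")
  dir.create(dir, showWarnings = FALSE)
  png::writePNG(matrix(0.5, 4, 6), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 4, 7), file.path(dir, "b.png"))
  expect_error(read_video(dir, 100), class = "dropfreq_dimension_error")
  unlink(dir, recursive = TRUE)

  empty <- file.path(tempdir(), "empty_frames")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_video(empty, 100), class = "dropfreq_io_error")
  unlink(empty, recursive = TRUE)

  txt <- file.path(tempdir(), "not_video.txt")
  writeLines("x", txt)
  expect_error(read_video(txt, 100), class = "dropfreq_io_error")
  expect_error(read_avi(txt, 100), class = "dropfreq_io_error")
  unlink(txt)
})

test_that("reports serialize with the canonical schema and round-trip numerically", {
  vid <- small_clip()
  est <- droplet_frequency(vid$stack)
  csv <- file.path(tempdir(), "est.csv")
  write_report(est, csv, "csv")
  df <- read.csv(csv)
  expect_identical(names(df), c("window_start_s", "window_end_s",
                                "mean_freq_hz", "cv_percent", "peak_power",
                                "n_frames"))
  expect_equal(nrow(df), 1)
  expect_equal(df$mean_freq_hz, est$mean_freq, tolerance = 1e-9)
  expect_equal(df$window_end_s, 0.3)

  rep3 <- monitor_process(vid$stack, window_frames = 200)
  write_report(rep3, csv, "csv")
  df3 <- read.csv(csv)
  expect_equal(nrow(df3), 3)
  expect_true(all(diff(df3$window_start_s) > 0))
  src <- report_frame(rep3)
  expect_equal(df3$mean_freq_hz, src$mean_freq_hz, tolerance = 1e-9)
  expect_equal(df3$cv_percent, src$cv_percent, tolerance = 1e-9)

  js <- file.path(tempdir(), "est.json")
  write_report(est, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$mean_freq_hz, est$mean_freq, tolerance = 1e-9)

  expect_error(write_report(est, csv, "xml"),
               class = "dropfreq_parameter_error")
  unlink(c(csv, js))
})
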