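test_that("stream initialization enforces its preconditions", {
  ref <- matrix(runif(24) + 0.1, 4, 6)
  expect_error(init_stream(ref, capacity = 8, frame_rate = 100),
               class = "dropfreq_parameter_error")
  expect_error(init_stream(matrix(0, 4, 6), capacity = 32, frame_rate = 100),
               class = "dropfreq_zero_vector_error")
  st <- init_stream(ref, capacity = 32, frame_rate = 100)
  expect_equal(stream_phase(st), "build_up")
  expect_error(stream_estimate(st),
               class = "dropfreq_insufficient_data_error")
  expect_error(push_frame(st, matrix(1, 4, 7)),
               class = "dropfreq_dimension_error")
})

test_that("the phase flips to real_time exactly when the buffer first fills", {
  vid <- small_clip(n_frames = 40)
  st <- init_stream(get_frame(vid$stack, 1), capacity = 32, frame_rate = 2000)
  for (i in 1:31) push_frame(st, get_frame(vid$stack, i))
  expect_equal(stream_phase(st), "build_up")
  push_frame(st, get_frame(vid$stack, 32))
  expect_equal(stream_phase(st), "real_time")
  expect_equal(st$count, 32L)
})

test_that("pushing past capacity evicts exactly the oldest entries", {
  vid <- small_clip(n_frames = 40)
  ref <- get_frame(vid$stack, 1)
  st <- init_stream(ref, capacity = 32, frame_rate = 2000)
  for (i in 1:33) push_frame(st, get_frame(vid$stack, i))
  expect_equal(st$count, 32L)
  # buffer must equal the batch similarities of frames 2..33 vs the fixed ref
  batch <- vapply(2:33, function(i)
    cosine_similarity(as.vector(get_frame(vid$stack, i)), as.vector(ref)),
    numeric(1))
  expect_identical(stream_similarities(st), batch)
})

test_that("pushing the reference frame itself appends similarity 1", {
  vid <- small_clip(n_frames = 40)
  ref <- get_frame(vid$stack, 5)
  st <- init_stream(ref, capacity = 32, frame_rate = 2000)
  push_frame(st, ref)
  expect_equal(stream_similarities(st), 1, tolerance = 1e-12)
})

test_that("streaming reproduces the batch estimate bit for bit", {
  vid <- small_clip()
  st <- init_stream(get_frame(vid$stack, 1), capacity = 1024, frame_rate = 2000)
  for (i in seq_len(n_frames(vid$stack))) {
    push_frame(st, get_frame(vid$stack, i))
  }
  expect_identical(stream_similarities(st),
                   build_similarity_vector(vid$stack)$similarities)
  se <- stream_estimate(st)
  be <- droplet_frequency(vid$stack)
  expect_identical(se$mean_freq, be$mean_freq)
  expect_identical(se$cv_percent, be$cv_percent)
  expect_identical(se$peak_freq, be$peak_freq)
  expect_true(se$provisional)  # 600 of 1024 frames buffered
  expect_equal(se$delta_f, 2000 / 600)
})

test_that("per-push similarity cost is a fixed number of pixel operations", {
  vid <- small_clip(n_frames = 40)
  st <- init_stream(get_frame(vid$stack, 1), capacity = 16, frame_rate = 2000)
  ops <- numeric(30)
  for (i in 1:30) {
    push_frame(st, get_frame(vid$stack, i))
    ops[i] <- st$last_push_ops
  }
  expect_true(all(ops == 2 * prod(frame_dim(vid$stack))))
})

test_that("re-referencing recomputes buffered similarities against the new frame", {
  vid <- small_clip(n_frames = 40)
  st <- init_stream(get_frame(vid$stack, 1), capacity = 32, frame_rate = 2000)
  for (i in 1:20) push_frame(st, get_frame(vid$stack, i))
  reref_stream(st)  # latest pushed frame becomes the reference
  newref <- as.vector(get_frame(vid$stack, 20))
  batch <- vapply(1:20, function(i)
    cosine_similarity(as.vector(get_frame(vid$stack, i)), newref), numeric(1))
  expect_identical(stream_similarities(st), batch)
  expect_equal(stream_similarities(st)[20], 1, tolerance = 1e-12)
})

test_that("monitoring a stationary process gives window means within one bin", {
  vid <- small_clip()
  rep <- monitor_process(vid$stack, window_frames = 200)
  expect_equal(length(rep$estimates), 3)
  means <- vapply(rep$estimates, function(e) e$mean_freq, numeric(1))
  expect_lt(max(means) - min(means), 2000 / 200)
  expect_equal(rep$window_start_s, c(0, 0.1, 0.2))
  expect_error(monitor_process(vid$stack, window_frames = 10000),
               class = "dropfreq_insufficient_data_error")
  expect_error(monitor_process(vid$stack, window_frames = 8),
               class = "dropfreq_parameter_error")
})

test_that("window means track a frequency schedule and flag the transition by CV", {
  # three windows of 0.5 s; the rate ramps 100 -> 110 Hz across window 2,
  # so the disturbance spans that whole window (as when monitoring at an
  # interval shorter than the disturbance)
  sch <- data.frame(start = c(0, 0.5), end = c(0.5, 1.5), freq = c(100, 110))
  vid <- generate_video(small_cfg(frequency_schedule = sch, n_frames = 3000,
                                  transition_s = 0.5, seed = 17))
  rep <- monitor_process(vid$stack, window_frames = 1000)
  means <- vapply(rep$estimates, function(e) e$mean_freq, numeric(1))
  cvs <- vapply(rep$estimates, function(e) e$cv_percent, numeric(1))
  expect_lt(abs(means[1] - 100), 2)
  expect_lt(abs(means[3] - 110), 2)
  expect_true(means[2] > means[1] && means[2] < means[3])
  # the disturbed window shows a several-fold CV elevation
  expect_gt(cvs[2], 3 * max(cvs[1], cvs[3]))
})

test_that("an iterator stream is equivalent to the in-memory stack", {
  vid <- small_clip(n_frames = 200)
  i <- 0L
  it <- function() {
    i <<- i + 1L
    if (i > n_frames(vid$stack)) NULL else get_frame(vid$stack, i)
  }
  rep_it <- monitor_process(it, window_frames = 100, frame_rate = 2000)
  rep_st <- monitor_process(vid$stack, window_frames = 100)
  expect_identical(report_frame(rep_it), report_frame(rep_st))
})
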