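test_that("threshold filtering is inclusive and order-preserving", {
  preds <- make_predictions(c(0.49, 0.50, 0.51))
  kept <- filter_predictions(preds, 0.5)
  expect_equal(kept$p_fish, c(0.50, 0.51))
  expect_equal(nrow(filter_predictions(preds, 0)), 3L)
  expect_equal(nrow(filter_predictions(preds[0, ], 0.5)), 0L)
  # NA scores count as below threshold
  preds$p_fish[2] <- NA
  expect_equal(filter_predictions(preds, 0.5)$p_fish, 0.51)
  # unordered input is the caller's bug
  shuffled <- preds[c(2, 1, 3), ]
  expect_error(filter_predictions(shuffled, 0.5),
               class = "fishclip_argument_error")
  expect_error(filter_predictions(preds, 1.5),
               class = "fishclip_argument_error")
})

test_that("adjacent positives group into maximal per-video runs", {
  p <- rep(0.1, 10)
  p[c(3, 4, 5, 9)] <- 0.9
  events <- group_adjacent(filter_predictions(make_predictions(p), 0.5))
  expect_equal(nrow(events), 2L)
  expect_equal(events$member_samples[[1]], c(3L, 4L, 5L))
  expect_equal(events$member_samples[[2]], 9L)
  expect_equal(events$group_id, c(1L, 2L))
  expect_equal(events$start_frame, c(801L, 3201L))  # (i-1)*400+1
  expect_equal(events$end_frame, c(1601L, 3201L))
})

test_that("runs never bridge video files and group ids restart per video", {
  a <- make_predictions(c(0.1, 0.9), video_path = "a.tif")
  b <- make_predictions(c(0.9, 0.1), video_path = "b.tif")
  b$global_order <- b$global_order + 2L
  preds <- rbind(a, b)
  # last sample of a and first of b are positive: still two events
  events <- group_adjacent(filter_predictions(preds, 0.5))
  expect_equal(nrow(events), 2L)
  expect_equal(events$video_path, c("a.tif", "b.tif"))
  expect_equal(events$group_id, c(1L, 1L))
  expect_equal(nrow(group_adjacent(preds[0, ])), 0L)
  dup <- rbind(a, a)
  expect_error(group_adjacent(dup), class = "fishclip_data_error")
})

test_that("grouping matches the brute-force run-length oracle on random streams", {
  set.seed(101)
  for (i in 1:300) {
    n_videos <- sample(1:3, 1)
    preds <- do.call(rbind, lapply(seq_len(n_videos), function(v) {
      n <- sample(1:40, 1)
      make_predictions(stats::runif(n), video_path = sprintf("v%d.tif", v))
    }))
    preds$global_order <- seq_len(nrow(preds))
    kept <- filter_predictions(preds, 0.5)
    events <- group_adjacent(kept)
    oracle <- rle_oracle(kept$video_path, kept$sample_index)
    expect_equal(nrow(events), nrow(oracle))
    if (nrow(events)) {
      expect_equal(events$first_sample, oracle$first_sample)
      expect_equal(events$last_sample, oracle$last_sample)
      expect_equal(events$video_path, oracle$video_path)
      # membership: consecutive integers spanning the run
      for (j in seq_len(nrow(events))) {
        expect_equal(events$member_samples[[j]],
                     seq(oracle$first_sample[j], oracle$last_sample[j]))
      }
    }
  }
})

test_that("event count equals kept samples without an adjacent predecessor", {
  set.seed(55)
  for (i in 1:50) {
    preds <- make_predictions(stats::runif(60))
    kept <- filter_predictions(preds, 0.5)
    events <- group_adjacent(kept)
    starts <- sum(!(kept$sample_index - 1L) %in% kept$sample_index)
    expect_equal(nrow(events), starts)
  }
})

test_that("raising the threshold shrinks membership and never merges events", {
  set.seed(77)
  for (i in 1:30) {
    preds <- make_predictions(stats::runif(50))
    lo <- group_adjacent(filter_predictions(preds, 0.3))
    hi <- group_adjacent(filter_predictions(preds, 0.7))
    expect_lte(sum(hi$n_samples), sum(lo$n_samples))
    # every high-threshold event lies inside exactly one low-threshold event
    if (nrow(hi)) {
      containing <- vapply(seq_len(nrow(hi)), function(j) {
        sum(lo$first_sample <= hi$first_sample[j] &
              lo$last_sample >= hi$last_sample[j])
      }, integer(1))
      expect_true(all(containing == 1L))
    }
  }
})

test_that("buffering pads by round(buffer_s * fps) frames and clamps to bounds", {
  # the canonical configuration: 20 s at 20 fps = 400 frames each side
  preds <- make_predictions(c(rep(0.1, 12), 0.9, 0.9, rep(0.1, 6)))
  events <- group_adjacent(filter_predictions(preds, 0.5))
  buffered <- buffer_and_clamp(events, segmentation_config(buffer_s = 20))
  expect_equal(events$start_frame - buffered$buffered_start, 400L)
  expect_equal(buffered$buffered_end - events$end_frame, 400L)

  # both clamps active on a short video
  short <- make_predictions(c(0.9, 0.1))
  ev <- group_adjacent(filter_predictions(short, 0.5))
  ev$total_frames <- 500L
  ev$start_frame <- 100L; ev$end_frame <- 100L
  b <- buffer_and_clamp(ev, segmentation_config(buffer_s = 20))
  expect_equal(c(b$buffered_start, b$buffered_end), c(1L, 500L))

  # plain arithmetic away from the edges, checked against scalar math
  ev$total_frames <- 100000L; ev$start_frame <- 5000L; ev$end_frame <- 5400L
  b <- buffer_and_clamp(ev, segmentation_config(buffer_s = 20))
  expect_equal(c(b$buffered_start, b$buffered_end), c(4600L, 5800L))

  # buffer converts through each video's own fps
  ev$fps <- 25
  b <- buffer_and_clamp(ev, segmentation_config(buffer_s = 20))
  expect_equal(ev$start_frame - b$buffered_start, 500L)
})

test_that("clamp safety holds for random event layouts", {
  set.seed(202)
  for (i in 1:50) {
    preds <- make_predictions(stats::runif(sample(2:50, 1)))
    events <- detect_events(preds, segmentation_config(
      threshold = 0.5, buffer_s = stats::runif(1, 0, 60)))
    if (nrow(events)) {
      expect_true(all(events$buffered_start >= 1L))
      expect_true(all(events$buffered_start <= events$start_frame))
      expect_true(all(events$buffered_end >= events$end_frame))
      expect_true(all(events$buffered_end <= events$total_frames))
    }
  }
})

test_that("planted runs are recovered exactly, with no spurious events", {
  stream <- generate_probability_stream(stream_config(
    n_videos = 1, samples_per_video = 12,
    planted_runs = list(list(c(3, 3, 0.9), c(9, 1, 0.9))), seed = 7))
  events <- detect_events(stream$predictions)
  expect_equal(nrow(events), 2L)
  expect_equal(events$first_sample, stream$truth$first_sample)
  expect_equal(events$last_sample, stream$truth$last_sample)
  expect_equal(events$start_frame, stream$truth$start_frame)
  expect_equal(events$end_frame, stream$truth$end_frame)
})

test_that("segment requests and clips follow buffered events", {
  dir <- withr::local_tempdir()
  scene <- render_test_scene(dir, duration_s = 30, fps = 20,
                             fish_intervals = list(c(10, 14)))
  meta <- probe_video(scene$path)
  manifest <- thin_video(meta, interval_s = 2,
                         out_dir = file.path(dir, "stills"))
  manifest$global_order <- seq_len(nrow(manifest))
  preds <- predict_batch(mock_predictor(), manifest)
  events <- detect_events(preds, segmentation_config(buffer_s = 4))
  expect_equal(nrow(events), 1L)

  out <- write_event_clips(events, file.path(dir, "clips"),
                           videos = setNames(list(meta), meta$path))
  expect_equal(nrow(out), 1L)
  expect_true(file.exists(out$clip_path))
  expect_equal(decode_frame_count(out$clip_path),
               events$buffered_end - events$buffered_start + 1L)

  # zero events is a success with an empty manifest
  none <- detect_events(make_predictions(rep(0.1, 5)))
  out0 <- write_event_clips(none, file.path(dir, "clips0"))
  expect_equal(nrow(out0), 0L)
})
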