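test_that("probing a rendered video recovers its frame count and fps", {
  dir <- withr::local_tempdir()
  scene <- render_test_scene(dir, duration_s = 10, fps = 20)
  meta <- probe_video(scene$path)
  expect_s3_class(meta, "video_meta")
  expect_equal(meta$total_frames, 200L)
  expect_equal(meta$fps, 20)
  # independent decode agrees with the probe
  expect_equal(decode_frame_count(scene$path), 200L)
})

test_that("probe handles the degenerate 1-frame video and rejects non-video files", {
  dir <- withr::local_tempdir()
  one <- render_test_scene(dir, duration_s = 0.05, fps = 20, name = "one.tif")
  expect_equal(probe_video(one$path)$total_frames, 1L)

  txt <- file.path(dir, "not_a_video.tif")
  writeLines("plain text", txt)
  expect_error(probe_video(txt), class = "fishclip_io_error")
  expect_error(probe_video(file.path(dir, "absent.tif")),
               class = "fishclip_io_error")
})

test_that("probing an ordinary container degrades cleanly by toolchain", {
  dir <- withr::local_tempdir()
  fake <- file.path(dir, "clip.mp4")
  writeBin(as.raw(1:16), fake)
  if (nzchar(Sys.which("ffprobe"))) {
    # a 16-byte junk file is not decodable: expect a probe I/O error
    expect_error(probe_video(fake), class = "fishclip_io_error")
  } else {
    expect_error(probe_video(fake), class = "fishclip_capability_error")
  }
})

test_that("chronological keys order by filename timestamp with path tie-break", {
  paths <- c("b/cam_20230726_060000.tif", "a/cam_20230726_050000.tif",
             "z/cam_2023-07-25_23-59-59.tif", "nostamp.tif")
  keys <- chrono_key_for(paths)
  expect_equal(paths[order(keys)],
               c("nostamp.tif", "z/cam_2023-07-25_23-59-59.tif",
                 "a/cam_20230726_050000.tif", "b/cam_20230726_060000.tif"))
  # ties on identical timestamps break lexicographically by path
  tied <- c("b/cam_20230726_050000.tif", "a/cam_20230726_050000.tif")
  expect_equal(order(chrono_key_for(tied)), c(2L, 1L))
})

test_that("sample-to-frame mapping anchors each interval at its first frame", {
  expect_equal(frame_number_for_sample(1, 20, 20), 1L)
  expect_equal(frame_number_for_sample(2, 20, 20), 401L)
  expect_equal(frame_number_for_sample(10, 20, 20), 3601L)
  # non-integer stride rounds to the nearest whole frame
  expect_equal(frame_number_for_sample(2, 1.5, 29.97), 46L)
  expect_error(frame_number_for_sample(0, 20, 20),
               class = "fishclip_argument_error")
  expect_error(frame_number_for_sample(1, -1, 20),
               class = "fishclip_argument_error")
})

test_that("thinned sample count follows the closed form across random regimes", {
  expect_equal(n_thinned_samples(1200, 20, 20), 3L)   # 60 s @ 20 fps
  expect_equal(n_thinned_samples(1152000, 20, 20), 2880L)  # a 16-h day
  expect_equal(n_thinned_samples(100, 20, 20), 1L)    # interval > video
  set.seed(42)
  for (i in 1:200) {
    fps <- sample(c(10, 20, 25, 29.97, 30), 1)
    interval <- runif(1, 0.5, 40)
    total <- sample.int(5000, 1)
    stride <- max(1, round(interval * fps))
    # oracle: enumerate the emitted frame numbers directly
    frames <- seq(1, total, by = stride)
    expect_equal(n_thinned_samples(total, fps, interval), length(frames))
    got <- frame_number_for_sample(seq_along(frames), interval, fps)
    expect_identical(as.integer(frames), got)
    expect_true(all(diff(got) > 0) && max(got) <= total)
  }
})

test_that("thin_video writes one correct still per interval", {
  dir <- withr::local_tempdir()
  scene <- render_test_scene(dir, duration_s = 60, fps = 20,
                             fish_intervals = list(c(18, 25)))
  meta <- probe_video(scene$path)
  manifest <- thin_video(meta, interval_s = 20,
                         out_dir = file.path(dir, "stills"))
  expect_equal(nrow(manifest), 3L)
  expect_equal(manifest$frame_number, c(1L, 401L, 801L))
  expect_true(all(file.exists(manifest$image_path)))
  # stills are lossless: pixel content equals the decoded source frame
  src <- tiff::readTIFF(scene$path, all = manifest$frame_number)
  for (i in seq_len(nrow(manifest))) {
    still <- png::readPNG(manifest$image_path[i])
    expect_lt(max(abs(still - src[[i]])), 1 / 255)
  }
})

test_that("a video shorter than the interval yields exactly its first frame", {
  dir <- withr::local_tempdir()
  scene <- render_test_scene(dir, duration_s = 5, fps = 20, name = "short.tif")
  manifest <- thin_video(probe_video(scene$path), interval_s = 20,
                         out_dir = file.path(dir, "stills"))
  expect_equal(nrow(manifest), 1L)
  expect_equal(manifest$frame_number, 1L)
  expect_error(thin_video(probe_video(scene$path), interval_s = 0,
                          out_dir = dir),
               class = "fishclip_argument_error")
})

test_that("batch thinning assigns global order across chronologically sorted videos", {
  dir <- withr::local_tempdir()
  late <- render_test_scene(dir, duration_s = 4, seed = 2,
                            name = "cam_20230726_070000.tif")
  early <- render_test_scene(dir, duration_s = 4, seed = 3,
                             name = "cam_20230726_050000.tif")
  manifest <- thin_videos(c(late$path, early$path), interval_s = 2,
                          out_dir = file.path(dir, "stills"))
  expect_equal(manifest$global_order, seq_len(nrow(manifest)))
  # the earlier recording comes first regardless of argument order
  expect_equal(unique(manifest$video_path), c(early$path, late$path))
})

test_that("write_segment cuts frame-exact clips from frame stacks", {
  dir <- withr::local_tempdir()
  scene <- render_test_scene(dir, duration_s = 10, fps = 20)
  meta <- probe_video(scene$path)

  clip <- file.path(dir, "clip.tif")
  write_segment(segment_request(meta, 41, 120, clip))
  expect_equal(decode_frame_count(clip), 80L)
  # clip content corresponds to source frames [41, 120]
  expect_equal(tiff::readTIFF(clip, all = 1)[[1]],
               tiff::readTIFF(scene$path, all = 41)[[1]])
  expect_equal(probe_video(clip)$fps, 20)

  whole <- file.path(dir, "whole.tif")
  write_segment(segment_request(meta, 1, meta$total_frames, whole))
  expect_equal(decode_frame_count(whole), meta$total_frames)

  single <- file.path(dir, "one.tif")
  write_segment(segment_request(meta, 5, 5, single))
  expect_equal(decode_frame_count(single), 1L)
})

test_that("segment requests outside video bounds are rejected, not clamped", {
  dir <- withr::local_tempdir()
  meta <- probe_video(render_test_scene(dir, duration_s = 2)$path)
  expect_error(segment_request(meta, 0, 10, "x.tif"),
               class = "fishclip_argument_error")
  expect_error(segment_request(meta, 10, 5, "x.tif"),
               class = "fishclip_argument_error")
  expect_error(segment_request(meta, 1, meta$total_frames + 1, "x.tif"),
               class = "fishclip_argument_error")
})

test_that("manifest CSV round-trips and validates its columns", {
  dir <- withr::local_tempdir()
  m <- make_predictions(c(0.1, 0.9))
  p <- file.path(dir, "m.csv")
  write_manifest(m, p)
  back <- read_manifest(p)
  expect_equal(back$p_fish, m$p_fish)
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_manifest(bad), class = "fishclip_data_error")
})
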