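# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately written as naive element-by-element walks so they
# share no code path with the vectorised implementation they check.

# Brute-force run-length encoder over per-video positive sample indices.
# Returns a data.frame(video_path, first_sample, last_sample), one row per
# maximal run of consecutive indices, videos in first-appearance order.
rle_oracle <- function(video_path, sample_index) {
  out <- list()
  for (v in unique(video_path)) {
    idx <- sort(sample_index[video_path == v])
    if (!length(idx)) next
    run_start <- idx[1]
    prev <- idx[1]
    for (i in idx[-1]) {
      if (i - prev > 1) {  # not adjacent: close the run
        out[[length(out) + 1]] <- data.frame(
          video_path = v, first_sample = run_start, last_sample = prev,
          stringsAsFactors = FALSE)
        run_start <- i
      }
      prev <- i
    }
    out[[length(out) + 1]] <- data.frame(
      video_path = v, first_sample = run_start, last_sample = prev,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(video_path = character(0), first_sample = integer(0),
                      last_sample = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Minimal prediction frame for event tests: one video unless told otherwise.
make_predictions <- function(p_fish, video_path = "v1.tif", fps = 20,
                             interval_s = 20) {
  n <- length(p_fish)
  stride <- as.integer(round(interval_s * fps))
  data.frame(video_path = video_path, fps = fps,
             total_frames = n * stride, sample_index = seq_len(n),
             frame_number = (seq_len(n) - 1L) * stride + 1L,
             p_fish = p_fish, global_order = seq_len(n),
             stringsAsFactors = FALSE)
}

# A small rendered scene; cached per test file via the tmpdir it's given.
render_test_scene <- function(dir, duration_s = 10, fps = 20,
                              fish_intervals = list(), seed = 1,
                              name = "scene_20230726_120000.tif") {
  cfg <- scene_config(duration_s = duration_s, fps = fps,
                      fish_intervals = fish_intervals, seed = seed)
  path <- file.path(dir, name)
  res <- render_video(cfg, path)
  res$path <- path
  res
}

# Count frames of a frame-stack clip by an independent full decode (no
# sidecar, no fishclip probe involved).
decode_frame_count <- function(path) {
  length(tiff::readTIFF(path, all = TRUE))
}
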