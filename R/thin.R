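#' Map a thinned-sample index to its source frame number
#'
#' Thinning takes one still every `interval_s` seconds, anchored at the
#' first frame of each interval, so sample *i* comes from frame
#' `(i - 1) * round(interval_s * fps) + 1` (frames are 1-based throughout).
#' Non-integer `interval_s * fps` products are rounded to the nearest whole
#' frame stride (minimum 1) so frame numbers stay integral and strictly
#' increasing.
#'
#' @param sample_index 1-based sample index (vectorised).
#' @param interval_s Thinning interval in seconds.
#' @param fps Source frame rate.
#' @return Integer frame number(s).
#' @export
#' @examples
#' frame_number_for_sample(1:3, interval_s = 20, fps = 20)  # 1, 401, 801
frame_number_for_sample <- function(sample_index, interval_s, fps) {
  check_positive_scalar(interval_s, "interval_s")
  check_positive_scalar(fps, "fps")
  if (!is.numeric(sample_index) || any(!is.finite(sample_index)) ||
      any(sample_index < 1) || any(sample_index != as.integer(sample_index))) {
    abort_argument("`sample_index` must contain integers >= 1.")
  }
  stride <- frame_stride(interval_s, fps)
  as.integer(sample_index - 1L) * stride + 1L
}

frame_stride <- function(interval_s, fps) {
  max(1L, as.integer(round(interval_s * fps)))
}

#' Number of thinned samples a video yields
#'
#' Closed form for the sample count of [thin_video()]:
#' `floor((total_frames - 1) / stride) + 1` with
#' `stride = round(interval_s * fps)`. A video shorter than one interval
#' yields exactly one sample (its first frame).
#'
#' @inheritParams frame_number_for_sample
#' @param total_frames Total frames in the video.
#' @return Integer sample count, at least 1.
#' @export
n_thinned_samples <- function(total_frames, fps, interval_s) {
  check_positive_scalar(interval_s, "interval_s")
  check_positive_scalar(fps, "fps")
  total_frames <- check_count(total_frames, "total_frames")
  stride <- frame_stride(interval_s, fps)
  as.integer((total_frames - 1L) %/% stride) + 1L
}

#' Thin a video into interval-sampled stills
#'
#' Extracts one frame per `interval_s` seconds, starting at frame 1, and
#' writes each as a lossless PNG still named
#' `<video-stem>_s<sample_index>_f<frame_number>.png`. This is the data
#' reduction step that turns hours of footage into a classifiable image set.
#'
#' @param video A [video_meta()] object (from [probe_video()]).
#' @param interval_s Seconds between consecutive samples (default 20).
#' @param out_dir Directory for the stills; created if needed.
#' @return A frame-sample manifest: a `data.frame` with columns
#'   `video_path`, `fps`, `total_frames`, `sample_index`, `frame_number`,
#'   `image_path`. `global_order` is assigned by [thin_videos()] at batch
#'   level.
#' @seealso [thin_videos()] for chronologically ordered batches.
#' @export
thin_video <- function(video, interval_s = 20, out_dir) {
  if (!inherits(video, "video_meta")) {
    abort_argument("`video` must be a video_meta object (see probe_video()).")
  }
  check_positive_scalar(interval_s, "interval_s")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_thinned_samples(video$total_frames, video$fps, interval_s)
  idx <- seq_len(n)
  frames <- frame_number_for_sample(idx, interval_s, video$fps)
  stem <- tools::file_path_sans_ext(basename(video$path))
  paths <- file.path(out_dir, sprintf("%s_s%04d_f%07d.png", stem, idx, frames))
  ext <- tolower(tools::file_ext(video$path))
  if (ext %in% c("tif", "tiff")) {
    imgs <- read_framestack_frames(video$path, frames)
    for (i in seq_along(imgs)) png::writePNG(imgs[[i]], paths[i])
  } else {
    extract_frames_ffmpeg(video, frames, paths)
  }
  fc_log("thin", video = video$path, n_samples = n, interval_s = interval_s)
  data.frame(video_path = video$path, fps = video$fps,
             total_frames = video$total_frames, sample_index = idx,
             frame_number = frames, image_path = paths,
             stringsAsFactors = FALSE)
}

#' Thin a batch of videos in chronological order
#'
#' Probes every file, sorts the batch by chronological key (filename
#' timestamp, ties broken by path), thins each video, and assigns
#' `global_order` across the whole batch so downstream event grouping sees
#' one chronologically ordered stream of samples.
#'
#' @param paths Character vector of video files.
#' @param interval_s Seconds between samples (default 20).
#' @param out_dir Directory for the stills.
#' @param timestamp_pattern Optional override passed to [probe_video()].
#' @return The combined frame-sample manifest with a `global_order` column.
#' @export
thin_videos <- function(paths, interval_s = 20, out_dir,
                        timestamp_pattern = NULL) {
  if (length(paths) == 0L) abort_argument("No video files given.")
  metas <- lapply(paths, probe_video, timestamp_pattern = timestamp_pattern)
  metas <- metas[order(vapply(metas, `[[`, "", "chrono_key"))]
  parts <- lapply(metas, thin_video, interval_s = interval_s,
                  out_dir = out_dir)
  manifest <- do.call(rbind, parts)
  manifest$global_order <- seq_len(nrow(manifest))
  manifest
}

#' Read/write frame-sample and prediction manifests
#'
#' CSV round-trip for the manifests that tie the pipeline stages together
#' (UTF-8, header row). `read_manifest()` validates that the core columns
#' are present.
#'
#' @param manifest A manifest `data.frame`.
#' @param path CSV file path.
#' @return `read_manifest()` returns the manifest `data.frame`;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Manifest '%s' not found.", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_path", "fps", "total_frames", "sample_index",
            "frame_number")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    abort_data(sprintf("Manifest '%s' lacks column(s): %s.", path,
                       paste(missing, collapse = ", ")))
  }
  m
}
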