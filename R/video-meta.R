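#' Video metadata
#'
#' A `video_meta` object holds the probed facts about one video file that the
#' rest of the pipeline needs: frame rate, total frame count, and a sortable
#' chronological key derived from the filename. Construct it with
#' [probe_video()]; the constructor is exported for synthetic/test use.
#'
#' @param path Path to the video file.
#' @param fps Frames per second; a single positive number.
#' @param total_frames Total number of frames; a single positive integer.
#' @param chrono_key Sortable character key placing this video in a batch's
#'   chronological order. Defaults to [chrono_key_for()] applied to `path`.
#' @param frames_estimated `TRUE` when `total_frames` was reconstructed from
#'   duration times frame rate rather than counted by the container probe.
#'
#' @return An object of class `video_meta`.
#' @seealso [probe_video()], [thin_video()], [write_segment()]
#' @export
video_meta <- function(path, fps, total_frames,
                       chrono_key = chrono_key_for(path),
                       frames_estimated = FALSE) {
  if (!is.character(path) || length(path) != 1L) {
    abort_argument("`path` must be a single file path.")
  }
  check_positive_scalar(fps, "fps")
  total_frames <- check_count(total_frames, "total_frames")
  structure(
    list(path = path, fps = fps, total_frames = total_frames,
         chrono_key = as.character(chrono_key),
         frames_estimated = isTRUE(frames_estimated)),
    class = "video_meta"
  )
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("<video_meta> %s\n  fps: %g  frames: %d%s  duration: %.1f s\n",
              x$path, x$fps, x$total_frames,
              if (x$frames_estimated) " (estimated)" else "",
              x$total_frames / x$fps))
  invisible(x)
}

#' Chronological sort key for a video filename
#'
#' Surveillance recorders embed a timestamp in each file name; batches are
#' processed in recording order. The key is the first match of
#' `timestamp_pattern` in the base name, with the full path appended as a
#' lexicographic tie-breaker, so that `order(chrono_key)` totally orders any
#' batch. Files without a timestamp sort before stamped ones, among
#' themselves by path.
#'
#' @param path Character vector of file paths.
#' @param timestamp_pattern Regular expression whose first match is the
#'   sortable timestamp. The default matches compact `YYYYMMDD_HHMMSS`-style
#'   stamps as well as `YYYY-MM-DD[_T]HH-MM-SS` variants.
#' @return Character vector of sort keys, same length as `path`.
#' @export
#' @examples
#' chrono_key_for(c("cam1_20230726_051500.mp4", "cam1_20230726_052000.mp4"))
chrono_key_for <- function(path,
                           timestamp_pattern = "[0-9]{4}-?[0-9]{2}-?[0-9]{2}[-_T ]?[0-9]{2}-?[0-9]{2}-?[0-9]{2}") {
  if (length(path) == 0L) return(character(0))
  base <- basename(path)
  m <- regexpr(timestamp_pattern, base)
  ts <- ifelse(m > 0L, regmatches(base, m), "")
  # strip separators so "2023-07-26_05-15-00" and "20230726_051500" compare
  ts <- gsub("[^0-9]", "", ts)
  paste(ts, path, sep = "\x1f")
}

#' Probe a video file
#'
#' Reads frame rate and total frame count from a video container. Two
#' backends are supported and chosen by file extension:
#'
#' * **frame-stack** (`.tif`/`.tiff`): a lossless multi-page TIFF whose frame
#'   rate lives in a JSON sidecar (`<path>.json`, field `fps`). This is the
#'   container written by [render_video()] and [write_segment()]; it is
#'   frame-accurate by construction and needs no external toolchain.
#' * **ffmpeg** (anything else, e.g. MP4/MKV/AVI): shells out to `ffprobe`.
#'   Requires the ffmpeg suite on the `PATH`; otherwise a capability error is
#'   raised. When the container does not report a frame count, it is
#'   reconstructed as `round(duration * fps)` and flagged via
#'   `frames_estimated`.
#'
#' @param path Path to one video file.
#' @param timestamp_pattern Passed to [chrono_key_for()].
#' @return A [video_meta()] object.
#' @export
probe_video <- function(path, timestamp_pattern = NULL) {
  if (!is.character(path) || length(path) != 1L) {
    abort_argument("`path` must be a single file path.")
  }
  if (!file.exists(path)) {
    abort_io(sprintf("Video file does not exist: '%s'.", path))
  }
  key <- if (is.null(timestamp_pattern)) chrono_key_for(path)
         else chrono_key_for(path, timestamp_pattern)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    probe_framestack(path, key)
  } else {
    probe_ffmpeg(path, key)
  }
}
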