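#' Request one frame-accurate video segment
#'
#' A segment request names a source video, an inclusive 1-based frame range
#' within its bounds, and an output path. Out-of-bounds ranges are rejected
#' here — clamping against video bounds is the event layer's job
#' ([buffer_and_clamp()]), so a violation reaching this constructor is a
#' caller bug, not data to be silently repaired.
#'
#' @param video A [video_meta()] object.
#' @param start_frame,end_frame Inclusive 1-based frame bounds,
#'   `1 <= start_frame <= end_frame <= video$total_frames`.
#' @param output_path Where the clip is written.
#' @return An object of class `segment_request`.
#' @export
segment_request <- function(video, start_frame, end_frame, output_path) {
  if (!inherits(video, "video_meta")) {
    abort_argument("`video` must be a video_meta object.")
  }
  start_frame <- check_count(start_frame, "start_frame")
  end_frame <- check_count(end_frame, "end_frame")
  if (start_frame > end_frame) {
    abort_argument("`start_frame` must not exceed `end_frame`.")
  }
  if (end_frame > video$total_frames) {
    abort_argument(sprintf(
      "`end_frame` (%d) exceeds the video's %d frames.",
      end_frame, video$total_frames))
  }
  structure(list(video = video, start_frame = start_frame,
                 end_frame = end_frame, output_path = output_path),
            class = "segment_request")
}

#' Write a video segment
#'
#' Cuts frames `[start_frame, end_frame]` out of the source video into a new
#' clip. For frame-stack (`.tif`) sources the cut is exact by construction:
#' the requested pages are copied into a new frame stack. For coded
#' containers the cut goes through ffmpeg; `mode = "reencode"` (default)
#' selects frames exactly, while `mode = "copy"` is faster but snaps to
#' keyframes, so the clip length may be off by a couple of frames.
#'
#' @param req A [segment_request()].
#' @param mode `"reencode"` (frame-accurate) or `"copy"` (fast,
#'   keyframe-snapped; coded containers only).
#' @return The output path, invisibly.
#' @export
write_segment <- function(req, mode = c("reencode", "copy")) {
  mode <- match.arg(mode)
  if (!inherits(req, "segment_request")) {
    abort_argument("`req` must be a segment_request object.")
  }
  ext <- tolower(tools::file_ext(req$video$path))
  if (ext %in% c("tif", "tiff")) {
    frames <- read_framestack_frames(req$video$path,
                                     seq(req$start_frame, req$end_frame))
    write_framestack(frames, req$output_path, fps = req$video$fps)
  } else {
    write_segment_ffmpeg(req$video, req$start_frame, req$end_frame,
                         req$output_path, mode = mode)
  }
  fc_log("write_segment", video = req$video$path,
         start_frame = req$start_frame, end_frame = req$end_frame,
         clip = req$output_path)
  invisible(req$output_path)
}
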