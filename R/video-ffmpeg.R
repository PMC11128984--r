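# ffmpeg/ffprobe backend for ordinary containers (MP4/MKV/AVI with
# H.264/H.265 and friends). Everything here degrades to a classed
# capability error when the ffmpeg suite is not on the PATH, so the rest of
# the pipeline (which can run entirely from CSV scores and frame-stack
# videos) stays usable without it.

have_ffmpeg <- function() {
  nzchar(Sys.which("ffmpeg")) && nzchar(Sys.which("ffprobe"))
}

require_ffmpeg <- function(what) {
  if (!have_ffmpeg()) {
    abort_capability(sprintf(
      "%s requires the ffmpeg suite (ffmpeg + ffprobe) on the PATH; it was not found. Frame-stack (.tif) videos and CSV score replay work without it.",
      what))
  }
}

probe_ffmpeg <- function(path, chrono_key) {
  require_ffmpeg(sprintf("Probing '%s'", path))
  args <- c("-v", "error", "-select_streams", "v:0",
            "-show_entries", "stream=nb_frames,r_frame_rate,duration",
            "-of", "json", path)
  out <- suppressWarnings(system2("ffprobe", shQuote(args), stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    abort_io(sprintf("ffprobe failed on '%s': %s", path,
                     paste(out, collapse = " ")))
  }
  meta <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "")),
                   error = function(e) NULL)
  stream <- meta$streams
  if (is.null(stream) || NROW(stream) < 1L) {
    abort_io(sprintf("ffprobe found no video stream in '%s'.", path))
  }
  stream <- as.list(stream[1L, , drop = FALSE])
  fps <- parse_ffmpeg_rate(stream$r_frame_rate)
  nb <- suppressWarnings(as.integer(stream$nb_frames))
  estimated <- FALSE
  if (is.null(nb) || length(nb) != 1L || is.na(nb)) {
    dur <- suppressWarnings(as.numeric(stream$duration))
    if (length(dur) != 1L || is.na(dur)) {
      abort_io(sprintf(
        "ffprobe reports neither frame count nor duration for '%s'.", path))
    }
    nb <- as.integer(round(dur * fps))
    estimated <- TRUE
  }
  video_meta(path, fps = fps, total_frames = nb, chrono_key = chrono_key,
             frames_estimated = estimated)
}

parse_ffmpeg_rate <- function(rate) {
  if (is.null(rate)) abort_io("ffprobe reported no frame rate.")
  parts <- strsplit(as.character(rate), "/", fixed = TRUE)[[1L]]
  num <- as.numeric(parts[1L])
  den <- if (length(parts) > 1L) as.numeric(parts[2L]) else 1
  if (!is.finite(num) || !is.finite(den) || den == 0 || num <= 0) {
    abort_io(sprintf("Unparseable frame rate '%s'.", rate))
  }
  num / den
}

# Extract single frames as PNG stills. `frames` are 1-based frame numbers.
extract_frames_ffmpeg <- function(video, frames, out_paths) {
  require_ffmpeg("Frame extraction from coded containers")
  for (i in seq_along(frames)) {
    t <- (frames[i] - 1L) / video$fps
    args <- c("-v", "error", "-ss", sprintf("%.6f", t), "-i", video$path,
              "-frames:v", "1", "-y", out_paths[i])
    status <- system2("ffmpeg", shQuote(args), stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      abort_io(sprintf("ffmpeg failed extracting frame %d of '%s'.",
                       frames[i], video$path))
    }
  }
  invisible(out_paths)
}

# Frame-accurate cut in re-encode mode (select filter counts frames, 0-based
# in ffmpeg); stream-copy mode snaps to keyframes and is fast but imprecise.
write_segment_ffmpeg <- function(video, start_frame, end_frame, output_path,
                                 mode = c("reencode", "copy")) {
  mode <- match.arg(mode)
  require_ffmpeg("Writing segments from coded containers")
  if (mode == "reencode") {
    vf <- sprintf("select='between(n,%d,%d)',setpts=N/FRAME_RATE/TB",
                  start_frame - 1L, end_frame - 1L)
    args <- c("-v", "error", "-i", video$path, "-vf", vf, "-an",
              "-y", output_path)
  } else {
    ss <- (start_frame - 1L) / video$fps
    to <- end_frame / video$fps
    args <- c("-v", "error", "-ss", sprintf("%.6f", ss), "-to",
              sprintf("%.6f", to), "-i", video$path, "-c", "copy",
              "-y", output_path)
  }
  status <- system2("ffmpeg", shQuote(args), stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    abort_io(sprintf("ffmpeg failed writing segment [%d, %d] of '%s'.",
                     start_frame, end_frame, video$path))
  }
  invisible(output_path)
}
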