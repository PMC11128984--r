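# Frame-stack video container: a multi-page 8-bit grayscale TIFF (deflate
# compressed) holding one page per frame, with a JSON sidecar `<path>.json`
# carrying at least {"fps": <number>}. Lossless and frame-accurate: page i
# IS frame i, so probing, thinning and segment extraction involve no codec
# heuristics. All synthetic footage and all written segments use it.

framestack_sidecar_path <- function(path) paste0(path, ".json")

read_framestack_sidecar <- function(path) {
  sc <- framestack_sidecar_path(path)
  if (!file.exists(sc)) {
    abort_data(sprintf(
      "Frame-stack video '%s' has no sidecar '%s' (needed for fps).",
      path, sc))
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

write_framestack_sidecar <- function(path, fps, ...) {
  jsonlite::write_json(c(list(fps = fps), list(...)),
                       framestack_sidecar_path(path), auto_unbox = TRUE)
}

probe_framestack <- function(path, chrono_key) {
  info <- tryCatch(
    tiff::readTIFF(path, all = TRUE, payload = FALSE),
    error = function(e) {
      abort_io(sprintf("Cannot probe '%s' as a frame-stack video: %s",
                       path, conditionMessage(e)))
    }
  )
  n <- if (is.data.frame(info)) nrow(info) else length(info)
  side <- read_framestack_sidecar(path)
  if (is.null(side$fps)) {
    abort_data(sprintf("Sidecar for '%s' lacks an 'fps' field.", path))
  }
  video_meta(path, fps = as.numeric(side$fps), total_frames = n,
             chrono_key = chrono_key)
}

# Read selected frames (1-based indices) as numeric matrices in [0, 1].
read_framestack_frames <- function(path, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L)) abort_argument("Frame indices must be >= 1.")
  out <- tryCatch(
    tiff::readTIFF(path, all = frames),
    error = function(e) {
      abort_io(sprintf("Cannot read frames from '%s': %s",
                       path, conditionMessage(e)))
    }
  )
  if (!is.list(out)) out <- list(out)
  # collapse any colour planes to grayscale; pipeline images are 2-D
  lapply(out, function(fr) {
    if (length(dim(fr)) == 3L) fr <- apply(fr, c(1L, 2L), mean)
    fr
  })
}

# Write a list of [0,1] matrices as a frame-stack video plus sidecar.
write_framestack <- function(frames, path, fps) {
  if (!length(frames)) abort_argument("Cannot write a video with 0 frames.")
  ok <- tryCatch({
    tiff::writeTIFF(frames, path, bits.per.sample = 8L,
                    compression = "deflate")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_io(sprintf("Failed to write frame-stack video '%s': %s",
                     path, conditionMessage(ok)))
  }
  write_framestack_sidecar(path, fps = fps, n_frames = length(frames))
  invisible(path)
}
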