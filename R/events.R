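#' Event-segmentation configuration
#'
#' The two knobs of the detection-event algorithm: the inclusive fish
#' probability threshold applied to each thinned frame (default 0.5, i.e.
#' keep frames scored at 50% or more), and the pre/post buffer, in seconds,
#' padded around each event before clip extraction (default 20 s — at
#' 20 fps footage that is the classic 400-frame pad). The buffer is stated
#' in seconds and converted per video via its own frame rate, so mixed-rate
#' batches pad by equal time, not equal frame count.
#'
#' @param threshold Probability threshold in `[0, 1]`; comparison is `>=`.
#' @param buffer_s Nonnegative buffer duration in seconds.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold = 0.5, buffer_s = 20) {
  check_probability(threshold, "threshold")
  if (!is_scalar_number(buffer_s) || buffer_s < 0) {
    abort_argument("`buffer_s` must be a single nonnegative number.")
  }
  structure(list(threshold = threshold, buffer_s = buffer_s),
            class = "segmentation_config")
}

#' Keep above-threshold predictions
#'
#' Inclusive threshold filter over a chronologically ordered prediction
#' stream: rows with `p_fish >= threshold` survive, order preserved.
#' Missing scores (`NA`, from unreadable frames) are treated as below
#' threshold, so they break adjacency rather than fabricate continuity.
#' The chronological ordering (`global_order` ascending) is the caller's
#' contract and is verified, not repaired.
#'
#' @param predictions Prediction `data.frame`: frame-sample manifest
#'   columns plus `p_fish` and `global_order`.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return The qualifying rows of `predictions`.
#' @export
filter_predictions <- function(predictions, threshold = 0.5) {
  check_probability(threshold, "threshold")
  check_prediction_frame(predictions)
  if (nrow(predictions) == 0L) return(predictions)
  if (is.unsorted(predictions$global_order, strictly = TRUE)) {
    abort_argument(
      "`predictions` must be strictly ordered by global_order (chronological).")
  }
  keep <- !is.na(predictions$p_fish) & predictions$p_fish >= threshold
  predictions[keep, , drop = FALSE]
}

check_prediction_frame <- function(predictions) {
  if (!is.data.frame(predictions)) {
    abort_argument("`predictions` must be a data.frame.")
  }
  need <- c("video_path", "sample_index", "frame_number", "p_fish",
            "global_order")
  missing <- setdiff(need, names(predictions))
  if (length(missing)) {
    abort_argument(sprintf("`predictions` lacks column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  invisible(predictions)
}

#' Group adjacent positive frames into detection events
#'
#' The heart of the pipeline: the filtered stream is split by video file
#' (runs never bridge files), and within each video every maximal run of
#' consecutive `sample_index` values — adjacent thinned frames that all
#' crossed the threshold — becomes one detection event. Each event records
#' its member samples and its raw frame bounds (min and max member frame
#' number); `group_id` restarts at 1 within each video, in chronological
#' order.
#'
#' @param filtered Output of [filter_predictions()]: ordered positive
#'   predictions carrying `fps` and `total_frames` columns.
#' @return A `fish_events` data.frame, one row per event, with columns
#'   `video_path`, `group_id`, `n_samples`, `first_sample`, `last_sample`,
#'   `start_frame`, `end_frame`, `fps`, `total_frames`, and a list column
#'   `member_samples`.
#' @export
group_adjacent <- function(filtered) {
  check_prediction_frame(filtered)
  if (anyDuplicated(filtered[c("video_path", "sample_index")])) {
    abort_data("Duplicate (video, sample_index) pairs in the predictions.")
  }
  if (nrow(filtered) == 0L) return(empty_events())
  videos <- unique(filtered$video_path)  # appearance order = chronological
  per_video <- lapply(videos, function(v) {
    d <- filtered[filtered$video_path == v, , drop = FALSE]
    d <- d[order(d$sample_index), , drop = FALSE]
    run <- cumsum(c(1L, diff(d$sample_index) != 1L))
    events <- lapply(split(seq_len(nrow(d)), run), function(rows) {
      dd <- d[rows, , drop = FALSE]
      data.frame(video_path = v, group_id = NA_integer_,
                 n_samples = nrow(dd),
                 first_sample = min(dd$sample_index),
                 last_sample = max(dd$sample_index),
                 start_frame = min(dd$frame_number),
                 end_frame = max(dd$frame_number),
                 fps = dd$fps[1L], total_frames = dd$total_frames[1L],
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, events)
    ev$group_id <- seq_len(nrow(ev))
    ev$member_samples <- unname(lapply(split(d$sample_index, run), as.integer))
    ev
  })
  out <- do.call(rbind, per_video)
  rownames(out) <- NULL
  class(out) <- c("fish_events", "data.frame")
  out
}

empty_events <- function() {
  out <- data.frame(video_path = character(0), group_id = integer(0),
                    n_samples = integer(0), first_sample = integer(0),
                    last_sample = integer(0), start_frame = integer(0),
                    end_frame = integer(0), fps = numeric(0),
                    total_frames = integer(0), stringsAsFactors = FALSE)
  out$member_samples <- list()
  class(out) <- c("fish_events", "data.frame")
  out
}

#' Pad events with the time buffer and clamp to video bounds
#'
#' Adds `buffered_start`/`buffered_end` columns:
#' `buffer_frames = round(buffer_s * fps)` per video, subtracted from the
#' start and added to the end, then clamped to `[1, total_frames]` so no
#' request can leave the video. 20 s at 20 fps gives the familiar 400-frame
#' pad.
#'
#' @param events A `fish_events` frame from [group_adjacent()].
#' @param config A [segmentation_config()].
#' @return `events` with `buffered_start` and `buffered_end` columns.
#' @export
buffer_and_clamp <- function(events, config = segmentation_config()) {
  if (!inherits(events, "fish_events")) {
    abort_argument("`events` must come from group_adjacent().")
  }
  if (!inherits(config, "segmentation_config")) {
    abort_argument("`config` must be a segmentation_config object.")
  }
  buf <- as.integer(round(config$buffer_s * events$fps))
  events$buffered_start <- pmax(1L, events$start_frame - buf)
  events$buffered_end <- pmin(events$total_frames, events$end_frame + buf)
  events
}

#' Turn buffered events into segment requests
#'
#' One [segment_request()] per event; clip files are named
#' `<video-stem>_g<group_id>_f<buffered_start>-<buffered_end>.<ext>` under
#' `out_dir`. Clip extension follows the source container (frame-stack
#' sources yield frame-stack clips).
#'
#' @param events Buffered `fish_events` (from [buffer_and_clamp()]).
#' @param out_dir Output directory for clips.
#' @param videos Optional named list of [video_meta()] objects keyed by
#'   path; probed on demand when absent.
#' @return List of `segment_request` objects.
#' @export
segment_events <- function(events, out_dir, videos = NULL) {
  if (!inherits(events, "fish_events")) {
    abort_argument("`events` must be a fish_events frame.")
  }
  if (is.null(events$buffered_start)) {
    abort_argument("`events` lacks buffered bounds; run buffer_and_clamp() first.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lapply(seq_len(nrow(events)), function(i) {
    path <- events$video_path[i]
    video <- if (!is.null(videos) && !is.null(videos[[path]])) videos[[path]]
             else probe_video(path)
    ext <- tools::file_ext(path)
    clip <- file.path(out_dir, sprintf(
      "%s_g%02d_f%07d-%07d.%s", tools::file_path_sans_ext(basename(path)),
      events$group_id[i], events$buffered_start[i], events$buffered_end[i],
      ext))
    segment_request(video, events$buffered_start[i], events$buffered_end[i],
                    clip)
  })
}

#' Write all event clips
#'
#' Executes [write_segment()] for every request, continuing past per-event
#' I/O failures (which are collected and reported as a warning), and
#' returns the segment manifest.
#'
#' @param events Buffered `fish_events`.
#' @param out_dir Clip output directory.
#' @param mode Passed to [write_segment()].
#' @param videos Optional pre-probed [video_meta()] list (see
#'   [segment_events()]).
#' @return Segment-manifest `data.frame`: `video_path`, `group_id`,
#'   `start_frame`, `end_frame`, `buffered_start`, `buffered_end`,
#'   `clip_path` (`NA` where writing failed).
#' @export
write_event_clips <- function(events, out_dir, mode = "reencode",
                              videos = NULL) {
  reqs <- segment_events(events, out_dir, videos = videos)
  clip_paths <- rep(NA_character_, length(reqs))
  failures <- character(0)
  for (i in seq_along(reqs)) {
    res <- tryCatch(write_segment(reqs[[i]], mode = mode),
                    fishclip_io_error = function(e) e)
    if (inherits(res, "fishclip_io_error")) {
      failures <- c(failures, conditionMessage(res))
    } else {
      clip_paths[i] <- reqs[[i]]$output_path
    }
  }
  if (length(failures)) {
    warning(sprintf("%d of %d clips failed to write; first error: %s",
                    length(failures), length(reqs), failures[1L]),
            call. = FALSE)
  }
  manifest <- as.data.frame(events)[c("video_path", "group_id", "start_frame",
                                      "end_frame", "buffered_start",
                                      "buffered_end")]
  manifest$clip_path <- clip_paths
  manifest
}

#' Detect fish events in a prediction stream
#'
#' Convenience wrapper chaining [filter_predictions()], [group_adjacent()]
#' and [buffer_and_clamp()]: from a chronologically ordered prediction
#' stream to buffered, clamped detection events in one call.
#'
#' @param predictions Prediction `data.frame` (manifest columns plus
#'   `p_fish` and `global_order`).
#' @param config A [segmentation_config()].
#' @return A buffered `fish_events` frame; the configuration is attached as
#'   attribute `"config"`.
#' @export
#' @examples
#' stream <- generate_probability_stream(stream_config(
#'   n_videos = 1, samples_per_video = 12,
#'   planted_runs = list(list(c(3, 3, 0.9), c(9, 1, 0.9))), seed = 7))
#' detect_events(stream$predictions)
detect_events <- function(predictions, config = segmentation_config()) {
  kept <- filter_predictions(predictions, config$threshold)
  events <- buffer_and_clamp(group_adjacent(kept), config)
  attr(events, "config") <- config
  fc_log("detect_events", n_predictions = nrow(predictions),
         n_kept = nrow(kept), n_events = nrow(events),
         threshold = config$threshold, buffer_s = config$buffer_s)
  events
}

#' @export
print.fish_events <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<fish_events> %d event(s) across %d video(s)\n",
              nrow(x), length(unique(x$video_path))))
  if (!is.null(cfg)) {
    cat(sprintf("  threshold >= %g, buffer %g s\n", cfg$threshold,
                cfg$buffer_s))
  }
  if (nrow(x)) {
    show <- as.data.frame(x)[setdiff(names(x), "member_samples")]
    print(utils::head(show, 10L), row.names = FALSE)
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' @export
summary.fish_events <- function(object, ...) {
  cat(sprintf("Detection events: %d\n", nrow(object)))
  if (nrow(object)) {
    dur <- (object$end_frame - object$start_frame + 1L) / object$fps
    cat(sprintf("  videos involved: %d\n", length(unique(object$video_path))))
    cat(sprintf("  member samples per event: median %g, max %d\n",
                stats::median(object$n_samples), max(object$n_samples)))
    cat(sprintf("  raw event span: %.1f-%.1f s (median %.1f)\n",
                min(dur), max(dur), stats::median(dur)))
  }
  invisible(object)
}
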