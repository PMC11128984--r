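#' Pipeline configuration
#'
#' The knobs of the full monitoring workflow, with defaults matching
#' standard practice for 20 fps stream surveillance: thin to one frame per
#' 20 s, keep frames scored at >= 50%, pad events by 20 s, and queue frames
#' at >= 3% for manual review.
#'
#' @param interval_s Thinning interval in seconds.
#' @param threshold Event probability threshold in `[0, 1]`.
#' @param buffer_s Event pad in seconds.
#' @param review_min_percent Manual-review percent threshold in `[0, 100]`.
#' @param timestamp_pattern Filename timestamp regex (see
#'   [chrono_key_for()]); `NULL` for the default.
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(interval_s = 20, threshold = 0.5, buffer_s = 20,
                            review_min_percent = 3L,
                            timestamp_pattern = NULL, seed = 1L) {
  check_positive_scalar(interval_s, "interval_s")
  check_probability(threshold, "threshold")
  if (!is_scalar_number(buffer_s) || buffer_s < 0) {
    abort_argument("`buffer_s` must be a single nonnegative number.")
  }
  review_min_percent <- check_count(review_min_percent, "review_min_percent",
                                    min = 0L)
  if (review_min_percent > 100L) {
    abort_argument("`review_min_percent` must be in [0, 100].")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(interval_s = interval_s, threshold = threshold,
                 buffer_s = buffer_s,
                 review_min_percent = review_min_percent,
                 timestamp_pattern = timestamp_pattern, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected (they are almost always typos of real knobs);
#' `overrides` (e.g. parsed command-line flags) win over file values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_io(sprintf("Config '%s' not found.", path))
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_argument(sprintf("Unknown config key(s): %s.",
                           paste(bad, collapse = ", ")))
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

# ---------------------------------------------------------------------------
# cmd_* functions: the composable pipeline stages behind the CLI script.
# Each consumes/produces the shared CSV dialects so any stage can be
# replaced or skipped (e.g. scoring done elsewhere and replayed from CSV).

#' Pipeline stage: thin a batch of videos
#'
#' @param inputs Video files, or a directory to scan for videos.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; stills under `<out_dir>/frames`, the
#'   manifest at `<out_dir>/frames.csv`.
#' @return Path of the written frame manifest, invisibly.
#' @export
cmd_thin <- function(inputs, config = pipeline_config(), out_dir) {
  paths <- resolve_video_inputs(inputs)
  manifest <- thin_videos(paths, interval_s = config$interval_s,
                          out_dir = file.path(out_dir, "frames"),
                          timestamp_pattern = config$timestamp_pattern)
  out <- file.path(out_dir, "frames.csv")
  write_manifest(manifest, out)
  invisible(out)
}

resolve_video_inputs <- function(inputs) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    paths <- list.files(inputs, pattern = "\\.(tif|tiff|mp4|mkv|avi)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(paths)) {
      abort_data(sprintf("No video files found under '%s'.", inputs))
    }
    return(paths)
  }
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    abort_io(sprintf("Video file(s) not found: %s.",
                     paste(missing, collapse = ", ")))
  }
  if (!length(inputs)) abort_argument("No video inputs given.")
  inputs
}

#' Pipeline stage: score a frame manifest
#'
#' @param manifest_path Frame-manifest CSV from [cmd_thin()].
#' @param predictor_choice `"mock"`, `"csv:<path>"` or `"model:<path>"`
#'   (a predictor saved with [save_predictor()]).
#' @param out_path Output prediction CSV.
#' @return `out_path`, invisibly.
#' @export
cmd_predict <- function(manifest_path, predictor_choice = "mock", out_path) {
  samples <- read_manifest(manifest_path)
  predictor <- resolve_predictor(predictor_choice)
  predictions <- predict_batch(predictor, samples)
  write_manifest(predictions, out_path)
  invisible(out_path)
}

resolve_predictor <- function(choice) {
  if (inherits(choice, c("mock_predictor", "csv_predictor", "fish_model",
                         "training_report"))) {
    return(choice)
  }
  if (!is.character(choice) || length(choice) != 1L) {
    abort_argument("`predictor_choice` must be a predictor or a choice string.")
  }
  if (choice == "mock") return(mock_predictor())
  if (startsWith(choice, "csv:")) return(csv_predictor(sub("^csv:", "", choice)))
  if (startsWith(choice, "model:")) {
    return(load_predictor(sub("^model:", "", choice)))
  }
  abort_argument(sprintf(
    "Unknown predictor choice '%s' (use 'mock', 'csv:<path>' or 'model:<path>').",
    choice))
}

#' Pipeline stage: segment events and write clips
#'
#' @param predictions_path Prediction CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Clip directory; the segment manifest is written to
#'   `<out_dir>/segments.csv`.
#' @return The segment manifest `data.frame`, invisibly.
#' @export
cmd_segment <- function(predictions_path, config = pipeline_config(),
                        out_dir) {
  predictions <- read_manifest(predictions_path)
  if (is.null(predictions$p_fish)) {
    abort_data(sprintf("'%s' has no p_fish column.", predictions_path))
  }
  events <- detect_events(predictions,
                          segmentation_config(threshold = config$threshold,
                                              buffer_s = config$buffer_s))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- write_event_clips(events, out_dir)
  write_manifest(manifest, file.path(out_dir, "segments.csv"))
  invisible(manifest)
}

#' Pipeline stage: probability table and review queue
#'
#' @param predictions_path Prediction CSV; dates come from a `date` column
#'   or are derived from each video's filename timestamp (first 8 stamp
#'   digits, `YYYYMMDD`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (`probability_table.csv`,
#'   `review_queue.csv`).
#' @return Invisibly, a list with the `probability_table` and the
#'   `review_queue`.
#' @export
cmd_report <- function(predictions_path, config = pipeline_config(),
                       out_dir) {
  predictions <- read_manifest(predictions_path)
  if (is.null(predictions$p_fish)) {
    abort_data(sprintf("'%s' has no p_fish column.", predictions_path))
  }
  if (is.null(predictions$date)) {
    predictions$date <- date_from_video_path(predictions$video_path,
                                             config$timestamp_pattern)
  }
  tab <- build_probability_table(predictions)
  queue <- review_queue(predictions,
                        min_percent = config$review_min_percent)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_probability_table(tab, file.path(out_dir, "probability_table.csv"))
  save_review_queue(queue, file.path(out_dir, "review_queue.csv"))
  fc_log("report", n_predictions = nrow(predictions),
         n_review = nrow(queue))
  invisible(list(table = tab, queue = queue))
}

date_from_video_path <- function(paths, timestamp_pattern = NULL) {
  keys <- if (is.null(timestamp_pattern)) chrono_key_for(paths)
          else chrono_key_for(paths, timestamp_pattern)
  stamp <- sub("\x1f.*$", "", keys)
  ifelse(nchar(stamp) >= 8L, substr(stamp, 1L, 8L), basename(paths))
}

#' Pipeline stage: generate synthetic demo assets
#'
#' Renders a seeded demo scene (three fish passes over two minutes by
#' default) and a matching probability stream, so the whole workflow can be
#' exercised end to end with no field data.
#'
#' @param out_dir Output directory.
#' @param scene A [scene_config()]; default is the demo scene.
#' @param stream A [stream_config()] or `NULL` to skip.
#' @return Invisibly, a list of written paths.
#' @export
cmd_simulate <- function(out_dir, scene = NULL, stream = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scene)) {
    scene <- scene_config(
      duration_s = 120, fps = 20,
      fish_intervals = list(c(20, 30), c(55, 68), c(100, 110)), seed = 1L)
  }
  video_path <- file.path(out_dir, "demo_20230726_050000.tif")
  rendered <- render_video(scene, video_path)
  out <- list(video = video_path,
              truth = paste0(video_path, ".truth.csv"))
  if (!is.null(stream)) {
    gen <- generate_probability_stream(stream)
    out$stream <- file.path(out_dir, "stream.csv")
    out$stream_truth <- file.path(out_dir, "stream_truth.csv")
    write_manifest(gen$predictions, out$stream)
    utils::write.csv(gen$truth, out$stream_truth, row.names = FALSE)
  }
  invisible(out)
}
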