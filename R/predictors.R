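# Predictor contract: anything accepted by predict_batch() maps a batch of
# frame samples to one fish probability each, order preserved. Three
# predictors satisfy it without any deep-learning dependency (the mock
# heuristic, CSV score replay, and the trained feature-GLM model); the keras
# model is a fourth when that optional stack is installed.

#' Deterministic mock fish predictor
#'
#' A pure, documented image heuristic standing in for the trained
#' classifier in tests and dry runs: salmonids in the synthetic scenes are
#' compact bright bodies against a dim noisy background, so the score is a
#' saturating function of the bright-pixel area fraction,
#' `p = a / (a + area_scale)` with `a = mean(pixels > bright_threshold)`.
#' Identical image bytes always give the identical score.
#'
#' @param bright_threshold Intensity in `(0, 1)` above which a pixel counts
#'   as part of a bright body (default 0.8).
#' @param area_scale Area fraction at which the score reaches 0.5
#'   (default 0.002, i.e. 0.2% of the frame).
#' @return An object of class `mock_predictor`.
#' @export
mock_predictor <- function(bright_threshold = 0.8, area_scale = 0.002) {
  check_probability(bright_threshold, "bright_threshold")
  check_positive_scalar(area_scale, "area_scale")
  structure(list(bright_threshold = bright_threshold,
                 area_scale = area_scale),
            class = "mock_predictor")
}

#' CSV score replay predictor
#'
#' Replays fish probabilities stored in a prediction CSV, so segmentation
#' and reporting can run with no classifier installed. Scores are matched
#' to samples by `image_path` when both sides carry it, otherwise by row
#' order; replayed values are passed through untouched.
#'
#' @param path CSV file with at least a `p_fish` column (the shared
#'   prediction-CSV dialect of [write_manifest()] plus `p_fish`).
#' @param column Name of the probability column (default `"p_fish"`).
#' @return An object of class `csv_predictor`.
#' @export
csv_predictor <- function(path, column = "p_fish") {
  if (!file.exists(path)) abort_io(sprintf("Score CSV '%s' not found.", path))
  scores <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!column %in% names(scores)) {
    abort_data(sprintf("Score CSV '%s' has no '%s' column.", path, column))
  }
  structure(list(path = path, column = column, scores = scores),
            class = "csv_predictor")
}

#' Score a batch of frame samples
#'
#' Applies a predictor to every row of a frame-sample manifest, returning
#' the manifest with a `p_fish` column appended (one prediction per sample,
#' order preserved). Samples whose image cannot be read are recorded with
#' `p_fish = NA` and a warning — never silently dropped — and are treated as
#' below threshold by the event layer.
#'
#' @param predictor A [mock_predictor()], [csv_predictor()], trained model
#'   (see [train()]), or keras model handle.
#' @param samples Frame-sample manifest `data.frame` (see [thin_video()]).
#' @return `samples` with a numeric `p_fish` column in `[0, 1]` (or `NA`).
#' @export
predict_batch <- function(predictor, samples) {
  UseMethod("predict_batch")
}

#' @export
predict_batch.default <- function(predictor, samples) {
  abort_argument(sprintf(
    "No predict_batch() method for class <%s>.",
    paste(class(predictor), collapse = "/")))
}

#' @export
predict_batch.mock_predictor <- function(predictor, samples) {
  check_samples_frame(samples)
  p <- vapply(seq_len(nrow(samples)), function(i) {
    img <- try_read_still(samples$image_path[i])
    if (is.null(img)) return(NA_real_)
    a <- mean(img > predictor$bright_threshold)
    a / (a + predictor$area_scale)
  }, numeric(1))
  warn_missing_predictions(samples, p)
  samples$p_fish <- p
  samples
}

#' @export
predict_batch.csv_predictor <- function(predictor, samples) {
  check_samples_frame(samples, need_images = FALSE)
  sc <- predictor$scores
  if (!is.null(sc$image_path) && !is.null(samples$image_path)) {
    idx <- match(samples$image_path, sc$image_path)
    if (anyNA(idx)) {
      abort_data(sprintf(
        "%d sample image(s) have no score in '%s'.",
        sum(is.na(idx)), predictor$path))
    }
    p <- sc[[predictor$column]][idx]
  } else {
    if (nrow(sc) != nrow(samples)) {
      abort_data(sprintf(
        "Score CSV '%s' has %d rows but the manifest has %d (no image_path to match on).",
        predictor$path, nrow(sc), nrow(samples)))
    }
    p <- sc[[predictor$column]]
  }
  samples$p_fish <- as.numeric(p)
  samples
}

check_samples_frame <- function(samples, need_images = TRUE) {
  if (!is.data.frame(samples)) {
    abort_argument("`samples` must be a frame-sample manifest data.frame.")
  }
  if (nrow(samples) == 0L) return(invisible(samples))
  if (need_images && is.null(samples$image_path)) {
    abort_argument("`samples` lacks an `image_path` column.")
  }
  invisible(samples)
}

try_read_still <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e) NULL)
  if (is.null(img)) return(NULL)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

warn_missing_predictions <- function(samples, p) {
  if (anyNA(p)) {
    bad <- samples$image_path[is.na(p)]
    fc_log("predict_missing", images = bad)
    warning(sprintf("%d image(s) could not be read and were scored NA: %s",
                    length(bad), paste(utils::head(bad, 3L), collapse = ", ")),
            call. = FALSE)
  }
  invisible(NULL)
}
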