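#' Synthetic underwater scene configuration
#'
#' Describes a short surveillance-style video with known ground truth: a
#' noisy dim background (turbid water, drifting bubbles) over which a
#' moving high-contrast ellipse — the synthetic stand-in for a salmonid
#' body — is composited during the stated time intervals. Defaults emulate
#' the field conditions the pipeline targets, scaled to test size: 20 fps
#' footage, 16:9 frames, low-to-moderate background noise.
#'
#' @param duration_s Video duration in seconds.
#' @param fps Frame rate (default 20, the recorder setting the pipeline's
#'   frame arithmetic is usually quoted at).
#' @param resolution `(width, height)` in pixels; default 96 x 54 keeps the
#'   16:9 aspect of 4K footage at test scale.
#' @param fish_intervals List of `c(start_s, end_s)` pairs, sorted and
#'   non-overlapping within `[0, duration_s]`, during which the object is
#'   present.
#' @param noise_level SD of the Gaussian background noise (default 0.05;
#'   raise towards ~0.3 to emulate white water that drowns the contrast
#'   cue).
#' @param seed Integer seed; every pixel of every frame is reproducible.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 10, fps = 20, resolution = c(96L, 54L),
                         fish_intervals = list(), noise_level = 0.05,
                         seed = 1L) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fps, "fps")
  if (!is.numeric(resolution) || length(resolution) != 2L ||
      any(resolution < 8)) {
    abort_argument("`resolution` must be (width, height), both >= 8 px.")
  }
  if (!is_scalar_number(noise_level) || noise_level < 0) {
    abort_argument("`noise_level` must be a single nonnegative number.")
  }
  seed <- check_count(seed, "seed", min = 0L)
  fish_intervals <- validate_intervals(fish_intervals, duration_s)
  structure(list(duration_s = duration_s, fps = fps,
                 resolution = as.integer(resolution),
                 fish_intervals = fish_intervals,
                 noise_level = noise_level, seed = seed),
            class = "scene_config")
}

validate_intervals <- function(intervals, duration_s) {
  if (!is.list(intervals)) {
    abort_argument("`fish_intervals` must be a list of c(start_s, end_s).")
  }
  if (!length(intervals)) return(intervals)
  iv <- lapply(intervals, function(x) {
    if (!is.numeric(x) || length(x) != 2L || x[1L] >= x[2L] ||
        x[1L] < 0 || x[2L] > duration_s) {
      abort_argument(sprintf(
        "Invalid fish interval %s: need 0 <= start < end <= %g.",
        deparse1(x), duration_s))
    }
    as.numeric(x)
  })
  starts <- vapply(iv, `[[`, 0, 1L)
  ends <- vapply(iv, `[[`, 0, 2L)
  o <- order(starts)
  iv <- iv[o]
  if (any(starts[o][-1L] < ends[o][-length(iv)])) {
    abort_argument("`fish_intervals` must not overlap.")
  }
  iv
}

# Frames (1-based) whose timestamp (frame i covers t = (i-1)/fps) falls in
# [start_s, end_s); clamped to the video.
interval_to_frames <- function(start_s, end_s, fps, total_frames) {
  first <- as.integer(ceiling(start_s * fps - 1e-9)) + 1L
  last <- as.integer(ceiling(end_s * fps - 1e-9))
  c(max(1L, first), min(total_frames, last))
}

# Composite one frame: noisy background, plus the moving bright body when
# `phase` (progress through its interval, in [0,1]) is not NA.
render_scene_frame <- function(cfg, phase) {
  w <- cfg$resolution[1L]; h <- cfg$resolution[2L]
  img <- matrix(0.35 + stats::rnorm(w * h, sd = cfg$noise_level), nrow = h)
  if (!is.na(phase)) {
    # body swims left to right across its interval with a slight vertical
    # wobble; semi-axes proportional to the frame (a compact bright blob)
    cx <- (0.15 + 0.7 * phase) * w
    cy <- (0.5 + 0.15 * sin(2 * pi * phase * 3)) * h
    a <- 0.08 * w; b <- 0.05 * h
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    img[inside] <- 0.95
  }
  pmin(pmax(img, 0), 1)
}

#' Render a synthetic surveillance video with ground truth
#'
#' Writes a frame-stack video of `round(duration_s * fps)` frames plus a
#' ground-truth manifest listing the exact frame ranges during which the
#' synthetic fish is present. Identical configurations (including seed)
#' give byte-identical frame content before encoding.
#'
#' @param cfg A [scene_config()].
#' @param out_path Output video path (`.tif`); the ground-truth manifest is
#'   written next to it as `<out_path>.truth.csv`.
#' @return Invisibly, a list with `video` (the probed [video_meta()]) and
#'   `truth` (data.frame `video_path`, `start_frame`, `end_frame`).
#' @export
render_video <- function(cfg, out_path) {
  if (!inherits(cfg, "scene_config")) {
    abort_argument("`cfg` must be a scene_config object.")
  }
  total <- as.integer(round(cfg$duration_s * cfg$fps))
  truth <- do.call(rbind, lapply(cfg$fish_intervals, function(iv) {
    fr <- interval_to_frames(iv[1L], iv[2L], cfg$fps, total)
    data.frame(video_path = out_path, start_frame = fr[1L],
               end_frame = fr[2L], stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(video_path = character(0), start_frame = integer(0),
                        end_frame = integer(0), stringsAsFactors = FALSE)
  }
  # phase of each frame within its interval (NA = no fish)
  phase <- rep(NA_real_, total)
  for (iv in cfg$fish_intervals) {
    fr <- interval_to_frames(iv[1L], iv[2L], cfg$fps, total)
    idx <- seq(fr[1L], fr[2L])
    t <- (idx - 1L) / cfg$fps
    phase[idx] <- (t - iv[1L]) / (iv[2L] - iv[1L])
  }
  frames <- with_seed(cfg$seed,
    lapply(seq_len(total), function(i) render_scene_frame(cfg, phase[i])))
  write_framestack(frames, out_path, fps = cfg$fps)
  utils::write.csv(truth, paste0(out_path, ".truth.csv"), row.names = FALSE)
  fc_log("render_video", path = out_path, frames = total,
         intervals = length(cfg$fish_intervals))
  invisible(list(video = probe_video(out_path), truth = truth))
}

#' Synthetic probability-stream configuration
#'
#' Describes a chronologically ordered batch of per-frame fish
#' probabilities with known above-threshold runs planted in it: the
#' classifier-free way to exercise event segmentation. Base scores are
#' drawn from a right-skewed Beta distribution (defaults Beta(1, 30), mean
#' about 0.03 — matching how heavily real score streams pile into the low
#' percents) and capped below 0.5, so the planted runs are the only
#' above-threshold content.
#'
#' @param n_videos Number of videos in the batch.
#' @param samples_per_video Thinned samples per video.
#' @param planted_runs A list with one element per video; each element is a
#'   list of `c(start_index, length, p_level)` runs (1-based sample index,
#'   `p_level > 0.5`), separated by at least one sample within each video so
#'   every run thresholds into its own event.
#' @param base_noise `c(shape1, shape2)` of the Beta base-score draw.
#' @param interval_s,fps Frame bookkeeping for the simulated videos
#'   (defaults 20 s thinning of 20 fps footage).
#' @param seed Integer seed.
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(n_videos = 1L, samples_per_video = 30L,
                          planted_runs = vector("list", n_videos),
                          base_noise = c(1, 30), interval_s = 20, fps = 20,
                          seed = 1L) {
  n_videos <- check_count(n_videos, "n_videos")
  samples_per_video <- check_count(samples_per_video, "samples_per_video")
  check_positive_scalar(interval_s, "interval_s")
  check_positive_scalar(fps, "fps")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(base_noise) || length(base_noise) != 2L ||
      any(base_noise <= 0)) {
    abort_argument("`base_noise` must be two positive Beta shapes.")
  }
  if (!is.list(planted_runs) || length(planted_runs) != n_videos) {
    abort_argument("`planted_runs` must be a list with one entry per video.")
  }
  for (v in seq_len(n_videos)) {
    runs <- planted_runs[[v]]
    if (is.null(runs)) { planted_runs[[v]] <- list(); next }
    covered <- integer(0)
    for (r in runs) {
      if (!is.numeric(r) || length(r) != 3L || r[1L] < 1 || r[2L] < 1 ||
          r[1L] + r[2L] - 1 > samples_per_video || r[3L] <= 0.5 ||
          r[3L] > 1) {
        abort_argument(sprintf(
          "Invalid run %s in video %d: need start >= 1, length >= 1, start+length-1 <= %d, 0.5 < p_level <= 1.",
          deparse1(r), v, samples_per_video))
      }
      span <- seq(r[1L], r[1L] + r[2L] - 1L)
      # runs must be separated by at least one below-threshold sample:
      # contiguous runs would threshold into a single event and the ground
      # truth would no longer be the expected event list
      if (any(span %in% c(covered - 1L, covered, covered + 1L))) {
        abort_argument(sprintf(
          "Overlapping or adjacent planted runs in video %d.", v))
      }
      covered <- c(covered, span)
    }
  }
  structure(list(n_videos = n_videos, samples_per_video = samples_per_video,
                 planted_runs = planted_runs, base_noise = base_noise,
                 interval_s = interval_s, fps = fps, seed = seed),
            class = "stream_config")
}

#' Generate a seeded probability stream with planted events
#'
#' Produces a chronologically ordered prediction frame across the
#' configured videos — planted runs score exactly their `p_level`, all
#' other samples draw base noise strictly below 0.5 — together with the
#' ground-truth event list that thresholding at 0.5 must recover.
#'
#' @param cfg A [stream_config()].
#' @return A list with `predictions` (the prediction `data.frame`, shared
#'   CSV dialect) and `truth` (`data.frame` of expected events:
#'   `video_path`, `first_sample`, `last_sample`, `start_frame`,
#'   `end_frame`).
#' @export
generate_probability_stream <- function(cfg) {
  if (!inherits(cfg, "stream_config")) {
    abort_argument("`cfg` must be a stream_config object.")
  }
  stride <- frame_stride(cfg$interval_s, cfg$fps)
  total_frames <- cfg$samples_per_video * stride
  preds <- list(); truths <- list()
  with_seed(cfg$seed, {
    for (v in seq_len(cfg$n_videos)) {
      vp <- sprintf("video_%03d.tif", v)
      p <- pmin(0.49, stats::rbeta(cfg$samples_per_video,
                                   cfg$base_noise[1L], cfg$base_noise[2L]))
      for (r in cfg$planted_runs[[v]]) {
        span <- seq(r[1L], r[1L] + r[2L] - 1L)
        p[span] <- r[3L]
        truths[[length(truths) + 1L]] <- data.frame(
          video_path = vp, first_sample = span[1L],
          last_sample = span[length(span)],
          start_frame = frame_number_for_sample(span[1L], cfg$interval_s,
                                                cfg$fps),
          end_frame = frame_number_for_sample(span[length(span)],
                                              cfg$interval_s, cfg$fps),
          stringsAsFactors = FALSE)
      }
      idx <- seq_len(cfg$samples_per_video)
      preds[[v]] <- data.frame(
        video_path = vp, fps = cfg$fps, total_frames = total_frames,
        sample_index = idx,
        frame_number = frame_number_for_sample(idx, cfg$interval_s, cfg$fps),
        p_fish = p, stringsAsFactors = FALSE)
    }
  })
  predictions <- do.call(rbind, preds)
  predictions$global_order <- seq_len(nrow(predictions))
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(video_path = character(0),
                           first_sample = integer(0),
                           last_sample = integer(0),
                           start_frame = integer(0), end_frame = integer(0),
                           stringsAsFactors = FALSE)
  list(predictions = predictions, truth = truth)
}

#' Build a labelled two-folder training set of synthetic stills
#'
#' Writes `n_fish` frames containing the bright synthetic body (at a
#' seeded random position) into `<out_root>/fish` and `n_nofish`
#' background-only frames into `<out_root>/no_fish`. At the default
#' `noise_level` the two classes are separable by mean intensity alone; a
#' high `noise_level` (around 0.3) buries that gap, emulating white-water
#' footage.
#'
#' @param n_fish,n_nofish Image counts per class, each at least 1.
#' @param out_root Dataset root directory.
#' @param cfg A [scene_config()] providing resolution, noise level, seed.
#' @return Invisibly, the [dataset_summary()] of the written set.
#' @export
build_training_set <- function(n_fish, n_nofish, out_root,
                               cfg = scene_config()) {
  n_fish <- check_count(n_fish, "n_fish")
  n_nofish <- check_count(n_nofish, "n_nofish")
  if (!inherits(cfg, "scene_config")) {
    abort_argument("`cfg` must be a scene_config object.")
  }
  fish_dir <- file.path(out_root, "fish")
  nofish_dir <- file.path(out_root, "no_fish")
  dir.create(fish_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(nofish_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, {
    for (i in seq_len(n_fish)) {
      img <- render_scene_frame(cfg, phase = stats::runif(1))
      png::writePNG(img, file.path(fish_dir, sprintf("fish_%04d.png", i)))
    }
    for (i in seq_len(n_nofish)) {
      img <- render_scene_frame(cfg, phase = NA_real_)
      png::writePNG(img, file.path(nofish_dir,
                                   sprintf("no_fish_%04d.png", i)))
    }
  })
  invisible(dataset_summary(out_root))
}
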