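#' Classifier hyper-parameter specification
#'
#' Bundles the hyper-parameters of the two-class fish/no-fish image
#' classifier: the transfer-learning head (dense-layer width, dropout,
#' learning rate) plus the training regime (batch size 32, 3 epochs by
#' default) and the seeded train/validation split. Frames are resized to
#' `input_size` before scoring; the default 299 x 299 is the native input
#' of the Xception backbone used by the deep backend.
#'
#' @param learning_rate Adam learning rate, > 0.
#' @param dropout_rate Dropout fraction in `[0, 1)`.
#' @param dense_units Width of the hidden dense layer; positive integer.
#' @param batch_size Mini-batch size; positive integer (default 32).
#' @param epochs Training epochs; positive integer (default 3).
#' @param input_size `(height, width)` in pixels.
#' @param seed Integer seed for the train/validation split (and weight
#'   initialisation where the backend honours it).
#' @return An object of class `classifier_spec`.
#' @seealso [grid_specs()], [build_model()], [train()]
#' @export
classifier_spec <- function(learning_rate = 1e-3, dropout_rate = 0.2,
                            dense_units = 256, batch_size = 32, epochs = 3,
                            input_size = c(299L, 299L), seed = 1L) {
  check_positive_scalar(learning_rate, "learning_rate")
  if (!is_scalar_number(dropout_rate) || dropout_rate < 0 ||
      dropout_rate >= 1) {
    abort_argument("`dropout_rate` must be a single number in [0, 1).")
  }
  dense_units <- check_count(dense_units, "dense_units")
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  if (!is.numeric(input_size) || length(input_size) != 2L ||
      any(input_size < 1)) {
    abort_argument("`input_size` must be two positive pixel dimensions.")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(learning_rate = learning_rate, dropout_rate = dropout_rate,
         dense_units = dense_units, batch_size = batch_size,
         epochs = epochs, input_size = as.integer(input_size), seed = seed),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf(
    "<classifier_spec> lr=%g dropout=%g units=%d batch=%d epochs=%d input=%dx%d seed=%d\n",
    x$learning_rate, x$dropout_rate, x$dense_units, x$batch_size, x$epochs,
    x$input_size[1L], x$input_size[2L], x$seed))
  invisible(x)
}

#' Enumerate the hyper-parameter grid
#'
#' All unique combinations of learning rate, dropout rate and dense-layer
#' width — with the defaults, 2 x 2 x 2 = 8 specifications. Enumeration
#' order (learning rate slowest, dense units fastest) is fixed and
#' documented because [grid_search()] breaks validation-accuracy ties in
#' favour of the earlier grid position.
#'
#' @param learning_rates,dropout_rates,dense_units Candidate values.
#' @param ... Passed to [classifier_spec()] (e.g. `seed`, `epochs`).
#' @return A list of [classifier_spec()] objects.
#' @export
#' @examples
#' length(grid_specs())  # 8
grid_specs <- function(learning_rates = c(1e-2, 1e-3),
                       dropout_rates = c(0.2, 0.3),
                       dense_units = c(256L, 1024L), ...) {
  if (!length(learning_rates) || !length(dropout_rates) ||
      !length(dense_units)) {
    abort_argument("Each grid axis needs at least one value.")
  }
  specs <- list()
  for (lr in learning_rates)
    for (dr in dropout_rates)
      for (du in dense_units)
        specs[[length(specs) + 1L]] <-
          classifier_spec(learning_rate = lr, dropout_rate = dr,
                          dense_units = du, ...)
  specs
}

#' Summarise a labelled training set
#'
#' The two-folder layout (`<root>/fish`, `<root>/no_fish`) is the package's
#' labelled-data interface. Given a directory, counts the images per class;
#' given named per-class counts, just totals them (useful for bookkeeping
#' against an externally curated set).
#'
#' @param x Either a dataset root directory or a named numeric vector of
#'   per-class image counts.
#' @return An object of class `training_set_summary` with elements
#'   `class_counts` and `total`.
#' @export
#' @examples
#' dataset_summary(c(fish = 1188, no_fish = 7772))$total  # 8960
dataset_summary <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) abort_io(sprintf("Directory '%s' not found.", x))
    classes <- list.dirs(x, recursive = FALSE)
    if (!length(classes)) {
      abort_data(sprintf("'%s' contains no class subdirectories.", x))
    }
    counts <- vapply(classes, function(d) {
      length(list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
    }, integer(1))
    names(counts) <- basename(classes)
  } else if (is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    if (any(x < 0) || any(x != as.integer(x))) {
      abort_argument("Class counts must be nonnegative integers.")
    }
    counts <- x
  } else {
    abort_argument("`x` must be a dataset directory or named class counts.")
  }
  structure(list(class_counts = counts, total = sum(counts)),
            class = "training_set_summary")
}

#' @export
print.training_set_summary <- function(x, ...) {
  cat("<training_set_summary>\n")
  for (cl in names(x$class_counts)) {
    cat(sprintf("  %-10s %d\n", cl, x$class_counts[[cl]]))
  }
  cat(sprintf("  total      %d\n", x$total))
  invisible(x)
}
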