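#' Round a fish probability to its integer percent bin
#'
#' Probabilities are multiplied by 100 and rounded to the nearest whole
#' percent; exact half-percent values round away from zero (so 0.035 is
#' bin 4, not 3). The result partitions `[0, 1]` into the 101 bins 0..100.
#'
#' @param p_fish Numeric vector of probabilities in `[0, 1]`.
#' @return Integer vector of percent bins in `[0, 100]`.
#' @export
#' @examples
#' to_percent_bin(c(0, 0.034, 0.035, 1))  # 0 3 4 100
to_percent_bin <- function(p_fish) {
  if (!is.numeric(p_fish) || any(is.na(p_fish)) ||
      any(p_fish < 0 | p_fish > 1)) {
    abort_argument("`p_fish` must contain probabilities in [0, 1].")
  }
  # round at 9 decimals first so decimal inputs like 0.035 hit their tie
  # exactly despite binary floating point, then half-away-from-zero
  as.integer(floor(round(p_fish * 100, 9) + 0.5))
}

#' Build the probability-frequency table
#'
#' Cross-tabulates predictions by integer percent bin (rows, always the
#' full 0..100 even where empty) and recording date (columns, in first-
#' appearance order unless `dates` is given). This is the evaluation
#' summary reviewers read to judge the classifier: almost all frames pile
#' into the low bins, and the sparse high bins are where the fish are.
#'
#' @param predictions Prediction `data.frame` with `p_fish`; dates are
#'   taken from its `date` column unless `date_of` is supplied.
#' @param date_of Optional character vector of dates, one per prediction
#'   row (overrides the `date` column).
#' @param dates Optional column order for the table.
#' @return An object of class `probability_table`: an integer matrix with
#'   `bin` rows "0".."100" and one column per date.
#' @export
build_probability_table <- function(predictions, date_of = NULL,
                                    dates = NULL) {
  if (!is.data.frame(predictions) || is.null(predictions$p_fish)) {
    abort_argument("`predictions` must be a data.frame with `p_fish`.")
  }
  d <- if (!is.null(date_of)) as.character(date_of)
       else as.character(predictions$date)
  if (nrow(predictions) > 0L &&
      (length(d) != nrow(predictions) || anyNA(d) || any(!nzchar(d)))) {
    abort_data("Every prediction must map to a date (column `date` or `date_of`).")
  }
  if (is.null(dates)) dates <- unique(d)
  if (nrow(predictions) > 0L && !all(d %in% dates)) {
    abort_data("`dates` does not cover all prediction dates.")
  }
  if (length(dates) == 0L) dates <- "all"
  bins <- to_percent_bin(predictions$p_fish)
  counts <- table(factor(bins, levels = 0:100),
                  factor(d, levels = dates))
  m <- matrix(as.integer(counts), nrow = 101L,
              dimnames = list(bin = as.character(0:100), date = dates))
  structure(m, class = c("probability_table", "matrix"))
}

#' Marginals of a probability table
#'
#' @param table A `probability_table`.
#' @return A list with `bin_totals` (row sums, named by bin), `date_totals`
#'   (column sums) and `grand_total`.
#' @export
table_marginals <- function(table) {
  if (!inherits(table, "probability_table")) {
    abort_argument("`table` must be a probability_table.")
  }
  m <- unclass(table)
  bins <- rowSums(m); storage.mode(bins) <- "integer"
  dates <- colSums(m); storage.mode(dates) <- "integer"
  list(bin_totals = bins, date_totals = dates, grand_total = sum(m))
}

#' @export
print.probability_table <- function(x, ...) {
  m <- unclass(x)
  nz <- rowSums(m) > 0
  cat(sprintf("<probability_table> %d predictions, %d date(s), %d nonzero bin(s)\n",
              sum(m), ncol(m), sum(nz)))
  if (any(nz)) print(m[nz, , drop = FALSE])
  invisible(x)
}

#' Write / read a probability table as CSV
#'
#' Machine-readable form keeps all 101 bins (zero rows included) so tables
#' from different runs align; the printed form compresses to nonzero rows.
#'
#' @param table A `probability_table`.
#' @param path CSV path; first column `bin`, then one column per date.
#' @return `write_probability_table()` returns `path` invisibly;
#'   `read_probability_table()` the `probability_table`.
#' @export
write_probability_table <- function(table, path) {
  if (!inherits(table, "probability_table")) {
    abort_argument("`table` must be a probability_table.")
  }
  df <- data.frame(bin = as.integer(rownames(table)),
                   unclass(table), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Table '%s' not found.", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"bin" %in% names(df)) {
    abort_data(sprintf("'%s' has no `bin` column.", path))
  }
  dates <- setdiff(names(df), "bin")
  m <- matrix(0L, nrow = 101L, ncol = length(dates),
              dimnames = list(bin = as.character(0:100), date = dates))
  bins <- as.integer(df$bin)
  if (any(is.na(bins) | bins < 0L | bins > 100L)) {
    abort_data(sprintf("'%s' contains bins outside 0..100.", path))
  }
  for (j in seq_along(dates)) {
    v <- suppressWarnings(as.integer(df[[dates[j]]]))
    v[is.na(v)] <- 0L
    m[bins + 1L, j] <- v
  }
  structure(m, class = c("probability_table", "matrix"))
}

#' The packaged probability-frequency fixture
#'
#' Loads the per-date percent-bin frequency table packaged with fishclip:
#' six July recording dates of thinned-frame predictions (17,296 images in
#' all), used by the test-suite and by [table_to_predictions()] to exercise
#' the reporting path on realistic, heavily zero-skewed score frequencies.
#'
#' @return A `probability_table`.
#' @export
read_table1_fixture <- function() {
  read_probability_table(
    system.file("extdata", "table1_fixture.csv", package = "fishclip",
                mustWork = TRUE))
}

#' Expand a probability table to pseudo-predictions
#'
#' Inverse of [build_probability_table()] up to binning: each count becomes
#' one pseudo-prediction with `p_fish = bin / 100` and the cell's date.
#' Useful for replaying a published frequency table through the reporting
#' pipeline.
#'
#' @param table A `probability_table`.
#' @return A prediction `data.frame` with `p_fish`, `date`, `global_order`.
#' @export
table_to_predictions <- function(table) {
  if (!inherits(table, "probability_table")) {
    abort_argument("`table` must be a probability_table.")
  }
  m <- unclass(table)
  idx <- which(m > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(p_fish = numeric(0), date = character(0),
                      global_order = integer(0)))
  }
  n <- m[idx]
  out <- data.frame(
    p_fish = rep(as.integer(rownames(m))[idx[, 1L]] / 100, n),
    date = rep(colnames(m)[idx[, 2L]], n),
    stringsAsFactors = FALSE)
  # chronological order: by date, then bin, deterministic
  out <- out[order(out$date, out$p_fish), , drop = FALSE]
  out$global_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the manual-review queue
#'
#' Frames scored at or above `min_percent` percent are queued for human
#' scrutiny — the default of 3% mirrors the working rule that anything
#' below is overwhelmingly background and not worth the labour. The queue
#' is sorted most-suspicious-first (percent bin descending), ties in
#' chronological order, with an unset verdict per item; saved verdicts can
#' later feed back into training labels.
#'
#' @param predictions Prediction `data.frame` with `p_fish` (and ideally
#'   `global_order`, `image_path`).
#' @param min_percent Integer review threshold in `[0, 100]` (default 3).
#' @return A `review_queue` data.frame with `percent_bin` and `verdict`
#'   (`NA` = unset) columns.
#' @export
review_queue <- function(predictions, min_percent = 3L) {
  if (!is_scalar_number(min_percent) || min_percent < 0 ||
      min_percent > 100 || min_percent != as.integer(min_percent)) {
    abort_argument("`min_percent` must be an integer in [0, 100].")
  }
  if (!is.data.frame(predictions) || is.null(predictions$p_fish)) {
    abort_argument("`predictions` must be a data.frame with `p_fish`.")
  }
  bins <- to_percent_bin(predictions$p_fish)
  keep <- bins >= min_percent
  q <- predictions[keep, , drop = FALSE]
  q$percent_bin <- bins[keep]
  chrono <- if (!is.null(q$global_order)) q$global_order else seq_len(nrow(q))
  q <- q[order(-q$percent_bin, chrono), , drop = FALSE]
  q$verdict <- NA_character_
  rownames(q) <- NULL
  class(q) <- c("review_queue", "data.frame")
  q
}

#' Save / load review verdicts
#'
#' The sidecar CSV holds `image_path` (where known), `percent_bin` and
#' `verdict` so that human fish/no-fish calls persist across sessions and
#' can be harvested as labels for further training.
#'
#' @param queue A `review_queue`.
#' @param path Sidecar CSV path.
#' @return `save_review_queue()` returns `path` invisibly;
#'   `load_review_queue()` the stored data.frame.
#' @export
save_review_queue <- function(queue, path) {
  if (!inherits(queue, "review_queue")) {
    abort_argument("`queue` must be a review_queue.")
  }
  cols <- intersect(c("image_path", "percent_bin", "verdict"), names(queue))
  utils::write.csv(as.data.frame(queue)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_review_queue
#' @export
load_review_queue <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Queue '%s' not found.", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
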