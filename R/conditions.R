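# Classed conditions used across the package. The CLI maps each class to a
# distinct exit code, so every user-facing failure must go through one of
# these helpers rather than a bare stop().

fc_abort <- function(class, message, call = sys.call(-1L), ...) {
  cnd <- structure(
    class = c(class, "fishclip_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

#' @noRd
abort_argument <- function(message, ...) {
  fc_abort("fishclip_argument_error", message, call = sys.call(-1L), ...)
}

#' @noRd
abort_data <- function(message, ...) {
  fc_abort("fishclip_data_error", message, call = sys.call(-1L), ...)
}

#' @noRd
abort_capability <- function(message, ...) {
  fc_abort("fishclip_capability_error", message, call = sys.call(-1L), ...)
}

#' @noRd
abort_io <- function(message, ...) {
  fc_abort("fishclip_io_error", message, call = sys.call(-1L), ...)
}

# scalar checks -------------------------------------------------------------

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_argument(sprintf("`%s` must be a single positive number, not %s.",
                           name, deparse1(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x < min || x != as.integer(x)) {
    abort_argument(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_probability <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort_argument(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}

# Evaluate an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# JSON-lines structured logging. Off unless a sink file is registered (the
# CLI registers one); each record carries a stage tag plus arbitrary fields.
fc_log <- function(stage, ...) {
  sink <- getOption("fishclip.log_file", NULL)
  if (is.null(sink)) return(invisible(NULL))
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  cat(line, "\n", sep = "", file = sink, append = TRUE)
  invisible(NULL)
}
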