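#' @importFrom stats setNames
#' @importFrom ggplot2 .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple structured logging to stderr
#'
#' One line per event: `LEVEL  message`. The threshold is controlled by
#' `options(metaprofiler.log_level=)`, one of "debug", "info", "warn",
#' "quiet" (default "warn").
#'
#' @param level one of "debug", "info", "warn"
#' @param ... message parts, pasted with no separator
#' @return invisibly, the message string
#' @keywords internal
spl_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  threshold <- levels[[getOption("metaprofiler.log_level", "warn")]]
  msg <- paste0(...)
  if (levels[[level]] >= threshold) {
    message(sprintf("%-5s %s", toupper(level), msg))
  }
  invisible(msg)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)
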