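#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Logging goes to stderr with a module prefix so CLI output streams stay clean.
pq_log <- function(module, ..., level = "INFO") {
  lv <- getOption("pboldqa.log_level", "INFO")
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (ranks[[level]] < ranks[[lv %||% "INFO"]]) return(invisible(NULL))
  message(sprintf("[pboldqa:%s] %s %s", module, level, paste0(..., collapse = "")))
  invisible(NULL)
}

pq_warn <- function(module, ...) {
  warning(sprintf("[pboldqa:%s] %s", module, paste0(..., collapse = "")), call. = FALSE)
}

pq_stop <- function(module, ...) {
  stop(sprintf("[pboldqa:%s] %s", module, paste0(..., collapse = "")), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0

## Strictly increasing, positive echo times in ms.
check_echo_times <- function(echo_times, module = "io") {
  if (!is.numeric(echo_times) || length(echo_times) < 2L)
    pq_stop(module, "p_BOLD requires >= 2 echoes")
  if (any(!is.finite(echo_times)) || any(echo_times <= 0))
    pq_stop(module, "echo times must be positive finite values (ms)")
  if (any(diff(echo_times) <= 0))
    pq_stop(module, "echo times must be strictly increasing")
  invisible(as.numeric(echo_times))
}
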