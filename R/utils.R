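## internal condition helpers: every user-facing failure carries a class so
## callers (and tests) can distinguish format, length, config and fit errors

abort_format <- function(msg, ...) {
  abort(msg, class = "rsapred_format_error", ...)
}

abort_length <- function(msg, ...) {
  abort(msg, class = c("rsapred_length_error", "rsapred_format_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "rsapred_config_error", ...)
}

abort_missing_input <- function(msg, ...) {
  abort(msg, class = "rsapred_missing_input_error", ...)
}

abort_singular <- function(msg, ...) {
  abort(msg, class = "rsapred_singular_error", ...)
}

abort_insufficient <- function(msg, ...) {
  abort(msg, class = "rsapred_insufficient_data_error", ...)
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_window <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n %% 2 != 1) {
    abort_config("window length must be a positive odd integer")
  }
  as.integer(n)
}

## derive a child seed from a base seed and a stream label, keeping the
## result inside the 32-bit integer range
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483629)
}
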