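# Internal helpers shared across modules.

# Locale-independent sort so entity indexes are identical across machines.
sort_c <- function(x) sort(x, method = "radix")

# 1/x with the 0/0 := 0 convention used throughout the propagation steps:
# a zero-degree node neither receives nor redistributes resource.
safe_inv <- function(x) ifelse(x > 0, 1 / x, 0)

stop_param <- function(msg, ...) abort(msg, class = "tripred_parameter_error", ...)
stop_io <- function(msg, ...) abort(msg, class = "tripred_io_error", ...)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param(sprintf("`%s` must be a single number in [0, 1], not %s.",
                       name, deparse(substitute(x))))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_param(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
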